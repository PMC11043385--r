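# Representative rigid-body base-step parameters for the 16 DNA dinucleotides,
# version 1. Columns: twist/tilt (degrees), roll (degrees), shift/slide/rise
# (Angstrom). SYNTHETIC: values are representative of the crystallographic
# literature ranges and obey complementary-step symmetry; they are not a
# transcription of any single published table. Encoders standardize each
# property to zero mean and unit variance across the 16 steps before use, so
# only the relative pattern matters.
dimer	twist	tilt	roll	shift	slide	rise
AA	35.3	-0.4	0.5	-0.05	-0.21	3.27
AC	31.9	-0.3	0.3	0.13	-0.54	3.36
AG	32.3	-0.1	4.5	0.05	-0.27	3.34
AT	29.8	0.0	-0.8	0.00	-0.62	3.31
CA	36.3	0.3	4.7	0.09	0.18	3.33
CC	32.9	-0.1	3.6	0.05	-0.47	3.42
CG	36.1	0.0	5.4	0.00	0.52	3.39
CT	32.3	0.1	4.5	-0.05	-0.27	3.34
GA	39.3	-0.1	1.9	-0.02	-0.03	3.37
GC	38.3	0.0	0.3	0.00	-0.07	3.40
GG	32.9	0.1	3.6	-0.05	-0.47	3.42
GT	31.9	0.3	0.3	-0.13	-0.54	3.36
TA	37.8	0.0	3.3	0.00	0.05	3.42
TC	39.3	0.1	1.9	0.02	-0.03	3.37
TG	36.3	-0.3	4.7	-0.09	0.18	3.33
TT	35.3	0.4	0.5	0.05	-0.21	3.27
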