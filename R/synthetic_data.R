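# Synthetic labeled sequence sets with the statistical structure the
# pipeline assumes: variable lengths and a class signal that is a 2-mer
# compositional bias concentrated in an initial region of the positive
# sequences.

#' Specification of a synthetic dataset
#'
#' Defaults are the package's study conditions: 200 sequences per class,
#' lengths uniform over 600-3000 nt, a 500-nt informative prefix enriched
#' for the dimers TT, TA and GG with effect size `delta = 0.8`, negatives
#' by dinucleotide-preserving shuffling.
#'
#' Positive sequences draw their first `B` nucleotides from a first-order
#' Markov chain: from residue x, with probability `delta` the successor is
#' uniform over the enriched continuations of x (when x starts an enriched
#' dimer), otherwise uniform over A,C,G,T. The remainder of the sequence is
#' uniform i.i.d. `delta = 0` therefore makes the classes exchangeable.
#'
#' @param n_pos,n_neg sequences per class.
#' @param length_range integer 2-vector (min, max) nt.
#' @param B informative prefix length, `B <= min(length_range)`.
#' @param enriched_dimers subset of the 16 dimers receiving the bias.
#' @param delta effect size in [0, 1].
#' @param negative_mode `"shuffle"` (dinucleotide-shuffled positives) or
#'   `"background"` (uniform i.i.d. sequences).
#' @param seed master seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L,
                           length_range = c(600L, 3000L), B = 500L,
                           enriched_dimers = c("TT", "TA", "GG"),
                           delta = 0.8, negative_mode = c("shuffle", "background"),
                           seed = 1L) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1L] >= 3L, length_range[2L] >= length_range[1L],
            B >= 1L, B <= length_range[1L],
            delta >= 0, delta <= 1,
            all(enriched_dimers %in% kmer_names(2L)))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), B = as.integer(B),
                 enriched_dimers = enriched_dimers, delta = delta,
                 negative_mode = negative_mode, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sample one positive sequence of length L under the spec's Markov prefix.
sample_positive <- function(L, B, enriched, delta) {
  succ <- lapply(NUCS, function(x) {
    e <- enriched[substr(enriched, 1L, 1L) == x]
    substr(e, 2L, 2L)
  })
  names(succ) <- NUCS
  out <- character(L)
  out[1L] <- sample(NUCS, 1L)
  nB <- min(B, L)
  for (i in seq_len(nB - 1L) + 1L) {
    x <- out[i - 1L]
    en <- succ[[x]]
    out[i] <- if (length(en) > 0L && stats::runif(1L) < delta) {
      if (length(en) == 1L) en else sample(en, 1L)
    } else {
      sample(NUCS, 1L)
    }
  }
  if (L > nB) out[(nB + 1L):L] <- sample(NUCS, L - nB, replace = TRUE)
  paste(out, collapse = "")
}

#' Generate a synthetic labeled dataset
#'
#' Fully determined by `spec$seed`; negatives either dinucleotide-shuffle
#' the positives (identical class-wise dimer composition, so any classifier
#' signal must come from arrangement) or are uniform background sequences.
#'
#' @param spec a [synthetic_spec()].
#' @return labeled sequence data.frame (no split), attribute `"spec"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(substream_seed(spec$seed, "synth:pos"))
  lens <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]),
                 spec$n_pos, replace = TRUE)
  pos <- make_seqs(id = sprintf("pos%04d", seq_len(spec$n_pos)),
                   seq = vapply(lens, sample_positive, "", B = spec$B,
                                enriched = spec$enriched_dimers,
                                delta = spec$delta),
                   label = 1L)
  neg <- if (spec$negative_mode == "shuffle") {
    if (spec$n_neg != spec$n_pos) {
      stop("shuffle mode requires n_neg == n_pos", call. = FALSE)
    }
    generate_negatives(pos, substream_seed(spec$seed, "synth:neg"))
  } else {
    set.seed(substream_seed(spec$seed, "synth:neg"))
    nlens <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]),
                    spec$n_neg, replace = TRUE)
    make_seqs(id = sprintf("neg%04d", seq_len(spec$n_neg)),
              seq = vapply(nlens, function(L)
                paste(sample(NUCS, L, replace = TRUE), collapse = ""), ""),
              label = 0L)
  }
  ds <- rbind(pos, neg)
  rownames(ds) <- NULL
  attr(ds, "spec") <- spec
  ds
}

#' Generate a toy genome assembly plus valid intervals
#'
#' Uniform random chromosomes and a table of in-bounds intervals, for
#' exercising coordinate extraction.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths (recycled to `n_chrom`).
#' @param n_intervals intervals to emit (default 10).
#' @param seed integer seed.
#' @return list with `assembly` (named character vector) and `intervals`
#'   (data.frame `chrom`, `start`, `end`, `id`).
#' @export
generate_toy_genome <- function(n_chrom, lengths, n_intervals = 10L, seed = 1L) {
  stopifnot(n_chrom >= 1L, all(lengths >= 2L))
  lengths <- rep_len(as.integer(lengths), n_chrom)
  set.seed(substream_seed(seed, "toygenome"))
  assembly <- stats::setNames(vapply(lengths, function(L)
    paste(sample(NUCS, L, replace = TRUE), collapse = ""), ""),
    sprintf("chr%d", seq_len(n_chrom)))
  chrom <- sample(names(assembly), n_intervals, replace = TRUE)
  starts <- vapply(chrom, function(cc)
    sample.int(nchar(assembly[[cc]]) - 1L, 1L) - 1L, 0L)
  ends <- vapply(seq_len(n_intervals), function(i) {
    L <- nchar(assembly[[chrom[i]]])
    starts[i] + sample.int(L - starts[i], 1L)
  }, 0L)
  list(assembly = assembly,
       intervals = data.frame(chrom = chrom, start = as.integer(starts),
                              end = as.integer(ends),
                              id = sprintf("iv%d", seq_len(n_intervals)),
                              row.names = NULL, stringsAsFactors = FALSE))
}
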