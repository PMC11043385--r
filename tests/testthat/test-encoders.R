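test_that("k-mer composition matches hand enumerations", {
  expect_equal(as.numeric(kmer_composition("ACGT", 1)), rep(0.25, 4))
  v <- kmer_composition("AAAA", 2)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  v2 <- kmer_composition("AGATGAG", 2)
  expect_equal(unname(v2[c("AG", "GA", "AT", "TG")]),
               c(2 / 6, 2 / 6, 1 / 6, 1 / 6))
  expect_equal(sum(v2 > 0), 4)
})

test_that("ENAC counts nucleotides per sliding window", {
  expect_equal(as.numeric(enac("AAAA", W = 2)), rep(c(2, 0, 0, 0), 3))
  expect_equal(as.numeric(enac("ACGT", W = 4)), c(1, 1, 1, 1))
  expect_equal(as.numeric(enac("AACG", W = 2)),
               c(2, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1, 0))
  expect_error(enac("ACG", W = 5), "shorter")
})

test_that("positional encodings follow their block definitions", {
  expect_equal(as.numeric(positional_encoding("ACGT", "EIIP")),
               c(0.1260, 0.1340, 0.0806, 0.1335))
  expect_equal(as.numeric(positional_encoding("A", "binary")), c(1, 0, 0, 0))
  expect_equal(as.numeric(positional_encoding("AG", "ANF")),
               c(1, 1, 1, 1, 1, 0, 0, 0.5))
  # N and pad positions give all-zero blocks
  expect_equal(as.numeric(positional_encoding("NP", "binary")), rep(0, 8))
  expect_equal(as.numeric(positional_encoding("ANP", "NCP")),
               c(1, 1, 1, rep(0, 6)))
})

test_that("CKSNAP reproduces the worked gap-pair enumeration", {
  v <- cksnap("AGATGAG", G = 1)
  g0 <- v[paste0("g0.", kmer_names(2))]
  expect_equal(unname(g0[c("g0.AG", "g0.GA", "g0.AT", "g0.TG")]),
               c(2 / 6, 2 / 6, 1 / 6, 1 / 6))
  g1 <- v[paste0("g1.", kmer_names(2))]
  expect_equal(unname(g1[c("g1.AA", "g1.GT", "g1.AG", "g1.TA", "g1.GG")]),
               rep(1 / 5, 5))
  expect_equal(sum(g1 > 0), 5)
  v2 <- cksnap("AAAA", G = 1)
  expect_equal(unname(v2[c("g0.AA", "g1.AA")]), c(1, 1))
  expect_error(cksnap("ACG", G = 5), "too short")
})

test_that("PseEIIP multiplies summed potentials by trimer frequencies", {
  v <- pseeiip("AAAA")
  expect_equal(unname(v["AAA"]), 3 * 0.1260)
  expect_equal(sum(v != 0), 1)
  v2 <- pseeiip("ACGT")
  expect_equal(unname(v2["ACG"]), (0.1260 + 0.1340 + 0.0806) * 0.5)
  expect_equal(unname(v2["CGT"]), (0.1340 + 0.0806 + 0.1335) * 0.5)
  expect_length(v2, 64)
})

test_that("pseudo compositions sum to 1 and collapse for poly-A input", {
  for (s in c("ACGTACGT", "AAGCTTGGACCA")) {
    expect_equal(sum(psednc(s, 2, 0.1)), 1, tolerance = 1e-12)
    expect_equal(sum(pseknc(s, 3, 2, 0.1)), 1, tolerance = 1e-12)
    expect_equal(sum(scpsednc(s, 2, 0.1)), 1, tolerance = 1e-12)
  }
  pa <- psednc(strrep("A", 30), 3, 0.1)
  expect_equal(unname(pa["AA"]), 1)
  expect_equal(unname(pa[17:19]), rep(0, 3))
  sc <- scpsednc(strrep("A", 30), 2, 0.1)
  expect_equal(unname(sc[17:28]), rep(0, 12))
  # PseKNC at k = 2 is PseDNC by definition
  expect_equal(as.numeric(pseknc("ACGTACGTAC", k = 2, 2, 0.1)),
               as.numeric(psednc("ACGTACGTAC", 2, 0.1)))
})

test_that("the property table is standardized per property", {
  props <- dinucleotide_properties()
  expect_equal(dim(props), c(16L, 6L))
  expect_equal(rownames(props), kmer_names(2))
  expect_equal(unname(colMeans(props)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(props, 2, var)), rep(1, 6), tolerance = 1e-9)
})

test_that("every encoder agrees with its naive-loop oracle on random input", {
  props <- oracle_props()
  set.seed(101)
  for (rep in 1:30) {
    s <- rand_seq(sample(12:50, 1))
    expect_equal(as.numeric(kmer_composition(s, 1)), unname(oracle_kmer_comp(s, 1)))
    expect_equal(as.numeric(kmer_composition(s, 2)), unname(oracle_kmer_comp(s, 2)))
    expect_equal(as.numeric(kmer_composition(s, 3)), unname(oracle_kmer_comp(s, 3)))
    expect_equal(as.numeric(enac(s, 5)), oracle_enac(s, 5))
    for (sch in c("binary", "NCP", "EIIP", "ANF")) {
      expect_equal(as.numeric(positional_encoding(s, sch)),
                   oracle_positional(s, sch))
    }
    expect_equal(as.numeric(cksnap(s, 5)), unname(oracle_cksnap(s, 5)))
    expect_equal(as.numeric(pseeiip(s)), oracle_pseeiip(s))
    expect_equal(as.numeric(psednc(s, 2, 0.1)),
                 unname(oracle_pseknc(s, 2, 2, 0.1, props)), tolerance = 1e-9)
    expect_equal(as.numeric(pseknc(s, 3, 2, 0.1)),
                 unname(oracle_pseknc(s, 3, 2, 0.1, props)), tolerance = 1e-9)
    expect_equal(as.numeric(scpsednc(s, 2, 0.1)),
                 unname(oracle_scpsednc(s, 2, 0.1, props)), tolerance = 1e-9)
  }
})

test_that("encoder output dimensions match their closed forms", {
  set.seed(55)
  dims <- list(nac = function(L) 4, dnc = function(L) 16,
               tnc = function(L) 64, enac = function(L) 4 * (L - 5 + 1),
               binary = function(L) 4 * L, ncp = function(L) 3 * L,
               eiip = function(L) L, anf = function(L) 4 * L,
               cksnap = function(L) 96, pseeiip = function(L) 64,
               psednc = function(L) 18, pseknc = function(L) 66,
               scpsednc = function(L) 28)
  for (rep in 1:40) {
    L <- sample(10:60, 1)
    s <- rand_seq(L)
    for (enc in encoder_ids()) {
      fn <- leccdna:::encoder_function(enc)
      expect_length(fn(s), dims[[enc]](L))
    }
  }
})

test_that("count-based encoders ignore pad and N residues entirely", {
  set.seed(9)
  for (rep in 1:10) {
    s <- rand_seq(sample(20:40, 1))
    padded <- fix_length(s, nchar(s) + 15)
    expect_equal(as.numeric(kmer_composition(s, 2)),
                 as.numeric(kmer_composition(padded, 2)))
    expect_equal(as.numeric(kmer_composition(s, 3)),
                 as.numeric(kmer_composition(padded, 3)))
    expect_equal(as.numeric(cksnap(s, 3)), as.numeric(cksnap(padded, 3)))
    expect_equal(as.numeric(pseeiip(s)), as.numeric(pseeiip(padded)))
  }
  # interior N drops affected words but keeps the rest
  v <- kmer_composition("AANAA", 2)
  expect_equal(unname(v["AA"]), 1)
})

test_that("fusion concatenates in order with provenance-prefixed names", {
  s <- strrep("ACGT", 10)
  a <- kmer_composition(s, 2)
  b <- pseeiip(s)
  f <- fuse(list(a, b))
  expect_length(f, 80)
  expect_equal(as.numeric(f[1:16]), as.numeric(a))
  expect_true(all(startsWith(names(f)[1:16], "dnc.")))
  expect_true(all(startsWith(names(f)[17:80], "pseeiip.")))
  expect_equal(as.numeric(fuse(list(a))), as.numeric(a))
  expect_error(fuse(list()), "non-empty")
  # the fused CKSNAP + PseEIIP representation is 96 + 64 = 160-dimensional
  expect_length(fuse(list(cksnap(s, 5), pseeiip(s))), 160)
})

test_that("encode_matrix builds aligned feature matrices", {
  set.seed(13)
  seqs <- data.frame(id = sprintf("s%d", 1:6),
                     seq = vapply(rep(30, 6), rand_seq, ""))
  X <- encode_matrix(seqs, c("dnc", "pseeiip"))
  expect_equal(dim(X), c(6L, 80L))
  expect_equal(rownames(X), seqs$id)
  expect_equal(as.numeric(X[3, 1:16]),
               as.numeric(kmer_composition(seqs$seq[3], 2)))
  expect_error(encode_matrix(seqs, "nope"), "unknown encoder")
})
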