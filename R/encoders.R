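# Sequence encoders: transform one DNA sequence into a fixed set of real
# features. Conventions shared by all encoders:
#   * k-mers/dimers are ordered lexicographically over A < C < G < T;
#   * residues N (ambiguous) and P (pad) never contribute to counts: any
#     k-mer or gapped pair touching them is excluded from numerator and
#     denominator, and positional encoders emit all-zero blocks for them;
#   * outputs are named numeric vectors with an "encoder" attribute, so
#     fusion can prefix feature names by provenance.

new_feature_vector <- function(values, names, encoder, params = list()) {
  stopifnot(length(values) == length(names))
  v <- stats::setNames(as.numeric(values), names)
  attr(v, "encoder") <- encoder
  attr(v, "params") <- params
  v
}

# Overlapping k-mer strings of a sequence; invalid (N/P-touching) ones are NA.
overlapping_kmers <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(character(0L))
  cols <- lapply(seq_len(k) - 1L, function(j) chars[(1L + j):(n - k + 1L + j)])
  km <- do.call(paste0, cols)
  valid <- !Reduce(`|`, lapply(cols, function(cc) !(cc %in% NUCS)))
  km[!valid] <- NA_character_
  km
}

count_kmers <- function(chars, k) {
  km <- overlapping_kmers(chars, k)
  km <- km[!is.na(km)]
  tab <- table(factor(km, levels = kmer_names(k)))
  as.integer(tab)
}

#' k-mer composition (NAC, DNC, TNC)
#'
#' Normalized frequencies of overlapping k-mers: k = 1 gives nucleic acid
#' composition (NAC), k = 2 dinucleotide composition (DNC), k = 3
#' trinucleotide composition (TNC).
#'
#' @param seq residue string.
#' @param k word length (1, 2 or 3).
#' @return feature vector of length `4^k`, summing to 1.
#' @export
kmer_composition <- function(seq, k) {
  stopifnot(k %in% 1:3)
  counts <- count_kmers(seq_chars(seq), k)
  tot <- sum(counts)
  if (tot == 0L) stop("no valid ", k, "-mer in sequence", call. = FALSE)
  new_feature_vector(counts / tot, kmer_names(k),
                     encoder = c("nac", "dnc", "tnc")[k], params = list(k = k))
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' Counts of the four nucleotides within a window slid along the sequence.
#'
#' @param seq residue string.
#' @param W window size.
#' @param step slide step (default 1).
#' @return feature vector of length `4 * number of windows`
#'   (`4 * (L - W + 1)` at step 1), windows ordered 5' to 3'.
#' @export
enac <- function(seq, W = 5L, step = 1L) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < W) stop("sequence shorter than ENAC window (", L, " < ", W, ")",
                  call. = FALSE)
  starts <- seq.int(1L, L - W + 1L, by = step)
  vals <- unlist(lapply(starts, function(s) {
    win <- chars[s:(s + W - 1L)]
    as.integer(table(factor(win, levels = NUCS)))
  }))
  nm <- as.vector(t(outer(sprintf("w%d", seq_along(starts)), NUCS,
                          function(a, b) paste(a, b, sep = "."))))
  new_feature_vector(vals, nm, "enac", list(W = W, step = step))
}

#' Positional (per-residue) encodings: binary, NCP, EIIP, ANF
#'
#' Encodes each position with a fixed-size block, concatenated 5' to 3':
#' `binary` one-hot (4), `NCP` chemical-property triplet (3), `EIIP` the
#' electron-ion interaction potential (1), `ANF` the NCP triplet plus the
#' accumulated density of the residue's nucleotide up to that position (4).
#' N and pad positions yield all-zero blocks.
#'
#' @param seq residue string.
#' @param scheme one of `"binary"`, `"NCP"`, `"EIIP"`, `"ANF"`.
#' @return feature vector of length `L * block size`.
#' @export
positional_encoding <- function(seq, scheme = c("binary", "NCP", "EIIP", "ANF")) {
  scheme <- match.arg(scheme)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  valid <- chars %in% NUCS
  blocks <- switch(scheme,
    binary = {
      m <- matrix(0, nrow = L, ncol = 4L)
      idx <- match(chars, NUCS)
      m[cbind(which(valid), idx[valid])] <- 1
      m
    },
    NCP = {
      m <- matrix(0, nrow = L, ncol = 3L)
      m[valid, ] <- ncp_table()[chars[valid], , drop = FALSE]
      m
    },
    EIIP = {
      m <- matrix(0, nrow = L, ncol = 1L)
      m[valid, 1L] <- eiip_table()[chars[valid]]
      m
    },
    ANF = {
      m <- matrix(0, nrow = L, ncol = 4L)
      m[valid, 1:3] <- ncp_table()[chars[valid], , drop = FALSE]
      cum <- vapply(NUCS, function(nt) cumsum(chars == nt), numeric(L))
      dens <- if (L == 1L) matrix(cum, nrow = 1L) else cum
      pos <- seq_len(L)
      dwn <- dens[cbind(pos[valid], match(chars[valid], NUCS))] / pos[valid]
      m[valid, 4L] <- dwn
      m
    })
  b <- ncol(blocks)
  nm <- sprintf("p%d.%d", rep(seq_len(L), each = b), rep(seq_len(b), L))
  new_feature_vector(as.vector(t(blocks)), nm, tolower(scheme),
                     list(scheme = scheme))
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP)
#'
#' For each gap g in 0..G, the frequencies of the 16 ordered nucleotide pairs
#' at positions (i, i + g + 1), normalized by the number of valid pairs at
#' that gap. Pairs touching N or pad residues are excluded from both
#' numerator and denominator.
#'
#' @param seq residue string.
#' @param G maximum gap (default 5, giving 96 features).
#' @return feature vector of length `16 * (G + 1)`; each gap block sums to 1.
#' @export
cksnap <- function(seq, G = 5L) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < G + 2L) {
    stop("sequence too short for CKSNAP gap ", G, " (length ", L, ")",
         call. = FALSE)
  }
  dimers <- kmer_names(2L)
  out <- numeric(0L)
  nm <- character(0L)
  for (g in 0:G) {
    i <- seq_len(L - g - 1L)
    a <- chars[i]; b <- chars[i + g + 1L]
    ok <- a %in% NUCS & b %in% NUCS
    if (!any(ok)) stop("no valid pair at gap ", g, call. = FALSE)
    pair <- paste0(a[ok], b[ok])
    counts <- as.integer(table(factor(pair, levels = dimers)))
    out <- c(out, counts / sum(counts))
    nm <- c(nm, sprintf("g%d.%s", g, dimers))
  }
  new_feature_vector(out, nm, "cksnap", list(G = G))
}

#' Pseudo electron-ion interaction potential of trinucleotides (PseEIIP)
#'
#' Each of the 64 trinucleotides contributes the product of (i) the sum of
#' the EIIP constants of its three nucleotides and (ii) its normalized
#' overlapping frequency in the sequence.
#'
#' @param seq residue string.
#' @return feature vector of length 64.
#' @export
pseeiip <- function(seq) {
  counts <- count_kmers(seq_chars(seq), 3L)
  tot <- sum(counts)
  if (tot == 0L) stop("no valid trinucleotide in sequence", call. = FALSE)
  trimers <- kmer_names(3L)
  ei <- eiip_table()
  E <- vapply(strsplit(trimers, "", fixed = TRUE),
              function(tri) sum(ei[tri]), 0)
  new_feature_vector(E * (counts / tot), trimers, "pseeiip", list())
}

# Dimer-correlation factor Theta(d1, d2): mean over the 6 standardized
# properties of the squared value difference. Returns the lag-j averages
# theta_1..theta_lambda for the valid (N/P-free) dimer positions.
theta_factors <- function(chars, lambda, props) {
  L <- length(chars)
  dim_idx <- function(i) {
    a <- chars[i]; b <- chars[i + 1L]
    ifelse(a %in% NUCS & b %in% NUCS, match(paste0(a, b), rownames(props)), NA)
  }
  d <- dim_idx(seq_len(L - 1L))
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(L - 1L - j)
    di <- d[i]; dj <- d[i + j]
    ok <- !is.na(di) & !is.na(dj)
    if (!any(ok)) return(0)
    mean(rowMeans((props[di[ok], , drop = FALSE] -
                   props[dj[ok], , drop = FALSE])^2))
  }, 0)
}

#' Pseudo dinucleotide composition (PseDNC)
#'
#' The 16 normalized dinucleotide frequencies augmented with `lambda`
#' global sequence-order correlation factors computed from six standardized
#' physicochemical step properties, all normalized so the vector sums to 1.
#'
#' @param seq residue string.
#' @param lambda number of correlation lags (default 2).
#' @param w weight of the correlation block in (0, 1] (default 0.1).
#' @param props standardized 16 x 6 property matrix
#'   (default [dinucleotide_properties()]).
#' @return feature vector of length `16 + lambda`, summing to 1.
#' @export
psednc <- function(seq, lambda = 2L, w = 0.1,
                   props = get_dinucleotide_properties()) {
  v <- pseknc(seq, k = 2L, lambda = lambda, w = w, props = props)
  attr(v, "encoder") <- "psednc"
  attr(v, "params") <- list(lambda = lambda, w = w)
  v
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' The `4^k` normalized k-tuple frequencies augmented with `lambda`
#' dinucleotide-property correlation factors; reduces to [psednc()] at
#' `k = 2`.
#'
#' @inheritParams psednc
#' @param k tuple size (default 3).
#' @return feature vector of length `4^k + lambda`, summing to 1.
#' @export
pseknc <- function(seq, k = 3L, lambda = 2L, w = 0.1,
                   props = get_dinucleotide_properties()) {
  stopifnot(k >= 1L, lambda >= 0L, w > 0, w <= 1)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < max(k, lambda + 2L)) {
    stop("sequence too short for PseKNC (length ", L, ", needs >= ",
         max(k, lambda + 2L), ")", call. = FALSE)
  }
  counts <- count_kmers(chars, k)
  tot <- sum(counts)
  if (tot == 0L) stop("no valid ", k, "-mer in sequence", call. = FALSE)
  f <- counts / tot
  th <- if (lambda > 0L) theta_factors(chars, lambda, props) else numeric(0L)
  denom <- 1 + w * sum(th)
  vals <- c(f / denom, w * th / denom)
  nm <- c(kmer_names(k),
          if (lambda > 0L) sprintf("theta%d", seq_len(lambda)))
  new_feature_vector(vals, nm, "pseknc", list(k = k, lambda = lambda, w = w))
}

#' Series correlation pseudo dinucleotide composition (SCPseDNC)
#'
#' Like [psednc()] but keeps the six physicochemical properties separate:
#' one correlation factor per property per lag (`6 * lambda` factors), each
#' the lag-averaged squared difference of that standardized property.
#'
#' @inheritParams psednc
#' @return feature vector of length `16 + 6 * lambda`, summing to 1.
#' @export
scpsednc <- function(seq, lambda = 2L, w = 0.1,
                     props = get_dinucleotide_properties()) {
  stopifnot(lambda >= 0L, w > 0, w <= 1)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < lambda + 2L) {
    stop("sequence too short for SCPseDNC (length ", L, ")", call. = FALSE)
  }
  counts <- count_kmers(chars, 2L)
  tot <- sum(counts)
  if (tot == 0L) stop("no valid dinucleotide in sequence", call. = FALSE)
  f <- counts / tot
  dimers <- rownames(props)
  a <- chars[seq_len(L - 1L)]; b <- chars[seq_len(L - 1L) + 1L]
  d <- ifelse(a %in% NUCS & b %in% NUCS, match(paste0(a, b), dimers), NA)
  th <- numeric(0L); nm_th <- character(0L)
  for (j in seq_len(lambda)) {
    i <- seq_len(L - 1L - j)
    di <- d[i]; dj <- d[i + j]
    ok <- !is.na(di) & !is.na(dj)
    per_prop <- if (any(ok)) {
      colMeans((props[di[ok], , drop = FALSE] -
                props[dj[ok], , drop = FALSE])^2)
    } else rep(0, ncol(props))
    th <- c(th, per_prop)
    nm_th <- c(nm_th, sprintf("lag%d.%s", j, colnames(props)))
  }
  denom <- 1 + w * sum(th)
  new_feature_vector(c(f / denom, w * th / denom), c(kmer_names(2L), nm_th),
                     "scpsednc", list(lambda = lambda, w = w))
}

#' Fuse feature vectors by concatenation
#'
#' Early fusion: the p- and q-dimensional vectors of two (or more) encoders
#' for the same sequence are concatenated into one (p + q)-dimensional
#' vector. Feature names are prefixed with the encoder id.
#'
#' @param vectors non-empty list of feature vectors from the same sequence.
#' @return fused feature vector of length `sum(lengths(vectors))`.
#' @export
fuse <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L) {
    stop("fuse() needs a non-empty list of feature vectors", call. = FALSE)
  }
  parts <- lapply(vectors, function(v) {
    enc <- attr(v, "encoder")
    if (is.null(enc)) enc <- "x"
    stats::setNames(as.numeric(v), paste(enc, names(v), sep = "."))
  })
  out <- do.call(c, parts)
  attr(out, "encoder") <- paste(vapply(vectors, function(v) {
    e <- attr(v, "encoder"); if (is.null(e)) "x" else e
  }, ""), collapse = "+")
  out
}

#' The thirteen encoder ids
#'
#' @return character vector of encoder names usable with [encode_matrix()].
#' @export
encoder_ids <- function() {
  c("nac", "dnc", "tnc", "enac", "binary", "ncp", "eiip", "anf",
    "cksnap", "pseeiip", "psednc", "pseknc", "scpsednc")
}

encoder_function <- function(name) {
  switch(name,
    nac = function(s, ...) kmer_composition(s, 1L),
    dnc = function(s, ...) kmer_composition(s, 2L),
    tnc = function(s, ...) kmer_composition(s, 3L),
    enac = function(s, W = 5L, step = 1L, ...) enac(s, W, step),
    binary = function(s, ...) positional_encoding(s, "binary"),
    ncp = function(s, ...) positional_encoding(s, "NCP"),
    eiip = function(s, ...) positional_encoding(s, "EIIP"),
    anf = function(s, ...) positional_encoding(s, "ANF"),
    cksnap = function(s, G = 5L, ...) cksnap(s, G),
    pseeiip = function(s, ...) pseeiip(s),
    psednc = function(s, lambda = 2L, w = 0.1, ...) psednc(s, lambda, w),
    pseknc = function(s, k = 3L, lambda = 2L, w = 0.1, ...)
      pseknc(s, k, lambda, w),
    scpsednc = function(s, lambda = 2L, w = 0.1, ...) scpsednc(s, lambda, w),
    stop("unknown encoder: ", name, call. = FALSE)
  )
}

#' Encode a sequence table into a feature matrix
#'
#' Applies one or several encoders to every sequence and column-binds
#' (fuses) the per-encoder blocks. Positional encoders require equal-length
#' sequences; run [fix_length_seqs()] first for variable-length input.
#'
#' @param seqs sequence data.frame (`id`, `seq`).
#' @param encoders character vector of encoder ids (see [encoder_ids()]).
#' @param ... encoder parameters (`G`, `W`, `step`, `k`, `lambda`, `w`),
#'   passed to every encoder that accepts them.
#' @return numeric matrix, one row per sequence (rownames = ids), columns
#'   named `<encoder>.<feature>`.
#' @export
encode_matrix <- function(seqs, encoders, ...) {
  validate_seqs(seqs)
  stopifnot(length(encoders) >= 1L)
  unknown <- setdiff(encoders, encoder_ids())
  if (length(unknown)) stop("unknown encoder(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  fns <- lapply(encoders, encoder_function)
  rows <- lapply(seqs$seq, function(s) {
    fuse(lapply(fns, function(f) f(s, ...)))
  })
  dims <- vapply(rows, length, 0L)
  if (length(unique(dims)) != 1L) {
    stop("encoders produced unequal dimensions across sequences; ",
         "fix sequence lengths first (fix_length_seqs)", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- seqs$id
  colnames(m) <- names(rows[[1L]])
  m
}
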