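# Intrinsic 2-mer region analysis: where along the sequences does the
# dinucleotide composition of the two classes diverge? Sequences are cut
# into consecutive subsequences, per-segment dimer counts are averaged over
# sequences per class, and the class difference profile localizes the
# information-rich region.

#' Cut a sequence into consecutive segments
#'
#' Non-overlapping windows of length `S` from the 5' end; a trailing remnant
#' is kept iff it still contains at least one dimer (length >= 2).
#'
#' @param seq residue string.
#' @param S segment length (>= 2).
#' @return character vector of subsequences.
#' @export
segment_sequence <- function(seq, S) {
  if (S < 2L) stop("segment length must be >= 2", call. = FALSE)
  L <- nchar(seq)
  starts <- seq.int(1L, max(L, 1L), by = S)
  segs <- substring(seq, starts, pmin(starts + S - 1L, L))
  segs[nchar(segs) >= 2L]
}

#' Per-segment dimer density profile of a sequence class
#'
#' Entry (s, d) is the total count of overlapping dimer `d` inside segment
#' `s` across all sequences, divided by the number of sequences. Sequences
#' that do not extend into a segment contribute zero there; dimers touching
#' N/pad residues are excluded.
#'
#' @param seqs sequence data.frame for one class.
#' @param S segment length in nt (default 500).
#' @param num_segments number of segments from the 5' end (default 10).
#' @return a `density_profile`: list with `matrix` (num_segments x 16,
#'   rownames `seg1..`), `S`, `n`.
#' @export
dimer_density_profile <- function(seqs, S = 500L, num_segments = 10L) {
  validate_seqs(seqs)
  stopifnot(S >= 2L, num_segments >= 1L)
  dimers <- kmer_names(2L)
  m <- matrix(0, nrow = num_segments, ncol = 16L,
              dimnames = list(sprintf("seg%d", seq_len(num_segments)), dimers))
  for (s in seqs$seq) {
    chars <- seq_chars(s)
    L <- length(chars)
    for (g in seq_len(num_segments)) {
      lo <- (g - 1L) * S + 1L
      hi <- min(g * S, L)
      if (hi - lo + 1L < 2L) break
      seg <- chars[lo:hi]
      a <- seg[-length(seg)]; b <- seg[-1L]
      ok <- a %in% NUCS & b %in% NUCS
      if (!any(ok)) next
      counts <- table(factor(paste0(a[ok], b[ok]), levels = dimers))
      m[g, ] <- m[g, ] + as.integer(counts)
    }
  }
  structure(list(matrix = m / nrow(seqs), S = S, n = nrow(seqs)),
            class = "density_profile")
}

#' Class difference of two density profiles
#'
#' @param pos density profile of the positive (leccDNA) class.
#' @param neg density profile of the negative class.
#' @return matrix (segments x 16): `pos$matrix - neg$matrix`.
#' @export
density_difference <- function(pos, neg) {
  stopifnot(inherits(pos, "density_profile"), inherits(neg, "density_profile"))
  if (pos$S != neg$S || !identical(dim(pos$matrix), dim(neg$matrix))) {
    stop("profiles have mismatched segmentation", call. = FALSE)
  }
  pos$matrix - neg$matrix
}

#' Rank the most discriminative (dimer, segment) cells
#'
#' @param diff difference matrix from [density_difference()].
#' @param m number of top cells to return.
#' @return data.frame (`dimer`, `segment`, `difference`) sorted by
#'   `|difference|` descending; ties broken by dimer then segment index.
#' @export
top_discriminative_dimers <- function(diff, m = 10L) {
  stopifnot(m >= 1L)
  long <- data.frame(
    dimer = rep(colnames(diff), each = nrow(diff)),
    segment = rep(seq_len(nrow(diff)), times = ncol(diff)),
    difference = as.vector(diff))
  ord <- order(-abs(long$difference), long$dimer, long$segment)
  out <- long[ord, , drop = FALSE][seq_len(min(m, nrow(long))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a density profile or difference matrix as TSV
#'
#' @param x a `density_profile` or a difference matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  m <- if (inherits(x, "density_profile")) x$matrix else x
  utils::write.table(data.frame(segment = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
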