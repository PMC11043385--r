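#' Read sequences from a FASTA file
#'
#' Records are returned in file order with residues upper-cased. Sequences are
#' stored in a plain data.frame with columns `id`, `seq` and `label`
#' (`NA` unless the caller assigns class labels).
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `seq`, `label`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA format error at line 1: file is empty", call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error at line ", first,
         ": expected a '>' header", call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  df <- make_seqs(id = names(recs),
                  seq = vapply(recs, function(r) as.character(r)[1L], ""))
  rownames(df) <- NULL
  df
}

#' Write sequences to a FASTA file
#'
#' @param seqs sequence data.frame (`id`, `seq`).
#' @param path output path.
#' @param width line width for wrapping residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  validate_seqs(seqs)
  stopifnot(width >= 1L)
  seqinr::write.fasta(as.list(seqs$seq), names = seqs$id,
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Read a genome assembly from FASTA
#'
#' @param path genome FASTA; one record per chromosome.
#' @return named character vector, chromosome id -> residue string.
#' @export
read_genome <- function(path) {
  df <- read_fasta(path)
  stats::setNames(df$seq, df$id)
}

#' Read a coordinate table (BED dialect)
#'
#' Headerless TSV with columns chromosome, start, end and an optional id.
#' Coordinates are 0-based half-open by default; `one_based = TRUE` accepts
#' 1-based inclusive coordinates and converts them on read.
#'
#' @param path TSV/BED path.
#' @param one_based logical; input uses 1-based inclusive coordinates.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_intervals <- function(path, one_based = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("interval table needs >= 3 columns", call. = FALSE)
  df <- data.frame(chrom = as.character(tab[[1L]]),
                   start = as.integer(tab[[2L]]),
                   end = as.integer(tab[[3L]]),
                   stringsAsFactors = FALSE)
  df$id <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
    sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  if (one_based) df$start <- df$start - 1L
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("invalid intervals: need 0 <= start < end", call. = FALSE)
  }
  df
}

#' Extract a genomic interval from an assembly
#'
#' Coordinates are 0-based half-open; the strand is assumed '+' (no
#' reverse complementing).
#'
#' @param assembly named character vector (see [read_genome()]).
#' @param chrom chromosome id.
#' @param start 0-based start (inclusive).
#' @param end 0-based end (exclusive); must exceed `start`.
#' @param id optional record id for the returned sequence.
#' @return one-row sequence data.frame of length `end - start`.
#' @export
extract_interval <- function(assembly, chrom, start, end, id = NULL) {
  if (!chrom %in% names(assembly)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  L <- nchar(assembly[[chrom]])
  if (end <= start) stop("empty or inverted interval [", start, ",", end, ")",
                         call. = FALSE)
  if (start < 0L || end > L) {
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", L, ")", call. = FALSE)
  }
  res <- substr(assembly[[chrom]], start + 1L, end)
  make_seqs(id = if (is.null(id)) sprintf("%s:%d-%d", chrom, start, end) else id,
            seq = res)
}

#' Force a sequence to a fixed length
#'
#' Sequences longer than `L` keep their 5' prefix (the information-rich
#' region of leccDNA sequences concentrates at the start); shorter sequences
#' are padded at the 3' end with the pad character.
#'
#' @param seq residue string (or vector of strings).
#' @param L target length.
#' @param pad single pad character, default `"P"`.
#' @return character vector of residue strings, each of length `L`.
#' @export
fix_length <- function(seq, L, pad = "P") {
  stopifnot(L >= 1L, nchar(pad) == 1L)
  seq <- toupper(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n >= L) substr(s, 1L, L)
    else paste0(s, strrep(pad, L - n))
  }, "", USE.NAMES = FALSE)
}

#' Fix the length of every sequence in a table
#'
#' @param seqs sequence data.frame.
#' @inheritParams fix_length
#' @return the table with `seq` replaced by fixed-length residues.
#' @export
fix_length_seqs <- function(seqs, L, pad = "P") {
  validate_seqs(seqs)
  seqs$seq <- fix_length(seqs$seq, L, pad)
  seqs
}
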