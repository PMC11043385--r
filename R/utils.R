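#' @keywords internal
"_PACKAGE"

# Residue alphabet: A,C,G,T plus ambiguous N and the pad character P.
NUCS <- c("A", "C", "G", "T")
SEQ_ALPHABET <- c(NUCS, "N", "P")

#' Deterministic sub-stream seed
#'
#' All randomness in the package flows from one user seed; each component
#' draws from its own named sub-stream so that, e.g., negative generation and
#' fold assignment are reproducible independently of call order.
#'
#' @param seed integer master seed.
#' @param name character sub-stream name.
#' @return an integer in [0, 2^31), usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' All k-mers over {A,C,G,T} in lexicographic order
#'
#' @param k word length.
#' @return character vector of length `4^k`, ordered A < C < G < T.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1)
  out <- NUCS
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      out <- as.vector(t(outer(out, NUCS, paste0)))
    }
  }
  out
}

# Split a residue string into a character vector, upper-cased.
seq_chars <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
}

# Validate a sequence table: data.frame with id, seq and optional label column.
validate_seqs <- function(seqs, require_label = FALSE) {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("expected a data.frame with columns 'id' and 'seq'", call. = FALSE)
  }
  if (nrow(seqs) == 0L) stop("sequence table is empty", call. = FALSE)
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(SEQ_ALPHABET, collapse = "")),
               toupper(seqs$seq))
  if (any(bad)) {
    stop("residues outside alphabet {A,C,G,T,N,P} in: ",
         paste(utils::head(seqs$id[bad], 3L), collapse = ", "), call. = FALSE)
  }
  if (require_label) {
    if (!("label" %in% names(seqs)) || any(is.na(seqs$label)) ||
        !all(seqs$label %in% c(0L, 1L))) {
      stop("labels must be present and in {0, 1}", call. = FALSE)
    }
  }
  invisible(seqs)
}

# Construct a sequence table (the package's NucleotideSequence container).
make_seqs <- function(id, seq, label = NA_integer_) {
  df <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                   label = as.integer(label), stringsAsFactors = FALSE)
  validate_seqs(df)
  df
}
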