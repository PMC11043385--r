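#' Electron-ion interaction potential (EIIP) of the four nucleotides
#'
#' Fixed pseudopotential constants representing the energy of delocalized
#' electrons of each nucleotide: A 0.1260, C 0.1340, G 0.0806, T 0.1335.
#'
#' @return named numeric vector of length 4.
#' @export
eiip_table <- function() {
  c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
}

# Nucleotide chemical property triplets: ring structure, functional group,
# hydrogen-bond strength. Purines (A,G) open the first bit; amino bases (A,C)
# the second; weak H-bonding bases (A,T) the third.
ncp_table <- function() {
  rbind(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), T = c(0, 0, 1))
}

#' Standardized dinucleotide physicochemical property table
#'
#' Loads the packaged 16 x 6 table of rigid-body step parameters (twist,
#' tilt, roll, shift, slide, rise) and standardizes each property to zero
#' mean and unit variance across the 16 dinucleotides. The shipped values are
#' a synthetic representative table (see the file header in
#' `extdata/dinucleotide_properties_synthetic.tsv`); standardization makes
#' the pseudo-composition encoders insensitive to each property's scale.
#'
#' @param path optional path to an alternative raw property TSV with a
#'   `dimer` column and one numeric column per property.
#' @return 16 x 6 numeric matrix, rows named by dinucleotide in lexicographic
#'   order, each column with mean 0 and unit variance.
#' @export
dinucleotide_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinucleotide_properties_synthetic.tsv",
                        package = "leccdna", mustWork = TRUE)
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"dimer" %in% names(raw) || nrow(raw) != 16L) {
    stop("property table must have a 'dimer' column and 16 rows",
         call. = FALSE)
  }
  m <- as.matrix(raw[, setdiff(names(raw), "dimer"), drop = FALSE])
  rownames(m) <- raw$dimer
  m <- m[kmer_names(2L), , drop = FALSE]
  scale(m)[, , drop = FALSE]
}

# Memoized copy of the standardized property table (loaded once per session).
prop_env <- new.env(parent = emptyenv())
get_dinucleotide_properties <- function() {
  if (is.null(prop_env$tab)) prop_env$tab <- dinucleotide_properties()
  prop_env$tab
}
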