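# Benchmark-style dataset construction: dinucleotide-preserving shuffled
# negatives, approximate redundancy filtering, stratified splits.

#' Dinucleotide-preserving shuffle of one sequence
#'
#' Produces a random permutation of the sequence that preserves exactly its
#' multiset of overlapping dinucleotides (hence also its length, its
#' mononucleotide counts, and its first and last residues), via the
#' Altschul-Erickson Euler-path construction on the nucleotide transition
#' multigraph: a random last-edge arborescence converging on the terminal
#' residue guarantees an Eulerian walk exists, the remaining out-edges of
#' each residue are randomly ordered, and the walk spells the shuffled
#' sequence.
#'
#' @param seq residue string over {A,C,G,T}, length >= 3.
#' @param seed integer seed; identical seeds give identical output.
#' @return shuffled residue string.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 3L) stop("sequence too short to shuffle (length ", L, ")",
                   call. = FALSE)
  if (!all(chars %in% NUCS)) {
    stop("dinucleotide_shuffle requires residues in {A,C,G,T}", call. = FALSE)
  }
  set.seed(seed)
  first <- chars[1L]; last <- chars[L]
  # adjacency: for each source nucleotide, the multiset of targets
  adj <- lapply(NUCS, function(nt) chars[which(chars[-L] == nt) + 1L])
  names(adj) <- NUCS
  present <- NUCS[vapply(adj, length, 0L) > 0L | NUCS == last]

  # Choose, for every non-terminal vertex with out-edges, a random "last
  # edge"; accept when the chosen edges form paths that all reach `last`
  # (a spanning arborescence of the contracted graph toward `last`).
  sources <- setdiff(NUCS[vapply(adj, length, 0L) > 0L], last)
  repeat {
    last_edge <- vapply(sources, function(nt) {
      tg <- adj[[nt]]
      tg[sample.int(length(tg), 1L)]
    }, "")
    reaches <- function(nt) {
      seen <- character(0L)
      while (nt != last) {
        if (nt %in% seen || !(nt %in% names(last_edge))) return(FALSE)
        seen <- c(seen, nt)
        nt <- last_edge[[nt]]
      }
      TRUE
    }
    if (all(vapply(sources, reaches, TRUE))) break
  }

  # Shuffle the remaining out-edges of each vertex, appending its last edge.
  ordered <- lapply(NUCS, function(nt) {
    tg <- adj[[nt]]
    if (nt %in% names(last_edge)) {
      le <- last_edge[[nt]]
      tg <- tg[-match(le, tg)]
      c(tg[sample.int(length(tg))], le)
    } else {
      tg[sample.int(length(tg))]
    }
  })
  names(ordered) <- NUCS
  ptr <- stats::setNames(rep(1L, 4L), NUCS)
  out <- character(L)
  out[1L] <- first
  cur <- first
  for (i in 2:L) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Generate shuffled negatives for a positive set
#'
#' One dinucleotide-preserving shuffle per positive sequence: equal lengths,
#' identical per-pair dimer multisets, label 0, ids suffixed with `_neg`.
#'
#' @param positives sequence data.frame of positives (residues A/C/G/T).
#' @param seed master seed; per-sequence sub-seeds are derived from it.
#' @return sequence data.frame of negatives, same number of rows.
#' @export
generate_negatives <- function(positives, seed) {
  validate_seqs(positives)
  neg <- vapply(seq_len(nrow(positives)), function(i) {
    dinucleotide_shuffle(positives$seq[i],
                         substream_seed(seed, paste0("shuffle:",
                                                     positives$id[i])))
  }, "")
  make_seqs(id = paste0(positives$id, "_neg"), seq = neg, label = 0L)
}

shared_kmer_similarity <- function(kmers_a, kmers_b) {
  # containment fraction: shared distinct 5-mers over the smaller repertoire
  small <- if (length(kmers_a) <= length(kmers_b)) kmers_a else kmers_b
  big <- if (length(kmers_a) <= length(kmers_b)) kmers_b else kmers_a
  if (length(small) == 0L) return(0)
  length(intersect(small, big)) / length(small)
}

#' Redundancy filtering of similar sequences
#'
#' Greedy longest-first clustering with shared-5-mer containment fraction as
#' the similarity proxy: sequences are visited by decreasing length (id as
#' tie-break) and join the first existing cluster whose representative
#' shares more than `threshold` of the shorter repertoire's distinct
#' 5-mers; otherwise they found a new cluster. One representative (the
#' longest member) survives per cluster. This approximates similarity-based
#' redundancy removal (CD-HIT style); exact CD-HIT output can be imported
#' instead via `clstr_path`.
#'
#' @param seqs sequence data.frame.
#' @param threshold similarity threshold in (0, 1); sequences with
#'   similarity strictly greater than it are clustered. Default 0.6.
#' @param clstr_path optional path to a CD-HIT `.clstr` file; if given, its
#'   representatives (rows marked `*`) are returned and no internal
#'   clustering is done.
#' @return subset of `seqs` (cluster representatives), in input order.
#' @export
redundancy_filter <- function(seqs, threshold = 0.6, clstr_path = NULL) {
  validate_seqs(seqs)
  if (!is.null(clstr_path)) {
    reps <- read_clstr_representatives(clstr_path)
    missing <- setdiff(reps, seqs$id)
    if (length(missing)) {
      stop("cluster file names unknown ids: ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    }
    return(seqs[seqs$id %in% reps, , drop = FALSE])
  }
  stopifnot(threshold > 0, threshold < 1)
  ord <- order(-nchar(seqs$seq), seqs$id)
  kmer_sets <- lapply(seqs$seq, function(s) {
    km <- overlapping_kmers(seq_chars(s), 5L)
    unique(km[!is.na(km)])
  })
  rep_idx <- integer(0L)
  for (i in ord) {
    hit <- FALSE
    for (r in rep_idx) {
      if (shared_kmer_similarity(kmer_sets[[i]], kmer_sets[[r]]) > threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) rep_idx <- c(rep_idx, i)
  }
  seqs[sort(rep_idx), , drop = FALSE]
}

# Parse a CD-HIT .clstr file and return the representative ids (lines
# flagged with a trailing '*').
read_clstr_representatives <- function(path) {
  lines <- readLines(path, warn = FALSE)
  reps <- character(0L)
  for (ln in lines) {
    if (startsWith(ln, ">")) next
    if (!grepl("\\*\\s*$", ln)) next
    m <- regmatches(ln, regexpr(">[^.]+\\.\\.\\.", ln))
    if (length(m) == 0L) {
      stop("malformed .clstr line: ", ln, call. = FALSE)
    }
    reps <- c(reps, sub("\\.\\.\\.$", "", sub("^>", "", m)))
  }
  if (length(reps) == 0L) stop("no representatives found in ", path,
                               call. = FALSE)
  reps
}

#' Stratified train/test split
#'
#' Splits a labeled, balanced sequence set into train and test partitions,
#' preserving class balance in both, deterministically under `seed`.
#'
#' @param seqs labeled sequence data.frame (labels in {0, 1}).
#' @param test_fraction fraction held out per class (default 0.2).
#' @param seed integer seed.
#' @return the table with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(seqs, test_fraction = 0.2, seed) {
  validate_seqs(seqs, require_label = TRUE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  seqs$split <- NA_character_
  set.seed(substream_seed(seed, "split"))
  for (cls in c(0L, 1L)) {
    idx <- which(seqs$label == cls)
    if (length(idx) < 2L) {
      stop("class ", cls, " has fewer than 2 sequences", call. = FALSE)
    }
    idx <- idx[order(seqs$id[idx])]   # id order before drawing: reproducible
    n_test <- max(1L, round(test_fraction * length(idx)))
    test <- sample(idx, n_test)
    seqs$split[idx] <- "train"
    seqs$split[test] <- "test"
  }
  seqs
}

#' Build a balanced labeled dataset from positives
#'
#' The benchmark construction recipe: redundancy-filter the positives,
#' generate one dinucleotide-shuffled negative per surviving positive, and
#' split train/test stratified by class. Provenance (seed, threshold,
#' fraction, order of operations) is recorded as an attribute.
#'
#' @param positives sequence data.frame of positive (leccDNA) sequences.
#' @param seed master seed.
#' @param similarity_threshold redundancy threshold (default 0.6).
#' @param test_fraction held-out fraction (default 0.2).
#' @param filter logical; apply the redundancy filter (default TRUE).
#' @return labeled, split sequence data.frame with attribute `"provenance"`.
#' @export
build_dataset <- function(positives, seed, similarity_threshold = 0.6,
                          test_fraction = 0.2, filter = TRUE) {
  validate_seqs(positives)
  pos <- positives
  if (filter) pos <- redundancy_filter(pos, similarity_threshold)
  pos$label <- 1L
  neg <- generate_negatives(pos, seed)
  ds <- rbind(pos[, c("id", "seq", "label")], neg[, c("id", "seq", "label")])
  ds <- split_train_test(ds, test_fraction, seed)
  attr(ds, "provenance") <- list(
    seed = seed, similarity_threshold = if (filter) similarity_threshold else NA,
    test_fraction = test_fraction,
    order = "filter -> shuffle-negatives -> split")
  ds
}

#' Write a dataset manifest
#'
#' @param dataset labeled/split sequence data.frame.
#' @param path output TSV path (columns id, label, split, length).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  man <- data.frame(id = dataset$id, label = dataset$label,
                    split = if ("split" %in% names(dataset)) dataset$split
                            else NA_character_,
                    length = nchar(dataset$seq))
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
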