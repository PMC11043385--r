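# Independent brute-force oracles, written as naive loops straight from the
# encoder definitions. They deliberately share no code with the package
# implementation (beyond the packaged property fixture, which is the
# definition of the property values themselves).

ORACLE_NUCS <- c("A", "C", "G", "T")

oracle_kmers <- function(k) {
  words <- ORACLE_NUCS
  if (k > 1) for (i in 2:k) {
    words <- unlist(lapply(words, function(w) paste0(w, ORACLE_NUCS)))
  }
  sort(words)
}

rand_seq <- function(L, alphabet = ORACLE_NUCS) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

oracle_kmer_comp <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  words <- oracle_kmers(k)
  cnt <- stats::setNames(numeric(length(words)), words)
  total <- 0
  for (i in seq_len(length(ch) - k + 1)) {
    w <- paste(ch[i:(i + k - 1)], collapse = "")
    if (w %in% words) {
      cnt[w] <- cnt[w] + 1
      total <- total + 1
    }
  }
  cnt / total
}

oracle_enac <- function(s, W) {
  ch <- strsplit(s, "")[[1]]
  out <- numeric(0)
  for (start in seq_len(length(ch) - W + 1)) {
    win <- ch[start:(start + W - 1)]
    for (nt in ORACLE_NUCS) out <- c(out, sum(win == nt))
  }
  out
}

oracle_positional <- function(s, scheme) {
  ch <- strsplit(s, "")[[1]]
  onehot <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                 G = c(0, 0, 1, 0), T = c(0, 0, 0, 1))
  ncp <- list(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), T = c(0, 0, 1))
  ei <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  out <- numeric(0)
  for (i in seq_along(ch)) {
    nt <- ch[i]
    known <- nt %in% ORACLE_NUCS
    block <- switch(scheme,
      binary = if (known) onehot[[nt]] else rep(0, 4),
      NCP = if (known) ncp[[nt]] else rep(0, 3),
      EIIP = if (known) ei[[nt]] else 0,
      ANF = if (known) {
        c(ncp[[nt]], sum(ch[1:i] == nt) / i)
      } else rep(0, 4))
    out <- c(out, block)
  }
  out
}

oracle_cksnap <- function(s, G) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  dimers <- oracle_kmers(2)
  out <- numeric(0)
  for (g in 0:G) {
    cnt <- stats::setNames(numeric(16), dimers)
    total <- 0
    for (i in seq_len(L - g - 1)) {
      a <- ch[i]; b <- ch[i + g + 1]
      if (a %in% ORACLE_NUCS && b %in% ORACLE_NUCS) {
        cnt[paste0(a, b)] <- cnt[paste0(a, b)] + 1
        total <- total + 1
      }
    }
    out <- c(out, cnt / total)
  }
  out
}

oracle_pseeiip <- function(s) {
  ei <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  f <- oracle_kmer_comp(s, 3)
  out <- numeric(64)
  trimers <- oracle_kmers(3)
  for (t in seq_along(trimers)) {
    parts <- strsplit(trimers[t], "")[[1]]
    out[t] <- (ei[[parts[1]]] + ei[[parts[2]]] + ei[[parts[3]]]) * f[[t]]
  }
  out
}

# lag-j correlation factors, mean over properties of squared differences
oracle_theta <- function(s, lambda, props) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  th <- numeric(lambda)
  for (j in seq_len(lambda)) {
    vals <- c()
    for (i in seq_len(L - 1 - j)) {
      d1 <- paste0(ch[i], ch[i + 1]); d2 <- paste0(ch[i + j], ch[i + j + 1])
      vals <- c(vals, mean((props[d1, ] - props[d2, ])^2))
    }
    th[j] <- mean(vals)
  }
  th
}

oracle_pseknc <- function(s, k, lambda, w, props) {
  f <- oracle_kmer_comp(s, k)
  th <- oracle_theta(s, lambda, props)
  c(f, w * th) / (1 + w * sum(th))
}

oracle_scpsednc <- function(s, lambda, w, props) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  f <- oracle_kmer_comp(s, 2)
  th <- c()
  for (j in seq_len(lambda)) {
    for (p in seq_len(ncol(props))) {
      vals <- c()
      for (i in seq_len(L - 1 - j)) {
        d1 <- paste0(ch[i], ch[i + 1]); d2 <- paste0(ch[i + j], ch[i + j + 1])
        vals <- c(vals, (props[d1, p] - props[d2, p])^2)
      }
      th <- c(th, mean(vals))
    }
  }
  c(f, w * th) / (1 + w * sum(th))
}

# every distinct permutation of s with the same overlapping-dimer multiset
brute_dimer_preserving <- function(s) {
  ch <- strsplit(s, "")[[1]]
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  dimer_multiset <- function(x) sort(paste0(x[-length(x)], x[-1]))
  target <- dimer_multiset(ch)
  hits <- vapply(perms(ch), function(p) {
    identical(dimer_multiset(p), target)
  }, TRUE)
  unique(vapply(perms(ch)[hits], paste, "", collapse = ""))
}

# Mann-Whitney U / (P*N), ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- 0
  for (p in pos) for (n in neg) {
    u <- u + (p > n) + 0.5 * (p == n)
  }
  u / (length(pos) * length(neg))
}

oracle_props <- function() leccdna::dinucleotide_properties()
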