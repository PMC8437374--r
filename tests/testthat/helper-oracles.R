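# Independent brute-force oracles used to freeze expected values.

# Kendall tau-b by exhaustive pair counting with tie correction
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# AUC by exhaustive pairwise comparison
auc_bruteforce <- function(scores, labels, caseLevel) {
  cases <- scores[labels == caseLevel]
  controls <- scores[labels != caseLevel]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# pseudo-F for a labelled distance matrix (direct formula, no permutation)
pseudo_f <- function(D, labels) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  f <- as.factor(labels)
  a <- nlevels(f)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (l in levels(f)) {
    ix <- which(f == l)
    ssw <- ssw + sum(D2[ix, ix]) / (2 * length(ix))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# exhaustive two-group PERMANOVA p over all balanced assignments
permanova_exhaustive_p <- function(D, labels) {
  f <- as.factor(labels)
  n <- length(f)
  k <- sum(f == levels(f)[1])
  fObs <- pseudo_f(D, f)
  combs <- utils::combn(n, k)
  fs <- apply(combs, 2, function(ix) {
    lab <- rep(levels(f)[2], n)
    lab[ix] <- levels(f)[1]
    pseudo_f(D, lab)
  })
  mean(fs >= fObs - 1e-12)
}

# random small abundance fixture
random_table <- function(p, n, seed, zero_frac = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(p * n, 20) * rbinom(p * n, 1, 1 - zero_frac), p, n)
    dimnames(m) <- list(sprintf("t%02d", seq_len(p)), sprintf("s%02d", seq_len(n)))
    storage.mode(m) <- "integer"
    m
  })
}
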