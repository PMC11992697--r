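# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# Savitzky-Golay by explicit per-window Vandermonde least squares,
# evaluating the first/last full window's polynomial at the edges.
sg_oracle <- function(x, window, degree) {
  n <- length(x)
  if (n < window) return(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - h), n - window + 1L)
    hi <- lo + window - 1L
    V <- outer(lo:hi, 0:degree, `^`)
    beta <- qr.solve(V, x[lo:hi])
    out[i] <- sum(beta * i^(0:degree))
  }
  out
}

# maximal runs of TRUE by linear scan, then length filter
runs_oracle <- function(flags, min_len) {
  segs <- list()
  start <- NA_integer_
  for (i in seq_along(flags)) {
    if (flags[i] && is.na(start)) start <- i
    if ((!flags[i] || i == length(flags)) && !is.na(start)) {
      end <- if (flags[i]) i else i - 1L
      if (end - start + 1L >= min_len) {
        segs[[length(segs) + 1L]] <- c(start, end)
      }
      start <- NA_integer_
    }
  }
  if (!length(segs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, segs)
}

# AUC as the fraction of (pathogenic, benign) pairs correctly ordered,
# ties counted one half
auc_pair_oracle <- function(scores, labels) {
  sp <- scores[labels == "PATHOGENIC"]
  sb <- scores[labels == "BENIGN"]
  tot <- 0
  for (p in sp) for (b in sb) tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(sp) * length(sb))
}

# exact one-sided ("greater") rank-sum p-value by full enumeration of all
# C(n+m, n) rank assignments (tie-free inputs)
wilcox_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(seq_len(n + m)[combos], nrow = n)) - n * (n + 1) / 2
  mean(u_all >= u_obs)
}

# Pearson chi-square by direct formula, with adjusted standardized residuals
chisq_oracle <- function(obs) {
  tot <- sum(obs)
  E <- outer(rowSums(obs), colSums(obs)) / tot
  stat <- sum((obs - E)^2 / E)
  dof <- (nrow(obs) - 1) * (ncol(obs) - 1)
  rp <- rowSums(obs) / tot
  cp <- colSums(obs) / tot
  res <- (obs - E) / sqrt(E * outer(1 - rp, 1 - cp))
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       std_residuals = res)
}
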