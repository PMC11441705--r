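# Independent brute-force oracles. Each recomputes a quantity from first
# principles, by direct enumeration or elementwise loops, never through the
# code path it is used to check.

# two-sided Fisher exact p by full hypergeometric enumeration over the
# support, summing probabilities <= that of the observed table (ties kept)
oracle_fisher_two_sided <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(k)
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)), numeric(1))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square by direct sum((O - E)^2 / E)
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1),
       p_value = pchisq(stat, (nrow(m) - 1) * (ncol(m) - 1),
                        lower.tail = FALSE))
}

# hand product-limit estimator: loop over distinct times, events before
# censorings at the same time
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# two-group log-rank by observed-minus-expected tabulation with the
# hypergeometric variance at each distinct event time
oracle_logrank <- function(times_a, events_a, times_b, events_b) {
  t_all <- c(times_a, times_b)
  e_all <- c(events_a, events_b)
  g <- rep(c(0, 1), c(length(times_a), length(times_b)))
  ut <- sort(unique(t_all[e_all == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n1 <- sum(times_a >= t)
    n2 <- sum(times_b >= t)
    n <- n1 + n2
    d <- sum(t_all == t & e_all == 1)
    d1 <- sum(times_a == t & events_a == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# karyotype scores by elementwise loops
oracle_aneuploidy <- function(mat) {
  w <- mat$bins$width
  per <- numeric(ncol(mat$calls))
  for (j in seq_len(ncol(mat$calls))) {
    num <- 0
    for (b in seq_len(nrow(mat$calls)))
      num <- num + w[b] * abs(mat$calls[b, j] - mat$expected_ploidy[b])
    per[j] <- num / sum(w)
  }
  list(per_library = per, sample = mean(per))
}

oracle_heterogeneity <- function(mat) {
  n <- ncol(mat$calls)
  w <- mat$bins$width
  bin_scores <- numeric(nrow(mat$calls))
  for (b in seq_len(nrow(mat$calls))) {
    disc <- 0; tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + 1
      if (mat$calls[b, i] != mat$calls[b, j]) disc <- disc + 1
    }
    bin_scores[b] <- disc / tot
  }
  sum(bin_scores * w) / sum(w)
}

oracle_concordance <- function(a, b, w) {
  num <- 0
  for (i in seq_along(a)) if (a[i] == b[i]) num <- num + w[i]
  num / sum(w)
}

oracle_depth_keep <- function(mat, thr) {
  keep <- logical(ncol(mat$calls))
  for (j in seq_len(ncol(mat$calls))) {
    tot <- sum(mat$calls[, j])
    keep[j] <- tot > 0 && mat$read_totals[j] / tot >= thr
  }
  keep
}

# exhaustive depth-1 Gini split (independent loop formulation)
oracle_gini_split <- function(values, outcomes) {
  u <- sort(unique(values))
  best_thr <- NA_real_; best_imp <- Inf
  for (i in seq_len(length(u) - 1)) {
    thr <- (u[i] + u[i + 1]) / 2
    imp <- 0
    for (side in c(TRUE, FALSE)) {
      y <- outcomes[(values <= thr) == side]
      if (length(y) > 0) {
        p <- sum(y) / length(y)
        imp <- imp + length(y) * 2 * p * (1 - p)
      }
    }
    imp <- imp / length(values)
    if (imp < best_imp - 1e-12) {
      best_imp <- imp; best_thr <- thr
    }
  }
  list(threshold = best_thr, impurity = best_imp)
}

# grayscale reconstruction by naive iterated vectorized dilation (8-conn),
# independent of the compiled path
oracle_reconstruct <- function(marker, mask) {
  rec <- pmin(marker, mask)
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    d <- rec
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) d <- pmax(d, shift(rec, dr, dc))
    nxt <- pmin(d, mask)
    if (identical(nxt, rec)) return(rec)
    rec <- nxt
  }
}

# random small copy-number matrix for the score oracles
random_cn_matrix <- function(n_libs, n_bins, with_reads = FALSE) {
  w <- sample(2e5:2e6, n_bins, replace = TRUE)
  start <- c(0, cumsum(w))[seq_len(n_bins)]
  bins <- data.frame(chrom = "chr1", start = start, end = start + w)
  calls <- matrix(sample(0:6, n_libs * n_bins, replace = TRUE,
                         prob = c(.02, .08, .6, .2, .06, .02, .02)),
                  nrow = n_bins)
  rt <- NULL
  if (with_reads) {
    colnames(calls) <- paste0("lib", seq_len(n_libs))
    rt <- setNames(sample(1000:100000, n_libs), colnames(calls))
  }
  cn_matrix(bins, calls, read_totals = rt)
}
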