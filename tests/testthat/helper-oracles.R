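# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementations.

# KS enrichment via an explicit sweep over every rank position r = 1..n,
# comparing the in-set empirical CDF against the uniform CDF.
es_oracle <- function(ranks_in_set, n) {
  V <- sort(ranks_in_set)
  t <- length(V)
  a <- -Inf; b <- -Inf
  for (r in seq_len(n)) {
    F_at <- sum(V <= r) / t        # in-set CDF at r
    F_before <- sum(V < r) / t     # in-set CDF just below r
    a <- max(a, F_at - r / n)
    b <- max(b, r / n - F_before)
  }
  list(a = a, b = b, es = if (a > b) a else -b)
}

# Naive elementwise regression metrics.
metrics_oracle <- function(y, yhat) {
  n <- length(y)
  mae <- 0; mre <- 0; mse <- 0; sstot <- 0
  ybar <- sum(y) / n
  for (i in seq_len(n)) {
    mae <- mae + abs(y[i] - yhat[i]) / n
    mre <- mre + abs(y[i] - yhat[i]) / abs(y[i]) / n
    mse <- mse + (y[i] - yhat[i])^2 / n
    sstot <- sstot + (y[i] - ybar)^2
  }
  list(MAE = mae, MRE = mre, MSE = mse, RMSE = sqrt(mse),
       R2 = 1 - n * mse / sstot)
}

# Tree-walk expectation of a generic tree list given a feature subset S:
# splits on features in S follow the instance, others average children by
# cover fractions.
tree_walk_value <- function(trees, x, S) {
  walk <- function(tr, node) {
    f <- tr$feature[node]
    if (f < 0) return(tr$value[node])
    if ((f + 1) %in% S) {
      goes_left <- if (tr$cmp == 1) x[f + 1] <= tr$threshold[node]
                   else x[f + 1] < tr$threshold[node]
      walk(tr, (if (goes_left) tr$left[node] else tr$right[node]) + 1)
    } else {
      wl <- tr$cover[tr$left[node] + 1] / tr$cover[node]
      wl * walk(tr, tr$left[node] + 1) +
        (1 - wl) * walk(tr, tr$right[node] + 1)
    }
  }
  sum(vapply(trees, walk, numeric(1), node = 1))
}

# Exhaustive Shapley values over all 2^p subsets (p small).
shapley_exhaustive <- function(vfun, p) {
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (m in 0:(2^(p - 1) - 1)) {
      S <- others[as.logical(bitwAnd(m, 2^(seq_len(p - 1) - 1)))]
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + w * (vfun(c(S, i)) - vfun(S))
    }
  }
  phi
}

# Ordinary pooled-variance two-sample t (brute force, single gene).
ordinary_t_oracle <- function(case, ctrl) {
  n1 <- length(case); n2 <- length(ctrl)
  sp2 <- (sum((case - mean(case))^2) + sum((ctrl - mean(ctrl))^2)) / (n1 + n2 - 2)
  (mean(case) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
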