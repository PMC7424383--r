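# Independent oracles, deliberately brute-force and separate from the
# package's code paths.

# P(|subset of size n| shares >= k elements with marked set 1..K) by
# exhaustive enumeration of all C(N, n) draws.
enum_overlap_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked set
  mean(hits >= k)
}

# Product-limit estimator built literally from the risk table.
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# Two-group log-rank built literally from the O - E / V risk table.
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  chi <- (O1 - E1)^2 / V
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Helper to build a SurvivalSplit directly from group labels.
split_from_groups <- function(ids, groups) {
  structure(list(
    group = stats::setNames(factor(groups, levels = c("low", "high")), ids),
    split_value = NA_real_), class = "SurvivalSplit")
}
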