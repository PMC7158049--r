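# Shared fixtures, generated in code.

# small phantom used by several files
tiny_phantom <- function(seed = 7, low = 0.3, grid = c(12, 12, 4),
                         necrosis = 0.05) {
  generate_phantom(phantom_config(grid_shape = grid,
                                  low_region_fraction = low,
                                  necrosis_fraction = necrosis,
                                  seed = seed))
}

# parametric map holding given values on a flat mask
map_from_values <- function(values, voxel_dims = c(0.78, 0.78, 5.0)) {
  n <- length(values)
  arr <- array(NA_real_, c(n, 1, 1))
  arr[, 1, 1] <- values
  parametric_map(arr, array(TRUE, c(n, 1, 1)), voxel_dims, "ktrans")
}

# brute-force AUC by pair counting (independent oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand log-rank statistic: sum over event times of (O1 - E1), variance from
# the hypergeometric distribution (independent of survival::survdiff)
logrank_bruteforce <- function(time, event, group1) {
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Breslow Cox partial log-likelihood for a single covariate (oracle)
cox_pll <- function(beta, time, event, x) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    dead <- event == 1 & time == tt
    ll <- ll + sum(x[dead]) * beta -
      sum(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}
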