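# Independent oracle implementations, deliberately written differently from
# the package code paths they check.

# plug-in entropy by direct table() counting
oracle_entropy <- function(symbols) {
  symbols <- symbols[!is.na(symbols)]
  p <- as.numeric(table(symbols)) / length(symbols)
  -sum(p * log2(p))
}

# transfer entropy by exhaustive triple-loop summation over the joint
# contingency table, evaluating the defining sum
#   sum p(yi, yim1, xl) * log2( p(yi | yim1, xl) / p(yi | yim1) )
oracle_te <- function(xs, ys, lag, bx, by) {
  n <- length(ys)
  i <- (max(lag, 1) + 1):n
  yi <- ys[i]; yim1 <- ys[i - 1]; xl <- xs[i - lag]
  keep <- !(is.na(yi) | is.na(yim1) | is.na(xl))
  yi <- yi[keep]; yim1 <- yim1[keep]; xl <- xl[keep]
  m <- length(yi)
  te <- 0
  for (a in 0:(by - 1)) for (b in 0:(by - 1)) for (cc in 0:(bx - 1)) {
    n_abc <- sum(yi == a & yim1 == b & xl == cc)
    if (n_abc == 0) next
    n_bc <- sum(yim1 == b & xl == cc)
    n_ab <- sum(yi == a & yim1 == b)
    n_b <- sum(yim1 == b)
    p_abc <- n_abc / m
    te <- te + p_abc * log2((n_abc / n_bc) / (n_ab / n_b))
  }
  te
}

# fixed-effect inverse-variance pool by direct weighted-mean arithmetic
oracle_pool <- function(lnr, v) {
  w <- 1 / v
  est <- sum(w * lnr) / sum(w)
  c(est = est, se = sqrt(1 / sum(w)))
}

# nu recomputed with independent arithmetic straight from the run arrays
oracle_nu <- function(perturbed, baseline, depth, window) {
  l <- which(perturbed$site$layer_depths == depth)
  in_win_p <- perturbed$year > window[1] & perturbed$year <= window[2]
  in_win_b <- baseline$year > window[1] & baseline$year <= window[2]
  c_p <- perturbed$soc[max(which(in_win_p)), l]
  c_b <- baseline$soc[max(which(in_win_b)), l]
  dt <- mean(perturbed$soil_temp[in_win_p, l]) -
    mean(baseline$soil_temp[in_win_b, l])
  ((c_p - c_b) / dt) / (window[2] - window[1])
}
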