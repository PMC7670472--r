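#' Discretize a numeric series into symbols
#'
#' The transfer-entropy estimator is a discrete plug-in estimator, so
#' continuous series are first mapped to integer symbols. Two schemes are
#' supported: `"quantile"` (default; rank-based, near-equal bin occupancy,
#' robust to the skewed distributions typical of ecosystem fluxes) and
#' `"uniform"` (equal-width bins spanning the observed range; values that
#' fall on an interior boundary go to the lower bin). Missing values are
#' preserved as `NA` symbols and handled pairwise-complete downstream.
#'
#' @param x Numeric series.
#' @param n_bins Number of bins (>= 2). A constant series under the quantile
#'   scheme falls back to a single bin with a warning.
#' @param method `"quantile"` or `"uniform"`.
#' @param source_var Optional label carried through to network output.
#'
#' @return An object of class `symbol_series`: list with `symbols` (integer
#'   codes in `[0, n_bins)`), `n_bins`, `bin_edges`, `method`, `source_var`.
#' @export
#' @examples
#' s <- discretize(rnorm(1000), n_bins = 8)
#' table(s$symbols)
discretize <- function(x, n_bins = 8,
                       method = c("quantile", "uniform"),
                       source_var = NULL) {
  method <- match.arg(method)
  if (n_bins < 2) stop("discretize: n_bins must be >= 2", call. = FALSE)
  ok <- is.finite(x)
  n_ok <- sum(ok)
  if (n_ok == 0) stop("discretize: no finite values", call. = FALSE)
  xr <- x[ok]
  sym <- rep(NA_integer_, length(x))

  if (method == "quantile") {
    if (diff(range(xr)) == 0) {
      warning("discretize: constant series; falling back to a single bin")
      sym[ok] <- 0L
      return(new_symbol_series(sym, 1L, range(xr), method, source_var))
    }
    r <- rank(xr, ties.method = "average")
    codes <- as.integer(ceiling(r * n_bins / n_ok)) - 1L
    codes <- pmin(pmax(codes, 0L), n_bins - 1L)
    sym[ok] <- codes
    edges <- as.numeric(quantile(xr, probs = seq(0, 1, length.out = n_bins + 1)))
  } else {
    edges <- seq(min(xr), max(xr), length.out = n_bins + 1)
    if (diff(range(xr)) == 0) {
      sym[ok] <- 0L
      return(new_symbol_series(sym, 1L, range(xr), method, source_var))
    }
    # right-closed intervals: boundary values drop to the lower bin
    codes <- as.integer(cut(xr, breaks = edges, include.lowest = TRUE,
                            right = TRUE, labels = FALSE)) - 1L
    sym[ok] <- codes
  }
  new_symbol_series(sym, as.integer(n_bins), edges, method, source_var)
}

new_symbol_series <- function(symbols, n_bins, edges, method, source_var) {
  structure(list(symbols = symbols, n_bins = n_bins, bin_edges = edges,
                 method = method, source_var = source_var),
            class = "symbol_series")
}

#' Wrap an already-discrete integer series
#'
#' @param symbols Integer codes in `[0, n_bins)` (`NA` allowed).
#' @param n_bins Alphabet size; defaults to `max(symbols) + 1`.
#' @rdname discretize
#' @export
symbol_series <- function(symbols, n_bins = max(symbols, na.rm = TRUE) + 1L,
                          source_var = NULL) {
  symbols <- as.integer(symbols)
  stopifnot(all(is.na(symbols) | (symbols >= 0L & symbols < n_bins)))
  new_symbol_series(symbols, as.integer(n_bins),
                    seq(-0.5, n_bins - 0.5, by = 1), "preset", source_var)
}

#' @export
print.symbol_series <- function(x, ...) {
  cat("<symbol_series> n =", length(x$symbols), ", bins =", x$n_bins,
      ", method =", x$method, "\n")
  invisible(x)
}

# entropy (bits) of a count vector, 0 log 0 = 0
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Plug-in Shannon entropy
#'
#' \deqn{H = -\sum_i p(x_i) \log_2 p(x_i)} estimated with empirical symbol
#' frequencies (`0 log 0 = 0`). No small-sample bias correction is applied:
#' the shuffle null downstream carries the same bias, so significance
#' decisions are unaffected.
#'
#' @param s A `symbol_series` (or an integer vector of codes).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(symbol_series(rep(0:3, 25)))  # 2 bits
shannon_entropy <- function(s) {
  if (!inherits(s, "symbol_series")) s <- symbol_series(s)
  sym <- s$symbols[!is.na(s$symbols)]
  if (length(sym) == 0) stop("shannon_entropy: empty series", call. = FALSE)
  entropy_from_counts(tabulate(sym + 1L, nbins = s$n_bins))
}

#' Transfer entropy between two symbol series
#'
#' Estimates the lag-`lag` transfer entropy from `x` to `y`,
#' \deqn{T_{X \to Y} = \sum p(y_i, y_{i-1}, x_{i-j})
#'       \log_2 \frac{p(y_i \mid y_{i-1}, x_{i-j})}{p(y_i \mid y_{i-1})},}
#' the reduction in uncertainty about the present of `y` given the lagged
#' source `x`, beyond what the immediate past of `y` already provides. The
#' plug-in form is a conditional mutual information
#' `I(y_i ; x_{i-j} | y_{i-1})` and is therefore non-negative; it is zero
#' exactly when the empirical conditional distributions factorize.
#'
#' Time steps where any of the three embedded values is missing are dropped
#' (pairwise-complete alignment), so seasonally masked series are handled
#' without fabricating values.
#'
#' @param x,y `symbol_series` objects on a shared time index (source,
#'   target).
#' @param lag Source lag `j >= 1` in time steps.
#' @param min_length Minimum number of complete embedded samples; defaults to
#'   `10 * max(n_bins)^2`. An error is raised below it (the estimate would be
#'   dominated by small-sample bias).
#' @return Transfer entropy in bits, with attribute `n_eff` (the number of
#'   complete embedded samples used).
#' @export
transfer_entropy <- function(x, y, lag = 1, min_length = NULL) {
  stopifnot(inherits(x, "symbol_series"), inherits(y, "symbol_series"))
  if (lag < 1) stop("transfer_entropy: lag must be >= 1", call. = FALSE)
  if (length(x$symbols) != length(y$symbols))
    stop("transfer_entropy: series must share a time index", call. = FALSE)
  if (is.null(min_length)) min_length <- 10 * max(x$n_bins, y$n_bins)^2

  emb <- te_embed(x$symbols, y$symbols, lag)
  n_eff <- length(emb$yi)
  if (n_eff < min_length)
    stop("transfer_entropy: only ", n_eff, " complete samples after lag ",
         "embedding; at least ", min_length, " required", call. = FALSE)
  te <- te_from_embedding(emb$yi, emb$yim1, emb$xl, y$n_bins, x$n_bins)
  structure(te, n_eff = n_eff)
}

te_embed <- function(xs, ys, lag) {
  n <- length(ys)
  start <- max(lag, 1L) + 1L
  if (start > n) stop("transfer_entropy: series shorter than lag", call. = FALSE)
  i <- start:n
  yi <- ys[i]
  yim1 <- ys[i - 1L]
  xl <- xs[i - lag]
  keep <- !(is.na(yi) | is.na(yim1) | is.na(xl))
  list(yi = yi[keep], yim1 = yim1[keep], xl = xl[keep])
}

# plug-in conditional mutual information I(yi ; xl | yim1) via the entropy
# identity H(yi,yim1) + H(yim1,xl) - H(yim1) - H(yi,yim1,xl)
te_from_embedding <- function(yi, yim1, xl, by, bx) {
  h_ab  <- entropy_from_counts(tabulate(1L + yi + by * yim1, nbins = by * by))
  h_bc  <- entropy_from_counts(tabulate(1L + yim1 + by * xl, nbins = by * bx))
  h_b   <- entropy_from_counts(tabulate(1L + yim1, nbins = by))
  h_abc <- entropy_from_counts(
    tabulate(1L + yi + by * yim1 + by * by * xl, nbins = by * by * bx))
  max(h_ab + h_bc - h_b - h_abc, 0)
}

#' Shuffle-null significance threshold for transfer entropy
#'
#' The significance threshold is obtained by randomly permuting the source
#' series (destroying any lagged dependency while keeping its marginal
#' distribution), recomputing the transfer entropy for each permutation, and
#' taking the `q` quantile of the shuffled values. Only the source is
#' permuted; the target and its own history are left intact so the
#' conditioning structure of the statistic is preserved.
#'
#' @inheritParams transfer_entropy
#' @param n_shuffles Number of permutations (>= 20).
#' @param q Null quantile in (0, 1) (default 0.95).
#' @param seed Integer seed; the threshold is deterministic given it.
#' @return Threshold in bits, with attribute `null_te` (the vector of
#'   shuffled TE values).
#' @export
shuffle_threshold <- function(x, y, lag = 1, n_shuffles = 100, q = 0.95,
                              seed = 1L, min_length = NULL) {
  stopifnot(n_shuffles >= 20, q > 0, q < 1)
  # run once to validate inputs and fix min_length semantics
  invisible(transfer_entropy(x, y, lag, min_length = min_length))
  null_te <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      xs <- x
      xs$symbols <- sample(x$symbols)
      as.numeric(transfer_entropy(xs, y, lag, min_length = min_length))
    }, numeric(1))
  })
  structure(as.numeric(quantile(null_te, probs = q)), null_te = null_te)
}

#' Transfer-entropy significance test for one directed pair
#'
#' Convenience wrapper combining [transfer_entropy()] and
#' [shuffle_threshold()] at a single lag.
#'
#' @inheritParams shuffle_threshold
#' @return A one-row tibble: `te`, `lag`, `threshold`, `significant`,
#'   `n_shuffles`, `n_eff`.
#' @export
te_test <- function(x, y, lag = 1, n_shuffles = 100, q = 0.95, seed = 1L,
                    min_length = NULL) {
  te <- transfer_entropy(x, y, lag, min_length = min_length)
  thr <- shuffle_threshold(x, y, lag, n_shuffles = n_shuffles, q = q,
                           seed = seed, min_length = min_length)
  n_eff <- attr(te, "n_eff")
  tibble::tibble(te = as.numeric(te), lag = lag,
                 threshold = as.numeric(thr),
                 significant = te > as.numeric(thr),
                 n_shuffles = n_shuffles, n_eff = n_eff)
}
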