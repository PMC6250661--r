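#' Spearman rank correlation
#'
#' Thin wrapper over `stats::cor(method = "spearman")` (average ranks for
#' ties) that reports zero-variance inputs as `NA` instead of warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in `[-1, 1]`, or `NA` when either input has zero variance.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# average ranks of each row of an integer matrix, via pairwise comparisons
# (vectorized over rows; intended for small column counts)
row_ranks <- function(X) {
  k <- ncol(X)
  R <- matrix(1, nrow(X), k)
  for (j in seq_len(k)) {
    less <- 0; eq <- 0
    for (l in seq_len(k)) {
      if (l == j) next
      less <- less + (X[, l] < X[, j])
      eq <- eq + (X[, l] == X[, j])
    }
    R[, j] <- 1 + less + eq / 2
  }
  R
}

#' Randomization test: knockout pleiotropy vs. number of pleiotropy steps
#'
#' The full-knockout pleiotropy of a gene bounds its number of stepwise
#' pleiotropy increases from above. Under the null hypothesis that, apart
#' from this bound, steps are unrelated to knockout pleiotropy, each
#' gene's step count is uniform on the integers `{0, ..., max pleiotropy}`.
#' The test draws `n_rand` such datasets (same maximal pleiotropies),
#' computes the Spearman correlation between knockout pleiotropy and steps
#' for each, and reports the empirical p-value
#' `(1 + #(rho_null >= rho_obs)) / (1 + n_rand)`.
#'
#' Null draws with zero step variance have undefined correlation and are
#' counted as not exceeding the observed value.
#'
#' @param max_pleiotropy per-gene full-knockout pleiotropy counts.
#' @param steps per-gene step counts (each `<= max_pleiotropy`).
#' @param n_rand number of randomizations (the headline analysis uses
#'   `1e6`).
#' @param seed RNG seed.
#' @param include_zero keep genes with `max_pleiotropy == 0`? They force
#'   ties at zero in both variables and are excluded by default.
#' @param chunk rows per block in the vectorized null computation (memory
#'   knob). Results are reproducible for a fixed `seed` and `chunk`;
#'   changing `chunk` consumes the RNG stream in a different order and
#'   yields a different — equally valid — Monte Carlo estimate.
#' @return object of class `step_test`: list with `rho` (observed),
#'   `p`, `n_rand`, `n_genes`, `null_mean`, `null_sd`, `n_exceed`.
#' @export
step_randomization_test <- function(max_pleiotropy, steps, n_rand = 1e6,
                                    seed = NULL, include_zero = FALSE,
                                    chunk = 1e5) {
  stopifnot(length(max_pleiotropy) == length(steps))
  bad <- which(steps > max_pleiotropy)
  if (length(bad))
    stop("step count exceeds maximal pleiotropy for entries: ",
         paste(bad, collapse = ", "))
  if (!include_zero) {
    keep <- max_pleiotropy > 0
    max_pleiotropy <- max_pleiotropy[keep]
    steps <- steps[keep]
  }
  k <- length(max_pleiotropy)
  if (k < 3) stop("need at least 3 genes with positive maximal pleiotropy")
  if (!is.null(seed)) set.seed(seed)

  rho_obs <- spearman_rho(max_pleiotropy, steps)
  if (is.na(rho_obs))
    stop("observed correlation undefined (zero variance)")

  rx <- rank(max_pleiotropy)
  mx <- mean(rx); vx <- mean(rx^2) - mx^2
  mean_r <- (k + 1) / 2

  n_exceed <- 0L; n_def <- 0L
  s1 <- 0; s2 <- 0  # running sums for null mean/sd
  done <- 0
  while (done < n_rand) {
    nb <- min(chunk, n_rand - done)
    X <- vapply(max_pleiotropy, function(mp)
      sample.int(mp + 1L, nb, replace = TRUE) - 1L,
      integer(nb))
    if (nb == 1L) X <- matrix(X, nrow = 1)
    R <- row_ranks(X)
    vy <- rowMeans(R^2) - mean_r^2
    covxy <- as.numeric(R %*% rx) / k - mx * mean_r
    rho <- ifelse(vy > 0, covxy / sqrt(vx * vy), NA_real_)
    def <- !is.na(rho)
    n_def <- n_def + sum(def)
    n_exceed <- n_exceed + sum(rho[def] >= rho_obs - 1e-12)
    s1 <- s1 + sum(rho[def]); s2 <- s2 + sum(rho[def]^2)
    done <- done + nb
  }

  p <- (1 + n_exceed) / (1 + n_rand)
  structure(list(rho = rho_obs, p = p, n_rand = n_rand, n_genes = k,
                 null_mean = s1 / n_def,
                 null_sd = sqrt(pmax(s2 / n_def - (s1 / n_def)^2, 0)),
                 n_exceed = n_exceed),
            class = "step_test")
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf("<step_test: rho = %.4f over %d genes, empirical p = %.3g (%g randomizations)>\n",
              x$rho, x$n_genes, x$p, x$n_rand))
  invisible(x)
}
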