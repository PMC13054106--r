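#' Per-draw heritabilities and correlations
#'
#' Transforms each retained `(G0, R0)` draw into the derived genetic
#' parameters, computed within the draw and only then averaged (mean of
#' ratios, the usual Bayesian practice): heritability
#' `h2_i = g_ii / (g_ii + r_ii)`, additive genetic correlations
#' `rg_ij = g_ij / sqrt(g_ii g_jj)` and residual correlations analogously.
#' Draws with a non-positive variance element are excluded with a message
#' reporting the count.
#'
#' @param samples a `btlam_samples` (or its `draws` matrix).
#' @return data frame of per-draw derived parameters, attribute
#'   `"n_excluded"` giving the number of dropped draws.
#' @export
derive_parameters <- function(samples) {
  d <- if (is.matrix(samples)) samples else samples$draws
  stopifnot(nrow(d) >= 1L)
  g <- d[, 1:6, drop = FALSE]
  r <- d[, 7:12, drop = FALSE]
  # vech order: 11, 12, 13, 22, 23, 33
  gv <- g[, c(1, 4, 6), drop = FALSE]
  rv <- r[, c(1, 4, 6), drop = FALSE]
  ok <- rowSums(gv <= 0) == 0 & rowSums(rv <= 0) == 0
  if (any(!ok)) {
    message(sum(!ok), " draw(s) with non-positive variance excluded")
    g <- g[ok, , drop = FALSE]; r <- r[ok, , drop = FALSE]
    gv <- gv[ok, , drop = FALSE]; rv <- rv[ok, , drop = FALSE]
  }
  out <- data.frame(
    h2_ww = gv[, 1] / (gv[, 1] + rv[, 1]),
    h2_wy = gv[, 2] / (gv[, 2] + rv[, 2]),
    h2_ac = gv[, 3] / (gv[, 3] + rv[, 3]),
    rg_ww_wy = g[, 2] / sqrt(gv[, 1] * gv[, 2]),
    rg_ww_ac = g[, 3] / sqrt(gv[, 1] * gv[, 3]),
    rg_wy_ac = g[, 5] / sqrt(gv[, 2] * gv[, 3]),
    re_ww_wy = r[, 2] / sqrt(rv[, 1] * rv[, 2]),
    re_ww_ac = r[, 3] / sqrt(rv[, 1] * rv[, 3]),
    re_wy_ac = r[, 5] / sqrt(rv[, 2] * rv[, 3]))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Effective sample size of an MCMC chain
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' by the initial-positive-sequence rule: consecutive pair sums
#' `rho_{2m} + rho_{2m+1}` are accumulated while they remain positive. A
#' zero-variance (constant) chain short-circuits to `ESS = n`.
#'
#' @param x numeric chain (length >= 10).
#' @param max_lag largest autocorrelation lag examined.
#' @return effective sample size (not capped at `n`).
#' @export
effective_sample_size <- function(x, max_lag = 1000L) {
  n <- length(x)
  stopifnot(n >= 10L)
  if (var(x) == 0) return(as.numeric(n))
  L <- min(n - 1L, max_lag)
  rho <- c(1, drop(stats::acf(x, lag.max = L, plot = FALSE,
                              demean = TRUE)$acf)[-1L])
  tau <- 0
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    gam <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1L
  }
  tau <- max(tau - 1, .Machine$double.eps)   # = 1 + 2*sum(rho_1..rho_K)
  n / tau
}

# lag-window (modified Bartlett) estimate of the spectral density at zero,
# i.e. the large-sample variance of the chain mean times n
spectrum0 <- function(x) {
  n <- length(x)
  L <- max(1L, floor(n^(1 / 3)))
  g <- drop(stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                       demean = TRUE)$acf)
  w <- 1 - seq_len(L) / (L + 1)
  max(g[1L] + 2 * sum(w * g[-1L]), .Machine$double.eps)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of the chain with the mean of a
#' late segment via `z = (m1 - m2) / sqrt(s1/n1 + s2/n2)`, the segment
#' variances `s` being lag-window estimates of the spectral density at zero
#' (so autocorrelation is accounted for). Under stationarity `z` is
#' standard normal; the two-sided p-value tests it.
#'
#' @param x numeric chain, length >= 100.
#' @param first_frac,last_frac fractions of the chain forming the early and
#'   late segments (defaults 0.1 and 0.5).
#' @return named vector `c(z, p)`.
#' @export
geweke <- function(x, first_frac = 0.1, last_frac = 0.5) {
  n <- length(x)
  if (n < 100L) stop("chain too short for the Geweke diagnostic (need >= 100)")
  n1 <- floor(first_frac * n)
  n2 <- floor(last_frac * n)
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(n - n2 + 1L, n)]
  if (var(x1) == 0 && var(x2) == 0) return(c(z = 0, p = 1))
  z <- (mean(x1) - mean(x2)) / sqrt(spectrum0(x1) / n1 + spectrum0(x2) / n2)
  c(z = z, p = 2 * pnorm(-abs(z)))
}

#' Posterior summary of one or more chains of draws
#'
#' Per quantity: posterior mean, SD (`n - 1` denominator), equal-tailed 95%
#' credible interval from the empirical 2.5th and 97.5th percentiles
#' (type-7 linear interpolation, R's default), Monte Carlo error
#' `SD / sqrt(ESS)`, effective sample size, and the Geweke z and p. ESS and
#' Geweke consume the chain order; the remaining summaries are
#' permutation-invariant.
#'
#' @param draws numeric vector, or a matrix/data frame with one column per
#'   quantity (rows in chain order).
#' @param prob credible-interval mass (default 0.95).
#' @return data frame with one row per quantity.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  if (is.vector(draws) && is.numeric(draws)) draws <- cbind(draw = draws)
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("no draws to summarise")
  if (nrow(draws) < 30L) warning("fewer than 30 draws: percentiles unstable")
  alpha <- (1 - prob) / 2
  one <- function(x) {
    ess <- if (length(x) >= 10L) effective_sample_size(x) else NA_real_
    gw <- if (length(x) >= 100L) geweke(x) else c(z = NA_real_, p = NA_real_)
    ci <- quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(mean = mean(x), sd = sd(x), lower = ci[1L], upper = ci[2L],
               mc_error = sd(x) / sqrt(ess), ess = ess,
               geweke_z = gw[["z"]], geweke_p = gw[["p"]])
  }
  out <- do.call(rbind, lapply(seq_len(ncol(draws)),
                               function(j) one(draws[, j])))
  out <- cbind(data.frame(parameter = colnames(draws)), out)
  rownames(out) <- NULL
  out
}

#' Summary tables of a fitted chain
#'
#' Convenience wrapper producing the two standard reports: the (co)variance
#' component summary and the derived-parameter (heritability / correlation)
#' summary.
#'
#' @param samples a `btlam_samples`.
#' @return list with data frames `components` and `parameters`.
#' @export
posterior_tables <- function(samples) {
  list(components = summarize_draws(samples$draws[, 1:12, drop = FALSE]),
       parameters = summarize_draws(derive_parameters(samples)))
}

#' Write posterior summaries as delimited text and JSON
#' @param tables result of [posterior_tables()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_posterior_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(tables$components, file.path(dir, "components.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tables$parameters, file.path(dir, "parameters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tables, file.path(dir, "posterior_summary.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
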