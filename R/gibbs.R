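#' Prior specification for the (co)variance components
#'
#' Inverse-Wishart priors for the additive (`G0`) and residual (`R0`) 3x3
#' covariance matrices, in the convention where `IW(nu, S)` has mean
#' `S / (nu - p - 1)` for a `p x p` matrix, and a vague zero-mean normal
#' prior on every fixed effect.
#'
#' @param nu_g,nu_r inverse-Wishart degrees of freedom; must exceed
#'   `p + 1 = 4` for a proper prior with finite mean.
#' @param S_g,S_r symmetric positive-definite 3x3 scale matrices.
#' @param beta_var fixed-effect prior variance (default 1e8): a proper but
#'   effectively flat normal, keeping every full conditional proper.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(nu_g = 5, S_g, nu_r = 5, S_r, beta_var = 1e8) {
  check_pd <- function(S, nm) {
    if (!isSymmetric(unname(S)) || any(eigen(S, symmetric = TRUE,
                                             only.values = TRUE)$values <= 0))
      stop(nm, " must be symmetric positive definite")
  }
  stopifnot(nu_g >= 4, nu_r >= 4)
  check_pd(S_g, "S_g"); check_pd(S_r, "S_r")
  structure(list(nu_g = nu_g, S_g = unname(as.matrix(S_g)),
                 nu_r = nu_r, S_r = unname(as.matrix(S_r)),
                 beta_var = beta_var),
            class = "prior_spec")
}

#' Default diffuse priors derived from the data
#'
#' Degrees of freedom `traits + 2 = 5` and scale matrices set to the
#' diagonal of half the sample phenotypic variances, with 0.5 in the
#' liability slot (whose phenotypic variance is not observable). With
#' `nu = 5` the prior mean equals the scale matrix and carries the weight of
#' roughly one observation.
#'
#' @param design a `btlam_design`.
#' @return a [prior_spec].
#' @export
default_priors <- function(design) {
  v_ww <- var(design$y[, 1L], na.rm = TRUE)
  v_wy <- var(design$y[, 2L], na.rm = TRUE)
  S <- diag(c(if (is.finite(v_ww)) 0.5 * v_ww else 1,
              if (is.finite(v_wy)) 0.5 * v_wy else 1,
              0.5))
  prior_spec(nu_g = 5, S_g = S, nu_r = 5, S_r = S)
}

#' Gibbs chain configuration
#'
#' @param n_cycles total Gibbs cycles.
#' @param burn_in cycles discarded before storage begins.
#' @param thin storage interval; `floor((n_cycles - burn_in) / thin)` draws
#'   are retained.
#' @param seed integer seed; the chain owns all randomness through R's
#'   generator, so a fixed seed makes runs bit-identical.
#' @param store_location accumulate running posterior means of the animal
#'   and fixed effects over retained cycles.
#' @export
chain_config <- function(n_cycles = 20000L, burn_in = 5000L, thin = 10L,
                         seed = 1L, store_location = TRUE) {
  stopifnot(burn_in < n_cycles, thin >= 1L, burn_in >= 0L)
  structure(list(n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 store_location = isTRUE(store_location)),
            class = "chain_config")
}

#' Number of retained draws implied by a chain configuration
#' @param config a [chain_config] (or list with `n_cycles`, `burn_in`, `thin`).
#' @export
n_retained <- function(config) {
  as.integer((config$n_cycles - config$burn_in) %/% config$thin)
}

# inverse-Wishart draw, IW(nu, S) with mean S / (nu - p - 1)
rinvwishart <- function(nu, S) {
  W <- stats::rWishart(1L, df = nu, Sigma = solve(S))[, , 1L]
  V <- solve(W)
  (V + t(V)) / 2
}

#' Initialize the sampler state
#'
#' Location effects start at zero; `G0` and `R0` at the prior scale
#' matrices; liabilities at their category midpoints (class 1 at `t1 - 0.5`,
#' middle classes at interval midpoints, top class at `t_last + 0.5`);
#' missing weights at the observed trait mean.
#'
#' @param design a `btlam_design`.
#' @param priors a [prior_spec].
#' @param seed optional seed set before initialization.
#' @return state list with elements `beta` (per-trait vectors), `a` (q x 3),
#'   `yaug` (augmented complete data), `e` (residuals), `G0`, `R0`,
#'   `thresholds`.
#' @export
init_state <- function(design, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- design$spec$thresholds
  mids <- c(tt[1L] - 0.5,
            if (length(tt) > 1L) (tt[-length(tt)] + tt[-1L]) / 2,
            tt[length(tt)] + 0.5)
  yaug <- design$y
  for (t in 1:2) {
    miss <- is.na(yaug[, t])
    yaug[miss, t] <- if (all(miss)) 0 else mean(yaug[!miss, t])
  }
  u <- rep(0, design$n)
  known <- !is.na(design$ac_class)
  u[known] <- mids[design$ac_class[known]]
  yaug[, 3L] <- u

  state <- list(beta = lapply(design$X, function(Xt) numeric(ncol(Xt))),
                a = matrix(0, design$q, 3L,
                           dimnames = list(design$animal_ids,
                                           design$spec$traits)),
                yaug = yaug, e = NULL,
                G0 = priors$S_g, R0 = priors$S_r,
                thresholds = tt)
  state$e <- yaug - fitted_values(design, state)
  state
}

#' Fitted location values (fixed + animal effects) per record and trait
#' @param design a `btlam_design`.
#' @param state a sampler state.
#' @return n x 3 matrix.
#' @export
fitted_values <- function(design, state) {
  out <- matrix(0, design$n, 3L)
  for (t in 1:3) {
    out[, t] <- design$X[[t]] %*% state$beta[[t]] + state$a[design$zi, t]
  }
  colnames(out) <- design$spec$traits
  out
}

#' Draw the augmented data (liabilities and missing weights)
#'
#' One Gibbs pass over the latent entries: each ordinal record's liability
#' is drawn from its normal full conditional -- location mean plus the
#' regression on the record's observed-trait residuals through `R0` --
#' truncated to the observed category's interval; missing weights are drawn
#' from the same conditional without truncation.
#'
#' @param state sampler state.
#' @param design a `btlam_design`.
#' @return updated state (`yaug` and `e` refreshed).
#' @export
sample_liabilities <- function(state, design) {
  fit <- fitted_values(design, state)
  state$e[] <- state$yaug - fit     # resync: removes incremental drift
  E <- solve(state$R0)
  e_new <- cpp_liability_sweep(state$e, fit,
                               design$latent * 1L, design$lower,
                               design$upper, E)
  state$e <- e_new
  state$yaug[design$latent] <- (fit + e_new)[design$latent]
  state
}

#' Draw all location parameters (fixed and animal effects)
#'
#' Single-site Gauss-Seidel scan: every scalar element of the fixed effects
#' (trait by trait) and then of the breeding values (pedigree order, traits
#' innermost) is replaced by a draw from its normal full conditional, with
#' residual precision `R0^-1` weighting the data and `A^-1 (x) G0^-1`
#' supplying the genetic prior.
#'
#' @param state sampler state.
#' @param design a `btlam_design`.
#' @param Ainv sparse A-inverse from [inverse_relationship()] (any Matrix
#'   sparse form; converted to full-pattern column storage internally).
#' @param beta_var fixed-effect prior variance (match the [prior_spec]).
#' @param encoding optional precomputed incidence encoding (internal reuse).
#' @return updated state.
#' @export
sample_location <- function(state, design, Ainv, beta_var = 1e8,
                            encoding = NULL) {
  if (is.null(encoding)) encoding <- design_encoding(design)
  A <- Ainv
  if (!inherits(A, "dgCMatrix")) A <- as(as(A, "generalMatrix"), "CsparseMatrix")
  res <- cpp_location_sweep(state$e, unlist(state$beta, use.names = FALSE),
                            state$a,
                            encoding$fpar_trait, encoding$fpar_ptr,
                            encoding$frows, encoding$fvals,
                            encoding$anim_ptr, encoding$anim_rows,
                            A@p, A@i, A@x,
                            solve(state$R0), solve(state$G0),
                            1 / beta_var)
  p <- vapply(design$X, ncol, integer(1))
  state$beta <- split(res$beta, rep(seq_along(p), p))
  names(state$beta) <- names(design$X)
  rownames(res$a) <- design$animal_ids
  colnames(res$a) <- design$spec$traits
  state$a <- res$a
  state$e <- res$e
  state
}

#' Draw the additive covariance matrix G0
#'
#' Conjugate update: `G0 | a ~ IW(nu_g + q, S_g + Sa)` where `q` is the
#' pedigree size and `Sa = a' A^-1 a` the A-inverse-weighted cross-product
#' of the trait-wise breeding values.
#'
#' @param state sampler state.
#' @param Ainv sparse A-inverse.
#' @param priors a [prior_spec].
#' @return updated state.
#' @export
sample_genetic_covariance <- function(state, Ainv, priors) {
  A <- Ainv
  if (!inherits(A, "dgCMatrix")) A <- as(as(A, "generalMatrix"), "CsparseMatrix")
  Sa <- cpp_quadform(A@p, A@i, A@x, state$a)
  q <- nrow(state$a)
  state$G0 <- rinvwishart(priors$nu_g + q, priors$S_g + (Sa + t(Sa)) / 2)
  state
}

#' Draw the residual covariance matrix R0
#'
#' Conjugate update on the augmented complete data: `R0 | e ~
#' IW(nu_r + n, S_r + Se)` with `Se = e'e` over records, liabilities
#' standing in for the ordinal observations. The full 3x3 is sampled -- no
#' unit-variance restriction -- because all thresholds are fixed.
#'
#' @param state sampler state.
#' @param design a `btlam_design`.
#' @param priors a [prior_spec].
#' @return updated state.
#' @export
sample_residual_covariance <- function(state, design, priors) {
  Se <- crossprod(state$e)
  state$R0 <- rinvwishart(priors$nu_r + design$n, priors$S_r + Se)
  state
}

cov_labels <- function(prefix, traits) {
  idx <- which(upper.tri(diag(3), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  paste0(prefix, "_", traits[idx[, "row"]], "_", traits[idx[, "col"]])
}

vech_upper <- function(M) {
  c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
}

#' Run the Gibbs sampler
#'
#' Full chain: initialization, then per cycle the fixed scan order
#' liabilities -> location -> `G0` -> `R0`, storing the (co)variance draws
#' every `thin` cycles after burn-in and accumulating running means of the
#' location effects. Fully reproducible given `config$seed`.
#'
#' @param design a `btlam_design`.
#' @param ped a [pedigree], or a precomputed sparse A-inverse matrix.
#' @param priors a [prior_spec]; defaults to [default_priors()].
#' @param config a [chain_config].
#' @param fix_g0,fix_r0 optional fixed covariance matrices; when supplied
#'   the corresponding component is held at that value and not sampled
#'   (used for known-variance analyses and validation).
#' @param verbose print progress.
#' @return object of class `btlam_samples`: `draws` (matrix, one row per
#'   retained cycle: 6 `G0` elements, 6 `R0` elements, iteration),
#'   `a_mean`, `beta_mean`, `config`, `priors`, trait names.
#' @export
run_chain <- function(design, ped, priors = default_priors(design),
                      config = chain_config(), fix_g0 = NULL, fix_r0 = NULL,
                      verbose = FALSE) {
  stopifnot(is(design, "btlam_design"))
  Ainv <- if (is(ped, "pedigree")) inverse_relationship(ped) else ped
  Ag <- as(as(Ainv, "generalMatrix"), "CsparseMatrix")
  if (nrow(Ag) != design$q) stop("A-inverse dimension does not match design")
  encoding <- design_encoding(design)

  set.seed(config$seed)
  state <- init_state(design, priors)
  if (!is.null(fix_g0)) state$G0 <- unname(as.matrix(fix_g0))
  if (!is.null(fix_r0)) state$R0 <- unname(as.matrix(fix_r0))

  m <- n_retained(config)
  traits <- design$spec$traits
  draws <- matrix(NA_real_, m, 13L,
                  dimnames = list(NULL, c(cov_labels("g", traits),
                                          cov_labels("r", traits), "iter")))
  a_sum <- matrix(0, design$q, 3L)
  b_sum <- numeric(length(unlist(state$beta)))
  k <- 0L
  for (it in seq_len(config$n_cycles)) {
    state <- sample_liabilities(state, design)
    state <- sample_location(state, design, Ag, priors$beta_var, encoding)
    if (is.null(fix_g0)) state <- sample_genetic_covariance(state, Ag, priors)
    if (is.null(fix_r0)) state <- sample_residual_covariance(state, design, priors)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      draws[k, ] <- c(vech_upper(state$G0), vech_upper(state$R0), it)
      if (config$store_location) {
        a_sum <- a_sum + state$a
        b_sum <- b_sum + unlist(state$beta, use.names = FALSE)
      }
    }
    if (verbose && it %% max(1L, config$n_cycles %/% 5L) == 0L) {
      message(sprintf("cycle %d / %d", it, config$n_cycles))
    }
  }
  a_mean <- a_sum / max(k, 1L)
  dimnames(a_mean) <- list(design$animal_ids, traits)
  beta_mean <- b_sum / max(k, 1L)
  names(beta_mean) <- unlist(lapply(design$X, colnames), use.names = FALSE)
  structure(list(draws = draws, a_mean = a_mean, beta_mean = beta_mean,
                 config = config, priors = priors, traits = traits,
                 final_state = state),
            class = "btlam_samples")
}

#' @export
print.btlam_samples <- function(x, ...) {
  cat(sprintf("btlam_samples: %d retained draws (of %d cycles, burn-in %d, thin %d)\n",
              nrow(x$draws), x$config$n_cycles, x$config$burn_in,
              x$config$thin))
  invisible(x)
}

#' Write retained (co)variance draws as a delimited table
#' @param samples a `btlam_samples`.
#' @param path output file (tab-delimited, with header).
#' @export
write_samples <- function(samples, path) {
  write.table(samples$draws, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a chain configuration from a YAML file
#'
#' Recognised keys: `n_cycles`, `burn_in`, `thin`, `seed`,
#' `store_location`.
#'
#' @param path YAML file.
#' @return a [chain_config].
#' @export
read_chain_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), c("n_cycles", "burn_in", "thin", "seed",
                                 "store_location"))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(chain_config, y)
}
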