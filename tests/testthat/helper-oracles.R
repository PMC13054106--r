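# Independent oracles and generators used across the suite. These deliberately
# re-derive quantities by different algorithms than the package (recursive
# kinship instead of the row-wise tabular build, dense solve instead of
# Henderson's rules) so agreement is a genuine cross-check.

# additive relationship by memoized kinship recursion:
# a(i,j) = (a(s_i, j) + a(d_i, j)) / 2 for the younger animal i,
# a(i,i) = 1 + a(s_i, d_i) / 2, unknown parents contribute 0
oracle_relationship <- function(ped) {
  n <- length(ped$id)
  K <- matrix(NA_real_, n, n)
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(K[i, j])) return(K[i, j])
    v <- if (i == j) {
      1 + 0.5 * rel(ped$sire[i], ped$dam[i])
    } else {
      y <- max(i, j); o <- min(i, j)   # sorted pedigree: parents precede
      0.5 * (rel(ped$sire[y], o) + rel(ped$dam[y], o))
    }
    K[i, j] <<- v; K[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) rel(i, j)
  dimnames(K) <- list(ped$id, ped$id)
  K
}

# random valid pedigree: founders first, later animals draw earlier parents
# (possibly unknown), so the result is topologically sorted by construction
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            p_unknown = 0.15) {
  id <- sprintf("A%04d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq.int(n_founders + 1L, length.out = max(0L, n - n_founders))) {
    pool <- seq_len(i - 1L)
    s <- if (runif(1) < p_unknown) 0L else sample(pool, 1L)
    d <- if (runif(1) < p_unknown) 0L else sample(pool, 1L)
    if (s == d && s != 0L) d <- 0L      # no selfing
    sire[i] <- as.character(if (s == 0L) "0" else id[s])
    dam[i] <- as.character(if (d == 0L) "0" else id[d])
  }
  pedigree(id, sire, dam)
}

# small single-CG record set over given animals (passes the filter pipeline
# only if >= min sizes; used where filters are not under test)
toy_records <- function(ids, date = "2020-03", preg = TRUE, age_diag = 16) {
  n <- length(ids)
  data.frame(animal = ids,
             ww = 220 + seq_len(n), age_ww = 7.5, date_ww = date,
             wy = 400 + seq_len(n), age_wy = 23, date_wy = date,
             preg = rep(preg, length.out = n),
             age_diag = rep(age_diag, length.out = n),
             stringsAsFactors = FALSE)
}

# single-trait design on a pedigree with one record per animal: trait 1 holds
# the data, traits 2 and 3 are fully latent; paired with fixed diagonal
# G0/R0 this reduces the model to a univariate animal model
univariate_design <- function(ped, y, cg = NULL) {
  n <- length(y)
  rec <- data.frame(animal = ped$id[seq_len(n)],
                    ww = y, age_ww = 0, date_ww = "x",
                    wy = NA_real_, age_wy = 0, date_wy = "x",
                    stringsAsFactors = FALSE)
  rec$cg_ww <- if (is.null(cg)) "all" else cg
  rec$cg_wy <- rec$cg_ww
  rec$cg_ac <- rec$cg_ww
  rec$ac_class <- NA_integer_
  spec <- model_spec(center_age = FALSE)
  # age constant would be collinear with CG: drop covariates via a design
  # built on CG only
  d <- build_design_cg_only(rec, ped, spec)
  d
}

# cell-means CG design with no covariates on any trait
build_design_cg_only <- function(rec, ped, spec = model_spec()) {
  rec$age_ww <- NULL; rec$age_wy <- NULL
  n <- nrow(rec)
  zi <- match(rec$animal, ped$id)
  X <- lapply(c("cg_ww", "cg_wy", "cg_ac"), function(cl) {
    f <- factor(rec[[cl]])
    matrix(vapply(levels(f), function(l) as.numeric(f == l),
                  numeric(length(f))),
           nrow = length(f), dimnames = list(NULL, levels(f)))
  })
  names(X) <- c("ww", "wy", "ac")
  y <- cbind(ww = as.numeric(rec$ww), wy = as.numeric(rec$wy),
             ac = rep(NA_real_, n))
  ac_class <- rec$ac_class
  latent <- cbind(is.na(y[, 1]), is.na(y[, 2]), rep(TRUE, n))
  tt <- c(-Inf, spec$thresholds, Inf)
  lower <- matrix(-Inf, n, 3); upper <- matrix(Inf, n, 3)
  known <- !is.na(ac_class)
  lower[known, 3] <- tt[ac_class[known]]
  upper[known, 3] <- tt[ac_class[known] + 1]
  structure(list(y = y, ac_class = ac_class, X = X, zi = zi,
                 latent = latent, lower = lower, upper = upper,
                 n = n, q = length(ped$id), animal_ids = ped$id,
                 record_animals = rec$animal, spec = spec),
            class = "btlam_design")
}

# independent blocked Gibbs sampler for the same hierarchical model:
# (beta, a) drawn jointly from their multivariate-normal full conditional via
# dense Cholesky, missing traits augmented per record, covariances by the
# same conjugate updates. Slow but algorithmically disjoint from the
# package's single-site sweep, so matching posteriors are a real check.
oracle_blocked_chain <- function(y, zi, Adense, S, nu, n_iter, burn, thin,
                                 seed) {
  set.seed(seed)
  n <- nrow(y); q <- nrow(Adense); Ainv <- solve(Adense)
  miss <- is.na(y)
  yaug <- y
  for (t in 1:3) yaug[miss[, t], t] <-
    if (all(miss[, t])) 0 else mean(y[, t], na.rm = TRUE)
  G0 <- S; R0 <- S
  beta <- rep(0, 3); a <- matrix(0, q, 3)
  Z <- matrix(0, n, q); Z[cbind(seq_len(n), zi)] <- 1
  W <- cbind(kronecker(diag(3), matrix(1, n, 1)), kronecker(diag(3), Z))
  idx <- 4:(3 + 3 * q)
  draws <- matrix(NA_real_, (n_iter - burn) %/% thin, 4,
                  dimnames = list(NULL, c("g11", "r11", "g22", "r22")))
  k <- 0
  rIW <- function(nu, Sc) {
    Wd <- rWishart(1, nu, solve(Sc))[, , 1]; V <- solve(Wd); (V + t(V)) / 2
  }
  for (it in seq_len(n_iter)) {
    E <- solve(R0)
    fit <- matrix(beta, n, 3, byrow = TRUE) + a[zi, , drop = FALSE]
    e <- yaug - fit
    for (r in seq_len(n)) for (t in 1:3) if (miss[r, t]) {
      cm <- -sum(E[t, -t] * e[r, -t]) / E[t, t]
      e[r, t] <- rnorm(1, cm, sqrt(1 / E[t, t]))
      yaug[r, t] <- fit[r, t] + e[r, t]
    }
    Rbig <- kronecker(E, diag(n))
    P <- t(W) %*% Rbig %*% W
    P[1:3, 1:3] <- P[1:3, 1:3] + diag(1e-8, 3)
    P[idx, idx] <- P[idx, idx] + kronecker(solve(G0), Ainv)
    rhs <- t(W) %*% Rbig %*% as.vector(yaug)
    ch <- chol((P + t(P)) / 2)
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    theta <- mu + backsolve(ch, rnorm(length(mu)))
    beta <- theta[1:3]; a <- matrix(theta[idx], q, 3)
    Sa <- t(a) %*% Ainv %*% a
    G0 <- rIW(nu + q, S + (Sa + t(Sa)) / 2)
    fit <- matrix(beta, n, 3, byrow = TRUE) + a[zi, , drop = FALSE]
    e <- yaug - fit
    R0 <- rIW(nu + n, S + t(e) %*% e)
    if (it > burn && (it - burn) %% thin == 0) {
      k <- k + 1
      draws[k, ] <- c(G0[1, 1], R0[1, 1], G0[2, 2], R0[2, 2])
    }
  }
  draws
}
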