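test_that("chain arithmetic and determinism contracts hold", {
  cfg <- chain_config(n_cycles = 1000, burn_in = 500, thin = 20, seed = 5)
  expect_identical(n_retained(cfg), 25L)
  # the published protocol's arithmetic
  expect_identical(n_retained(list(n_cycles = 2e6, burn_in = 5e5, thin = 20)),
                   75000L)
  expect_error(chain_config(n_cycles = 100, burn_in = 100), "burn_in")

  fix <- make_fixture("smallherd-200")
  rec <- prepare_records(fix$records, fix$ped)
  d <- build_design(rec, fix$ped)
  cfg <- chain_config(n_cycles = 200, burn_in = 100, thin = 10, seed = 42)
  s1 <- run_chain(d, fix$ped, config = cfg)
  s2 <- run_chain(d, fix$ped, config = cfg)
  expect_identical(nrow(s1$draws), 10L)
  expect_identical(s1$draws, s2$draws)        # bit-identical under one seed
  expect_identical(s1$a_mean, s2$a_mean)
})

test_that("initial state satisfies its invariants", {
  fix <- make_fixture("smallherd-200")
  rec <- prepare_records(fix$records, fix$ped)
  d <- build_design(rec, fix$ped)
  pr <- default_priors(d)
  st <- init_state(d, pr, seed = 1)
  expect_true(all(unlist(st$beta) == 0))
  expect_true(all(st$a == 0))
  # liabilities start at category midpoints, inside their intervals
  u <- st$yaug[, 3]
  expect_true(all(u[d$ac_class == 1] <= 0))
  expect_true(all(u[d$ac_class == 2] > 0 & u[d$ac_class == 2] < 1))
  expect_true(all(u[d$ac_class == 3] > 1))
  expect_equal(st$G0, pr$S_g)
  expect_equal(st$e, st$yaug - fitted_values(d, st), ignore_attr = TRUE)
})

test_that("liability draws match truncated-normal moments and intervals", {
  # n records of class 3 with identity R0 and zero location: draws are
  # N(0,1) truncated above t2 = 1; mean phi(1)/(1 - Phi(1)) = 1.5251
  n <- 20000
  ped <- pedigree("f0", "0", "0")
  rec <- data.frame(animal = "f0", ww = NA_real_, wy = NA_real_,
                    cg_ww = "g", cg_wy = "g", cg_ac = "g",
                    ac_class = 3L)[rep(1, n), ]
  d <- build_design_cg_only(rec, ped)
  pr <- prior_spec(S_g = diag(3), S_r = diag(3))
  set.seed(1)
  st <- init_state(d, pr)
  st$R0 <- diag(3)
  st <- sample_liabilities(st, d)
  u3 <- st$yaug[, 3]
  expect_true(all(u3 > 1))
  expect_equal(mean(u3), dnorm(1) / pnorm(-1) , tolerance = 0.01)

  # class 1 with t1 = 0: mean -sqrt(2/pi)
  rec$ac_class <- 1L
  d1 <- build_design_cg_only(rec, ped)
  set.seed(2)
  st <- init_state(d1, pr); st$R0 <- diag(3)
  st <- sample_liabilities(st, d1)
  u1 <- st$yaug[, 3]
  expect_true(all(u1 <= 0))
  expect_equal(mean(u1), -sqrt(2 / pi), tolerance = 0.01)
})

test_that("liability conditional regresses on observed-trait residuals", {
  # one record: ww observed with residual 5, R0 has corr(ww, ac) = 0.8:
  # U | e_ww ~ N(0.8 * 5, 1 - 0.64); with zero correlation the conditional
  # mean is the location mean exactly
  ped <- pedigree("f0", "0", "0")
  rec <- data.frame(animal = "f0", ww = 5, wy = NA_real_,
                    cg_ww = "g", cg_wy = "g", cg_ac = "g",
                    ac_class = NA_integer_)
  d <- build_design_cg_only(rec, ped)
  R0 <- diag(3); R0[1, 3] <- R0[3, 1] <- 0.8
  pr <- prior_spec(S_g = diag(3), S_r = diag(3))
  set.seed(3)
  st0 <- init_state(d, pr)
  st0$R0 <- R0
  st0$yaug[1, 1] <- 5; st0$e[1, 1] <- 5   # beta = a = 0 so residual = value
  draws <- replicate(4000, {
    st <- sample_liabilities(st0, d)
    st$yaug[1, 3]
  })
  expect_equal(mean(draws), 0.8 * 5, tolerance = 0.05)
  expect_equal(var(draws), 1 - 0.64, tolerance = 0.05)

  st0$R0 <- diag(3)
  draws0 <- replicate(2000, sample_liabilities(st0, d)$yaug[1, 3])
  expect_equal(mean(draws0), 0, tolerance = 0.08)
})

test_that("location sampler reproduces the GLS solution with known variances", {
  set.seed(21)
  ped <- random_pedigree(40, n_founders = 10, p_unknown = 0)
  A <- relationship_matrix(ped)
  q <- nrow(A)
  g <- 4; r <- 2
  a_true <- drop(t(chol(g * A)) %*% rnorm(q))
  y <- 10 + a_true + rnorm(q, 0, sqrt(r))
  d <- univariate_design(ped, y)
  cfg <- chain_config(n_cycles = 6000, burn_in = 1000, thin = 1, seed = 31)
  s <- run_chain(d, ped, priors = prior_spec(S_g = diag(3), S_r = diag(3)),
                 config = cfg,
                 fix_g0 = diag(c(g, 1, 1)), fix_r0 = diag(c(r, 1, 1)))

  V <- g * A + r * diag(q)
  Vi <- solve(V)
  X <- matrix(1, q, 1)
  beta_gls <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
  sd_gls <- sqrt(1 / drop(t(X) %*% Vi %*% X))
  # Monte Carlo error allowance: 3 posterior SDs over an assumed ESS of 100
  expect_equal(unname(s$beta_mean[1]), beta_gls,
               tolerance = 3 * sd_gls / sqrt(100) / abs(beta_gls))

  # posterior means of breeding values track the BLUP at known variances
  blup <- drop(g * A %*% Vi %*% (y - drop(X %*% beta_gls)))
  expect_gt(cor(s$a_mean[, 1], blup), 0.98)
})

test_that("covariance draws obey their conjugate inverse-Wishart limits", {
  # with breeding values pinned at zero the G0 full conditional is the
  # analytic IW(nu + q, S); its mean is S / (nu + q - 4)
  ped <- pedigree(sprintf("f%d", 1:12), rep("0", 12), rep("0", 12))
  Ainv <- inverse_relationship(ped)
  S <- diag(c(2, 3, 0.5))
  pr <- prior_spec(nu_g = 5, S_g = S, nu_r = 5, S_r = S)
  st <- list(a = matrix(0, 12, 3), e = matrix(0, 4, 3))
  set.seed(8)
  draws <- replicate(4000, sample_genetic_covariance(st, Ainv, pr)$G0)
  post_mean <- S / (5 + 12 - 4)
  for (i in 1:3) for (j in 1:3) {
    mc_se <- sd(draws[i, j, ]) / sqrt(4000)
    expect_lt(abs(mean(draws[i, j, ]) - post_mean[i, j]), 3 * mc_se + 1e-12)
  }
  # draws remain symmetric PD
  pd <- apply(draws[, , 1:500], 3, function(M)
    isSymmetric(M) && min(eigen(M, symmetric = TRUE,
                                only.values = TRUE)$values) > 0)
  expect_true(all(pd))

  # zero residuals: R0 | e ~ IW(nu + n, S)
  d_fake <- list(n = 4)
  set.seed(9)
  rdraws <- replicate(4000, sample_residual_covariance(st, d_fake, pr)$R0)
  post_mean_r <- S / (5 + 4 - 4)
  for (i in 1:3) {
    mc_se <- sd(rdraws[i, i, ]) / sqrt(4000)
    expect_lt(abs(mean(rdraws[i, i, ]) - post_mean_r[i, i]), 3 * mc_se)
  }
})

test_that("the univariate reduction recovers the phenotypic variance", {
  # A = I, one continuous trait: sigma2_a + sigma2_e is identified and its
  # posterior mean must match the sample phenotypic variance
  set.seed(33)
  n <- 300
  ped <- pedigree(sprintf("f%d", 1:n), rep("0", n), rep("0", n))
  y <- 10 + rnorm(n, 0, 2) + rnorm(n, 0, 2)
  d <- univariate_design(ped, y)
  pr <- prior_spec(S_g = diag(c(var(y) / 2, 1, 0.5)),
                   S_r = diag(c(var(y) / 2, 1, 0.5)))
  s <- run_chain(d, ped, priors = pr,
                 config = chain_config(4000, 1000, 3, seed = 44))
  tot <- s$draws[, "g_ww_ww"] + s$draws[, "r_ww_ww"]
  expect_equal(mean(tot), var(y), tolerance = 0.15)
})

test_that("retained covariance draws are symmetric PD throughout a real run", {
  fix <- make_fixture("smallherd-200")
  rec <- prepare_records(fix$records, fix$ped)
  d <- build_design(rec, fix$ped)
  s <- run_chain(d, fix$ped,
                 config = chain_config(600, 100, 5, seed = 3))
  unvech <- function(v) {
    matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
  }
  for (k in seq_len(nrow(s$draws))) {
    for (blk in list(1:6, 7:12)) {
      M <- unvech(s$draws[k, blk])
      expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  # liabilities in the final state respect their intervals
  u <- s$final_state$yaug[, 3]
  expect_true(all(u[d$ac_class == 1] <= 0))
  expect_true(all(u[d$ac_class == 2] > 0 & u[d$ac_class == 2] <= 1))
  expect_true(all(u[d$ac_class == 3] > 1))
})

test_that("single-site sampler agrees with an independent blocked sampler", {
  # same data, same priors, two algorithmically disjoint samplers: the
  # posteriors of the variance components must coincide within Monte Carlo
  # error
  set.seed(70)
  ns <- 6; nd <- 18
  ped <- pedigree(c(sprintf("s%d", 1:ns), sprintf("d%d", 1:nd),
                    sprintf("o%d", 1:nd)),
                  c(rep("0", ns + nd), rep(sprintf("s%d", 1:ns), each = 3)),
                  c(rep("0", ns + nd), sprintf("d%d", 1:nd)))
  q <- length(ped$id)
  A <- relationship_matrix(ped)
  a_true <- drop(t(chol(4 * A)) %*% rnorm(q))
  rec_ids <- ped$id[-(1:ns)]                  # dams + offspring recorded
  zi <- match(rec_ids, ped$id)
  y1 <- 10 + a_true[zi] + rnorm(length(zi), 0, sqrt(2))
  S <- diag(c(3, 1, 0.5)); nu <- 5

  od <- oracle_blocked_chain(cbind(y1, NA_real_, NA_real_), zi, A, S, nu,
                             n_iter = 4000, burn = 1000, thin = 2,
                             seed = 181)
  rec <- data.frame(animal = rec_ids, ww = y1, wy = NA_real_,
                    cg_ww = "all", cg_wy = "all", cg_ac = "all",
                    ac_class = NA_integer_)
  d <- build_design_cg_only(rec, ped)
  s <- run_chain(d, ped,
                 priors = prior_spec(nu_g = nu, S_g = S, nu_r = nu, S_r = S),
                 config = chain_config(40000, 5000, 5, seed = 182))
  for (nm in list(c("g11", "g_ww_ww"), c("r11", "r_ww_ww"))) {
    o <- od[, nm[1]]; p <- s$draws[, nm[2]]
    mcse <- sqrt(sd(o)^2 / effective_sample_size(o) +
                 sd(p)^2 / effective_sample_size(p))
    expect_lt(abs(mean(o) - mean(p)), 4 * mcse)
  }
})

test_that("chain configuration round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cycles: 5000", "burn_in: 1000", "thin: 4", "seed: 9"), f)
  cfg <- read_chain_config(f)
  expect_identical(cfg$n_cycles, 5000L)
  expect_identical(n_retained(cfg), 1000L)
  writeLines(c("n_cycles: 10", "bogus_key: 1"), f)
  expect_error(read_chain_config(f), "bogus_key")
})

test_that("retained draws written to disk round-trip numerically", {
  fix <- make_fixture("smallherd-200")
  rec <- prepare_records(fix$records, fix$ped)
  d <- build_design(rec, fix$ped)
  s <- run_chain(d, fix$ped, config = chain_config(150, 50, 10, seed = 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(s, f)
  back <- as.matrix(read.table(f, header = TRUE, sep = "\t"))
  expect_equal(unname(back), unname(s$draws), tolerance = 1e-12)
})
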