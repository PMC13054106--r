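#' Simulation configuration
#'
#' Defines the structure of the generated herd. The defaults emulate the
#' study conditions the model targets: roughly 800 recorded females on a
#' ~1,200-animal pedigree, weaning weight mean 228.24 kg (marginal SD
#' ~27.98), yearling weight mean 411.19 kg (marginal SD ~75.64), ordinal
#' class frequencies near 48.7 / 29.8 / 21.5%, contemporary groups well
#' above the minimum size, and sires with 10+ recorded progeny.
#'
#' The default true covariance matrices place the additive and residual
#' variances at the assignment consistent with those marginal SDs
#' (WW: 250.70 / 330.68; WY: 1201.00 / 683.69; AC liability: 0.32 / 1.32,
#' thresholds fixed at 0 and 1). Age slopes are set so the age covariate
#' explains about 5% of each weight's phenotypic variance, and the
#' contemporary-group SDs absorb the remainder of the marginal variance.
#' The liability intercept `mu_ac` = 0.04 calibrates the class-1 frequency
#' to ~48.7% under the default total liability variance.
#'
#' @param n_sires founder sires, reused across generations (overlapping
#'   sire use, which is what creates high-progeny sires).
#' @param dams_per_sire dams mated to each sire per generation.
#' @param progeny_per_dam offspring per mating (all female: the recorded
#'   population is the female herd).
#' @param founder_dams founder females (default `n_sires * dams_per_sire`,
#'   exactly the dams one generation needs).
#' @param n_generations total generations including the founders
#'   (`1` = founders only).
#' @param true_G0,true_R0 3x3 additive and residual covariance matrices
#'   (kg^2, kg.liability, liability^2), trait order (ww, wy, ac).
#' @param mu trait means: `ww`, `wy` (kg) and `ac` (liability intercept).
#' @param age_mean,age_sd measurement-age distributions (months) for the
#'   two weights.
#' @param age_slope linear age effects (kg/month).
#' @param cg_sd contemporary-group effect SDs per trait.
#' @param cg_count number of year-month groups per weight trait (the
#'   ordinal trait shares the yearling groups).
#' @param thresholds liability cutpoints.
#' @param diag_age per-class mean/SD (months) for the age at pregnancy
#'   diagnosis; class 3 is truncated at 18 months so the scoring rule
#'   round-trips.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 25L, dams_per_sire = 16L,
                       progeny_per_dam = 1L, n_generations = 3L,
                       founder_dams = n_sires * dams_per_sire,
                       true_G0 = matrix(c(250.70, 429.91, -1.94,
                                          429.91, 1201.00, 6.43,
                                          -1.94, 6.43, 0.32), 3, 3),
                       true_R0 = matrix(c(330.68, 116.52, 4.16,
                                          116.52, 683.69, 8.43,
                                          4.16, 8.43, 1.32), 3, 3),
                       mu = c(ww = 228.24, wy = 411.19, ac = 0.04),
                       age_mean = c(ww = 7.50, wy = 23.21),
                       age_sd = c(ww = 0.78, wy = 6.09),
                       age_slope = c(ww = 8.0, wy = 2.8),
                       cg_sd = c(ww = 12.75, wy = 59.55, ac = 0.2),
                       cg_count = c(ww = 12L, wy = 12L),
                       thresholds = c(0, 1),
                       diag_age = list(`1` = c(21.85, 4.72),
                                       `2` = c(30.46, 2.27),
                                       `3` = c(16.5, 1.2))) {
  check_pd <- function(S, nm) {
    if (!isSymmetric(unname(S)) || any(eigen(S, symmetric = TRUE,
                                             only.values = TRUE)$values <= 0))
      stop(nm, " must be symmetric positive definite")
  }
  check_pd(true_G0, "true_G0"); check_pd(true_R0, "true_R0")
  stopifnot(n_sires >= 1L, dams_per_sire >= 1L, progeny_per_dam >= 1L,
            n_generations >= 1L)
  structure(list(n_sires = as.integer(n_sires),
                 dams_per_sire = as.integer(dams_per_sire),
                 progeny_per_dam = as.integer(progeny_per_dam),
                 n_generations = as.integer(n_generations),
                 founder_dams = as.integer(founder_dams),
                 true_G0 = unname(true_G0), true_R0 = unname(true_R0),
                 mu = mu, age_mean = age_mean, age_sd = age_sd,
                 age_slope = age_slope, cg_sd = cg_sd,
                 cg_count = cg_count, thresholds = thresholds,
                 diag_age = diag_age),
            class = "sim_config")
}

#' Simulate a pedigree with discrete female generations
#'
#' Founders are `n_sires` males plus `n_sires * dams_per_sire` females.
#' Each later generation mates every sire to `dams_per_sire` dams sampled
#' from the previous generation's females, each dam leaving
#' `progeny_per_dam` female offspring. Sires are founders reused in every
#' generation (overlapping use), which yields the deep sire families the
#' ranking analyses need.
#'
#' @param config a [sim_config].
#' @return a [pedigree] with attributes `generation` (0 = founder) and
#'   `sex` (`"M"`/`"F"`), aligned with the sorted ids.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  ns <- config$n_sires
  nd <- ns * config$dams_per_sire
  sires <- sprintf("S%03d", seq_len(ns))
  fdams <- sprintf("D%04d", seq_len(config$founder_dams))
  animal <- c(sires, fdams)
  nf <- length(fdams)
  sire <- dam <- rep(NA_character_, ns + nf)
  gen <- rep(0L, ns + nf)
  sex <- c(rep("M", ns), rep("F", nf))

  prev_females <- fdams
  for (g in seq_len(config$n_generations - 1L)) {
    if (length(prev_females) < nd) {
      stop("infeasible mating counts: generation ", g, " needs ", nd,
           " dams but only ", length(prev_females), " females available")
    }
    dams_g <- sample(prev_females, nd)
    sire_of_dam <- rep(sires, each = config$dams_per_sire)
    off_dam <- rep(dams_g, each = config$progeny_per_dam)
    off_sire <- rep(sire_of_dam, each = config$progeny_per_dam)
    off_id <- sprintf("G%d_%04d", g, seq_along(off_dam))
    animal <- c(animal, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    gen <- c(gen, rep(g, length(off_id)))
    sex <- c(sex, rep("F", length(off_id)))
    prev_females <- off_id
  }
  names(gen) <- names(sex) <- animal
  ped <- pedigree(animal, sire, dam)
  attr(ped, "generation") <- unname(gen[ped$id])
  attr(ped, "sex") <- unname(sex[ped$id])
  ped
}

#' Simulate true breeding values down a pedigree
#'
#' Founders draw `a ~ N(0, G0)`; each non-founder receives the parent
#' average plus a Mendelian sampling deviation `N(0, m_i * G0)` where
#' `m_i` is 1/2 reduced by the parents' inbreeding, `3/4` with one unknown
#' parent, and `1` with both unknown (an unknown parent contributes a zero
#' term and a correspondingly inflated Mendelian variance).
#'
#' @param ped a [pedigree].
#' @param true_G0 3x3 additive covariance.
#' @return list (`sim_truth`): `a` (q x 3, rownames = ids), `f` (inbreeding).
#' @export
simulate_breeding_values <- function(ped, true_G0) {
  q <- n_animals(ped)
  f <- inbreeding(ped)
  msv <- mendelian_variance(ped, f)
  L <- chol(true_G0)
  a <- matrix(0, q, 3L, dimnames = list(ped$id, c("ww", "wy", "ac")))
  Z <- matrix(rnorm(q * 3L), q, 3L) %*% L
  for (i in seq_len(q)) {
    pa <- numeric(3L)
    if (ped$sire[i] > 0L) pa <- pa + 0.5 * a[ped$sire[i], ]
    if (ped$dam[i] > 0L) pa <- pa + 0.5 * a[ped$dam[i], ]
    a[i, ] <- pa + sqrt(msv[i]) * Z[i, ]
  }
  structure(list(a = a, f = f), class = "sim_truth")
}

# pool of YYYY-MM contemporary-group labels
cg_labels <- function(k, start_year = 2016L) {
  sprintf("%d-%02d", start_year + (seq_len(k) - 1L) %/% 12L,
          (seq_len(k) - 1L) %% 12L + 1L)
}

#' Simulate phenotype records from the generative model
#'
#' Runs the analysis model forward for every non-founder female: each
#' weight is its mean plus a contemporary-group effect, a linear age
#' deviation, the true breeding value and a residual; the three residuals
#' are drawn jointly from `N(0, R0)` per animal. The conception liability
#' (intercept + CG effect + breeding value + residual) is cut at the
#' thresholds into the ordinal class, and an age at diagnosis is drawn from
#' the class-consistent distribution (class 3 truncated at 18 months).
#'
#' @param ped a [pedigree] from [simulate_pedigree()].
#' @param truth a `sim_truth` from [simulate_breeding_values()].
#' @param config a [sim_config].
#' @return data frame of raw records (columns as [read_phenotypes()]);
#'   attribute `"truth"` carries liabilities and CG effect values.
#' @export
simulate_records <- function(ped, truth, config = sim_config()) {
  gen <- attr(ped, "generation")
  sex <- attr(ped, "sex")
  cand <- if (!is.null(gen) && !is.null(sex)) {
    which(gen > 0L & sex == "F")
  } else {
    which(ped$sire > 0L | ped$dam > 0L)
  }
  n <- length(cand)
  if (n == 0L) stop("pedigree has no non-founder females to record")

  lab_ww <- cg_labels(config$cg_count[["ww"]])
  lab_wy <- cg_labels(config$cg_count[["wy"]], start_year = 2017L)
  eff <- list(ww = setNames(rnorm(length(lab_ww), 0, config$cg_sd[["ww"]]), lab_ww),
              wy = setNames(rnorm(length(lab_wy), 0, config$cg_sd[["wy"]]), lab_wy),
              ac = setNames(rnorm(length(lab_wy), 0, config$cg_sd[["ac"]]), lab_wy))
  date_ww <- sample(lab_ww, n, replace = TRUE)
  date_wy <- sample(lab_wy, n, replace = TRUE)

  age_ww <- cpp_rtnorm(n, config$age_mean[["ww"]], config$age_sd[["ww"]], 0, Inf)
  age_wy <- cpp_rtnorm(n, config$age_mean[["wy"]], config$age_sd[["wy"]], 0, Inf)

  e <- matrix(rnorm(n * 3L), n, 3L) %*% chol(config$true_R0)
  a <- truth$a[cand, , drop = FALSE]

  ww <- config$mu[["ww"]] + eff$ww[date_ww] +
    config$age_slope[["ww"]] * (age_ww - config$age_mean[["ww"]]) +
    a[, 1L] + e[, 1L]
  wy <- config$mu[["wy"]] + eff$wy[date_wy] +
    config$age_slope[["wy"]] * (age_wy - config$age_mean[["wy"]]) +
    a[, 2L] + e[, 2L]
  U <- config$mu[["ac"]] + eff$ac[date_wy] + a[, 3L] + e[, 3L]
  cls <- findInterval(U, config$thresholds) + 1L

  da <- config$diag_age
  age_diag <- numeric(n)
  for (k in 1:3) {
    ik <- which(cls == k)
    if (!length(ik)) next
    bounds <- switch(k, c(0, Inf), c(18 + 1e-9, Inf), c(0, 18))
    age_diag[ik] <- cpp_rtnorm(length(ik), da[[as.character(k)]][1L],
                               da[[as.character(k)]][2L],
                               bounds[1L], bounds[2L])
  }

  rec <- data.frame(animal = ped$id[cand],
                    ww = unname(ww), age_ww = age_ww, date_ww = date_ww,
                    wy = unname(wy), age_wy = age_wy, date_wy = date_wy,
                    preg = cls > 1L, age_diag = age_diag,
                    stringsAsFactors = FALSE)
  attr(rec, "truth") <- list(liability = setNames(unname(U), rec$animal),
                             class = setNames(cls, rec$animal),
                             cg_effects = eff)
  rec
}

#' Simulate a complete dataset (pedigree, breeding values, records)
#'
#' @param config a [sim_config].
#' @param seed integer seed; all generator randomness flows through it.
#' @return list of class `btlam_sim`: `ped`, `records`, `truth` (breeding
#'   values, inbreeding, liabilities, CG effects), `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(config)
  truth <- simulate_breeding_values(ped, config$true_G0)
  records <- simulate_records(ped, truth, config)
  truth$liability <- attr(records, "truth")$liability
  truth$cg_effects <- attr(records, "truth")$cg_effects
  structure(list(ped = ped, records = records, truth = truth,
                 config = config, seed = seed),
            class = "btlam_sim")
}

#' Write a simulated dataset as delimited text
#'
#' Emits the same pedigree/phenotype formats the readers consume plus a
#' truth sidecar (true breeding values, inbreeding, liabilities) for tests.
#'
#' @param sim a `btlam_sim`.
#' @param dir output directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- as.data.frame(sim$ped)
  pd[is.na(pd)] <- "0"
  write.table(pd, file.path(dir, "pedigree.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(sim$records, file.path(dir, "phenotypes.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  tr <- data.frame(animal = rownames(sim$truth$a), sim$truth$a,
                   f = unname(sim$truth$f),
                   liability = unname(sim$truth$liability[rownames(sim$truth$a)]))
  write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Deterministic bundled fixtures
#'
#' Small named datasets used throughout the test suite:
#' \describe{
#'   \item{`trio`}{sire, dam and one offspring, with the hand-worked `A`
#'     and `A^-1`.}
#'   \item{`fullsib`}{two parents, two full sibs, and an offspring of the
#'     full-sib mating (inbreeding 0.25).}
#'   \item{`smallherd-200`}{a ~200-animal simulated herd with records and
#'     stored truth, regenerated from a fixed seed.}
#' }
#'
#' @param name fixture name.
#' @return list with at least `ped` and `records`; simulated fixtures also
#'   carry `truth` and `config`.
#' @export
make_fixture <- function(name = c("trio", "fullsib", "smallherd-200")) {
  name <- match.arg(name)
  fixture_records <- function(ids) {
    n <- length(ids)
    data.frame(animal = ids,
               ww = 200 + 5 * seq_len(n), age_ww = 7.5, date_ww = "2020-01",
               wy = 400 + 5 * seq_len(n), age_wy = 23, date_wy = "2021-01",
               preg = rep(c(TRUE, FALSE), length.out = n),
               age_diag = rep(c(16, 22), length.out = n),
               stringsAsFactors = FALSE)
  }
  switch(name,
    trio = {
      ped <- pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
      A <- matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3, 3,
                  dimnames = list(ped$id, ped$id))
      Ainv <- matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3,
                     dimnames = list(ped$id, ped$id))
      list(ped = ped, records = fixture_records(ped$id), A = A, Ainv = Ainv)
    },
    fullsib = {
      ped <- pedigree(c("P1", "P2", "C1", "C2", "X"),
                      c("0", "0", "P1", "P1", "C1"),
                      c("0", "0", "P2", "P2", "C2"))
      list(ped = ped, records = fixture_records(ped$id), f_X = 0.25)
    },
    `smallherd-200` = {
      cfg <- sim_config(n_sires = 5L, dams_per_sire = 8L,
                        progeny_per_dam = 2L, n_generations = 3L,
                        cg_count = c(ww = 6L, wy = 6L))
      sim <- simulate_dataset(cfg, seed = 4242L)
      list(ped = sim$ped, records = sim$records, truth = sim$truth,
           config = cfg)
    })
}
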