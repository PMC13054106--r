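test_that("simulated pedigrees have the configured structure and validate", {
  # founders only
  p1 <- simulate_pedigree(sim_config(n_sires = 3L, dams_per_sire = 2L,
                                     n_generations = 1L))
  expect_identical(length(p1$id), 9L)
  expect_true(all(p1$sire == 0L))

  # 10 sires x 5 dams x 2 progeny: 100 offspring, each sire 10 progeny
  set.seed(1)
  cfg <- sim_config(n_sires = 10L, dams_per_sire = 5L, progeny_per_dam = 2L,
                    n_generations = 2L)
  p2 <- simulate_pedigree(cfg)
  gen <- attr(p2, "generation")
  expect_identical(sum(gen == 1L), 100L)
  prog <- table(p2$sire[p2$sire > 0L])
  expect_true(all(prog == 10L))

  # round-trip through the file reader re-validates
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(p2); df[is.na(df)] <- "0"
  write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE)
  p3 <- read_pedigree(f)
  expect_identical(p3$id, p2$id)

  # infeasible mating counts are refused
  expect_error(simulate_pedigree(sim_config(n_sires = 10L,
                                            dams_per_sire = 5L,
                                            founder_dams = 10L,
                                            n_generations = 2L)),
               "infeasible")
})

test_that("breeding values follow the additive covariance structure", {
  cfg <- sim_config()
  # founder sample covariance approaches true_G0
  set.seed(2)
  ped <- pedigree(sprintf("f%d", 1:10000), rep("0", 10000), rep("0", 10000))
  tr <- simulate_breeding_values(ped, cfg$true_G0)
  S <- cov(tr$a)
  expect_lt(max(abs(S - cfg$true_G0)) / max(abs(cfg$true_G0)), 0.05)

  # full sibs share half the additive covariance: regression of one sib's
  # BV on the other's approaches 0.5 across many sib pairs
  set.seed(3)
  n_fam <- 4000
  ids <- c(sprintf("s%d", 1:n_fam), sprintf("d%d", 1:n_fam),
           sprintf("c1_%d", 1:n_fam), sprintf("c2_%d", 1:n_fam))
  sire <- c(rep("0", 2 * n_fam), rep(sprintf("s%d", 1:n_fam), 2))
  dam <- c(rep("0", 2 * n_fam), rep(sprintf("d%d", 1:n_fam), 2))
  ped2 <- pedigree(ids, sire, dam)
  tr2 <- simulate_breeding_values(ped2, cfg$true_G0)
  b1 <- tr2$a[sprintf("c1_%d", 1:n_fam), "ww"]
  b2 <- tr2$a[sprintf("c2_%d", 1:n_fam), "ww"]
  expect_equal(cor(b1, b2), 0.5, tolerance = 0.05)
})

test_that("records decompose phenotypic variance as configured", {
  # no CG effects, no age slope, diagonal R0: var(ww) = g + r
  cfg <- sim_config(n_sires = 50L, dams_per_sire = 20L, progeny_per_dam = 10L,
                    n_generations = 2L,
                    true_G0 = diag(c(250, 1200, 0.32)),
                    true_R0 = diag(c(330, 680, 1.32)),
                    cg_sd = c(ww = 0, wy = 0, ac = 0),
                    age_slope = c(ww = 0, wy = 0))
  sim <- simulate_dataset(cfg, seed = 5)
  expect_identical(nrow(sim$records), 10000L)
  expect_equal(var(sim$records$ww), 250 + 330, tolerance = 0.05 * 580)
  expect_equal(var(sim$records$wy), 1200 + 680, tolerance = 0.05 * 1880)

  # liability between thresholds maps to the middle class; with a symmetric
  # tight liability around 0.5 class 2 is modal
  cfg2 <- sim_config(mu = c(ww = 228, wy = 411, ac = 0.5),
                     true_G0 = diag(c(250, 1200, 0.02)),
                     true_R0 = diag(c(330, 680, 0.02)),
                     cg_sd = c(ww = 12, wy = 59, ac = 0))
  sim2 <- simulate_dataset(cfg2, seed = 6)
  cls <- attr(sim2$records, "truth")$class
  expect_identical(which.max(tabulate(cls)), 2L)
})

test_that("default configuration emulates the target herd", {
  sim <- simulate_dataset(sim_config(), seed = 31)
  expect_identical(length(sim$ped$id), 1225L)
  expect_identical(nrow(sim$records), 800L)

  expect_equal(mean(sim$records$ww), 228.24, tolerance = 0.02)
  expect_equal(sd(sim$records$ww), 27.98, tolerance = 0.10)
  expect_equal(mean(sim$records$wy), 411.19, tolerance = 0.02)
  expect_equal(sd(sim$records$wy), 75.64, tolerance = 0.10)

  # class frequencies within +/- 5 points of the calibration target
  rec <- prepare_records(sim$records, sim$ped)
  ft <- class_frequencies(rec)
  expect_true(all(abs(ft$pct - c(48.74, 29.77, 21.48)) < 5))

  # scoring rule round-trips: diagnosis ages are class-consistent
  expect_identical(rec$ac_class,
                   assign_conception_class(rec$preg, rec$age_diag))
})

test_that("simulation is reproducible and fixtures are deterministic", {
  s1 <- simulate_dataset(sim_config(n_sires = 4L, dams_per_sire = 4L,
                                    n_generations = 2L), seed = 8)
  s2 <- simulate_dataset(sim_config(n_sires = 4L, dams_per_sire = 4L,
                                    n_generations = 2L), seed = 8)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$a, s2$truth$a)

  f1 <- make_fixture("smallherd-200")
  f2 <- make_fixture("smallherd-200")
  expect_identical(f1$records, f2$records)

  # written datasets are byte-identical under one seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
})

test_that("written datasets round-trip through the readers", {
  sim <- simulate_dataset(sim_config(n_sires = 4L, dams_per_sire = 4L,
                                     n_generations = 2L), seed = 13)
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  ped <- read_pedigree(file.path(d, "pedigree.csv"))
  expect_identical(ped$id, sim$ped$id)
  rec <- read_phenotypes(file.path(d, "phenotypes.csv"))
  expect_identical(rec$animal, sim$records$animal)
  expect_equal(rec$ww, sim$records$ww, tolerance = 1e-10)
})
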