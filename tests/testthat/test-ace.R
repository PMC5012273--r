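test_that("ACE log-likelihood matches per-pair matrix-inversion oracle", {
  set.seed(55)
  for (rep in 1:5) {
    pt <- paired_trait(matrix(rnorm(20), 10), matrix(rnorm(20), 10))
    a <- runif(1, 0.1, 1); cc <- runif(1, 0, 1)
    e <- runif(1, 0.3, 1); mu <- rnorm(1)
    expect_equal(ace_loglik(a, cc, e, mu, pt),
                 ace_loglik_bruteforce(a, cc, e, mu, pt),
                 tolerance = 1e-10)
  }
})

test_that("ACE log-likelihood collapses and symmetrizes correctly", {
  set.seed(56)
  pt <- paired_trait(matrix(rnorm(16), 8), matrix(rnorm(12), 6))
  ## a = c = 0: independent univariate normals with variance e^2
  e <- 1.3; mu <- 0.2
  expect_equal(ace_loglik(0, 0, e, mu, pt),
               sum(dnorm(c(pt$mz, pt$dz), mu, e, log = TRUE)),
               tolerance = 1e-10)
  ## swapping twins within pairs leaves the likelihood unchanged
  pt_sw <- paired_trait(pt$mz[, 2:1], pt$dz[, 2:1])
  expect_equal(ace_loglik(0.5, 0.4, 0.8, 0.1, pt),
               ace_loglik(0.5, 0.4, 0.8, 0.1, pt_sw), tolerance = 1e-12)
  ## singular covariance returns -Inf
  expect_identical(ace_loglik(1, 0, 0, 0, pt), -Inf)
})

test_that("Falconer closed form follows the textbook identities", {
  ## construct pairs with exactly known double-entry correlations
  make_r <- function(n, r, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    ## symmetrize so the double-entered correlation is exact by averaging
    cbind(c(x, y), c(y, x))
  }
  mz <- make_r(2000, 0.6, 1)
  dz <- make_r(2000, 0.4, 2)
  f <- falconer_estimate(paired_trait(mz, dz))
  r_mz <- cor(c(mz[, 1]), c(mz[, 2]))
  r_dz <- cor(c(dz[, 1]), c(dz[, 2]))
  expect_equal(unname(f),
               c(2 * (r_mz - r_dz), 2 * r_dz - r_mz, 1 - r_mz),
               tolerance = 1e-12)
  ## rMZ = rDZ = r gives A = 0, C = r
  same <- paired_trait(mz, mz)
  f2 <- falconer_estimate(same)
  expect_equal(unname(f2["A"]), 0, tolerance = 1e-12)
  expect_equal(unname(f2["C"]), r_mz, tolerance = 1e-12)
})

test_that("fit_ace recovers simulated variance components", {
  ## large-sample recovery against the generating truth, with the
  ## Falconer closed form as the analytic cross-check at this n
  pt <- simulate_twin_traits(10000, 10000, 0.4, 0.2, 0.4, seed = 77)
  fit <- fit_ace(pt, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$A - 0.4), 0.03)
  expect_lt(abs(fit$C - 0.2), 0.03)
  expect_lt(abs(fit$E - 0.4), 0.03)
  falc <- falconer_estimate(pt)
  expect_lt(max(abs(coef(fit) - falc)), 0.02)
  ## A + C + E = 1 exactly by construction
  expect_equal(fit$A + fit$C + fit$E, 1, tolerance = 1e-10)
  ## solution at least as good as every start
  expect_gte(fit$loglik, fit$start_loglik - 1e-6)
})

test_that("degenerate correlation structures land on the right boundary", {
  set.seed(78)
  y_mz <- rnorm(60); y_dz <- rnorm(50)
  ## identical twins in both groups: rMZ = rDZ = 1 forces C
  pt_c <- paired_trait(cbind(y_mz, y_mz), cbind(y_dz, y_dz))
  fit_c <- fit_ace(pt_c, seed = 2)
  expect_lt(fit_c$E, 0.01)
  expect_lt(fit_c$A, 0.05)
  expect_gt(fit_c$C, 0.95)
  ## uncorrelated pairs: everything is unique environment
  pt_e <- paired_trait(matrix(rnorm(2000), 1000), matrix(rnorm(2000), 1000))
  fit_e <- fit_ace(pt_e, seed = 3)
  expect_lt(fit_e$A, 0.08)
  expect_lt(fit_e$C, 0.08)
  expect_gt(fit_e$E, 0.9)
})

test_that("standardized estimates are invariant to affine trait rescaling", {
  pt <- simulate_twin_traits(400, 350, 0.3, 0.2, 0.5, seed = 91)
  fit1 <- fit_ace(pt, seed = 4)
  pt5 <- paired_trait(5 * pt$mz + 2, 5 * pt$dz + 2)
  fit5 <- fit_ace(pt5, seed = 4)
  expect_equal(coef(fit1), coef(fit5), tolerance = 1e-6)
  expect_equal(fit5$mu, 5 * fit1$mu + 2, tolerance = 1e-4)
})

test_that("profile CI brackets the estimate and matches the LR definition", {
  pt <- simulate_twin_traits(473, 402, 0.3, 0.1, 0.6, seed = 13)
  fit <- fit_ace(pt, seed = 5)
  ci <- profile_ci(fit, "A")
  expect_lte(ci[1], fit$A)
  expect_gte(ci[2], fit$A)
  expect_gte(ci[1], 0)
  expect_lte(ci[2], 1)
  ## at the boundary the LR statistic equals the chi-square cutoff
  ss_mz <- otuherit:::pair_suffstats(pt$mz)
  ss_dz <- otuherit:::pair_suffstats(pt$dz)
  for (v in ci[ci > 1e-9 & ci < 1 - 1e-9]) {
    lr <- 2 * (fit$loglik -
                 otuherit:::profile_loglik_at(fit, "A", v, ss_mz, ss_dz))
    expect_equal(lr, qchisq(0.95, 1), tolerance = 0.02)
  }
  ## confint method exposes all three components
  ci3 <- confint(fit)
  expect_identical(dim(ci3), c(3L, 2L))
  expect_true(all(ci3[, 1] <= coef(fit) & coef(fit) <= ci3[, 2]))
})

test_that("fit_all produces a deterministic per-OTU profile", {
  cfg <- simulation_config(n_mz = 40, n_dz = 35, n_otus = 8,
                           library_size = 4000, seed = 12)
  ds <- simulate_twin_otu_table(cfg)
  pairs <- pair_samples(ds$table, ds$records)
  traits <- prepare_traits(ds$table, pairs)
  prof <- fit_all(traits, seed = 9)
  expect_s3_class(prof, "herit_profile")
  expect_equal(nrow(prof$estimates), nrow(traits$values))
  expect_equal(prof$mean_A, mean(prof$estimates$A))
  expect_true(all(prof$estimates$ci_A_lower <= prof$estimates$A + 1e-9))

  ## rerun with the same seed: bit-identical output TSV
  prof2 <- fit_all(traits, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_herit_profile(prof, f1); write_herit_profile(prof2, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## empty trait matrix errors
  empty <- traits
  empty$values <- traits$values[0, , drop = FALSE]
  expect_error(fit_all(empty), "empty")
})

test_that("simulate.ace_fit reproduces the fitted covariance structure", {
  pt <- simulate_twin_traits(3000, 3000, 0.5, 0.2, 0.3, seed = 31)
  fit <- fit_ace(pt, seed = 6)
  sim <- simulate(fit, nsim = 1, seed = 32)[[1]]
  expect_s3_class(sim, "paired_trait")
  refit <- fit_ace(sim, seed = 7)
  expect_lt(abs(refit$A - fit$A), 0.05)
})
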