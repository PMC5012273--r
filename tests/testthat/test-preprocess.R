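test_that("prevalence filter is inclusive at the boundary and ignores pseudo-counts", {
  m <- rbind(OTU1 = c(1L, 2L, 0L, 0L),   # 2 of 4 = 0.5 -> kept
             OTU2 = c(5L, 0L, 0L, 0L),   # 1 of 4 -> removed
             OTU3 = c(1L, 1L, 1L, 1L))
  colnames(m) <- paste0("S", 1:4)
  tab <- otu_table(m, "m")
  kept <- prevalence_filter(tab, 0.5)
  expect_identical(otu_ids(kept), c("OTU1", "OTU3"))
  expect_identical(sample_ids(kept), sample_ids(tab))
  ## min_fraction = 1 removes any OTU with a zero cell
  expect_identical(otu_ids(prevalence_filter(tab, 1)), "OTU3")
  ## prevalence must be computed before pseudo-counts are added
  expect_identical(otu_ids(prevalence_filter(add_pseudocount(tab), 0.5)),
                   otu_ids(tab))
})

test_that("pseudo-count and relative abundance behave arithmetically", {
  m <- rbind(A = c(0L, 2L), B = c(4L, 0L))
  colnames(m) <- c("S1", "S2")
  tab <- otu_table(m, "m")
  pc <- add_pseudocount(tab, 1)
  expect_identical(unname(pc$counts), unname(m + 1L))
  expect_equal(colSums(pc$counts), colSums(m) + nrow(m),
               ignore_attr = TRUE)

  rel <- to_relative_abundance(pc)
  expect_equal(unname(rel$rel_abundance[, 1]), c(1 / 6, 5 / 6))
  expect_equal(colSums(rel$rel_abundance), c(S1 = 1, S2 = 1))

  ## random fixture: all columns sum to 1
  big <- otu_table(make_counts(50, 20, seed = 7) + 1L, "m")
  expect_equal(unname(colSums(to_relative_abundance(big)$rel_abundance)),
               rep(1, 20), tolerance = 1e-9)

  zm <- matrix(c(0L, 0L, 1L, 1L), 2, 2,
               dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(to_relative_abundance(otu_table(zm, "m")), "zero total")
})

test_that("Box-Cox lambda recovers identity and log transforms", {
  set.seed(101)
  n <- 500
  design <- cbind(1, rnorm(n))
  mu <- 10 + 2 * design[, 2]
  y_id <- mu + rnorm(n)               # already normal -> lambda ~ 1
  expect_true(all(y_id > 0))
  fit1 <- boxcox_lambda(y_id, design)
  expect_lt(abs(fit1$lambda - 1), 0.15)

  y_log <- exp(0.5 * design[, 2] + rnorm(n) * 0.4)  # lognormal -> lambda ~ 0
  fit0 <- boxcox_lambda(y_log, design)
  expect_lt(abs(fit0$lambda - 0), 0.15)
})

test_that("Box-Cox optimizer matches the dense grid argmax and MASS profile", {
  set.seed(202)
  for (rep in 1:20) {
    n <- 60
    design <- cbind(1, rnorm(n), runif(n))
    y <- exp(rnorm(n, sd = 0.5) + 0.3 * design[, 2])^runif(1, 0.3, 2)
    fit <- boxcox_lambda(y, design)
    oracle <- boxcox_grid_oracle(y, design, step = 0.01)
    expect_lt(abs(fit$lambda - oracle), 0.011)
  }
  ## agreement with the MASS profile-likelihood maximizer on one fixture
  n <- 200
  design <- cbind(1, x = rnorm(n))
  y <- exp(1 + 0.5 * design[, 2] + rnorm(n, sd = 0.3))
  fit <- boxcox_lambda(y, design)
  bc <- MASS::boxcox(y ~ design[, 2], lambda = seq(-2, 2, 0.001),
                     plotit = FALSE)
  expect_lt(abs(fit$lambda - bc$x[which.max(bc$y)]), 0.01)
})

test_that("Box-Cox profile log-likelihood is continuous at lambda = 0", {
  set.seed(33)
  y <- rexp(80) + 0.1
  design <- cbind(1, rnorm(80))
  qrx <- qr(design)
  sly <- sum(log(y))
  l0 <- otuherit:::boxcox_profile_loglik(0, y, qrx, sly)
  leps <- otuherit:::boxcox_profile_loglik(1e-6, y, qrx, sly)
  expect_lt(abs(leps - l0), 1e-4)
})

test_that("covariate residuals are centred, standardized and orthogonal to the design", {
  set.seed(44)
  n <- 120
  design <- cbind(1, a = rnorm(n), b = runif(n))
  y <- 2 + design[, 2] - 0.5 * design[, 3] + rnorm(n)
  r <- covariate_residuals(y, design)
  expect_lt(abs(mean(r)), 1e-8)
  expect_equal(var(r), 1, tolerance = 1e-8)
  expect_true(all(abs(crossprod(design, as.numeric(r))) < 1e-8 *
                    max(abs(crossprod(design, y)))))

  ## intercept-only design: centred scaled y
  r0 <- covariate_residuals(y, matrix(1, n, 1))
  expect_equal(as.numeric(r0), as.numeric(scale(y)), tolerance = 1e-10)

  ## a response equal to a design column is degenerate, and flagged
  rd <- covariate_residuals(design[, 2], design)
  expect_true(attr(rd, "degenerate"))

  ## collinear design is rejected with the offending column named
  bad <- cbind(design, a2 = design[, 2])
  expect_error(covariate_residuals(y, bad), "a2|collinear")
  expect_error(boxcox_lambda(abs(y) + 1, bad), "a2|collinear")
})

test_that("prepare_traits runs the pipeline in the stated order", {
  cfg <- simulation_config(n_mz = 15, n_dz = 12, n_otus = 12,
                           zero_inflation = c(rep(0, 6), rep(0.8, 6)),
                           library_size = 3000, seed = 8)
  ds <- simulate_twin_otu_table(cfg)
  pairs <- pair_samples(ds$table, ds$records)
  traits <- prepare_traits(ds$table, pairs)

  ## row count equals brute-force prevalence on the raw counts
  samp <- c(rbind(pairs$pairs$sample_1, pairs$pairs$sample_2))
  raw <- ds$table$counts[, samp]
  prevalent <- rownames(raw)[rowMeans(raw > 0) >= 0.5]
  expect_identical(rownames(traits$values), prevalent)
  expect_true(length(prevalent) < nrow(raw))   # zero-inflated OTUs dropped

  ## per-OTU residuals: mean 0, unit variance
  expect_true(all(abs(rowMeans(traits$values)) < 1e-8))
  expect_equal(unname(apply(traits$values, 1, var)),
               rep(1, nrow(traits$values)), tolerance = 1e-8)

  ## determinism: identical inputs -> bit-identical traits
  traits2 <- prepare_traits(ds$table, pairs)
  expect_identical(traits2$values, traits$values)

  ## permuting the sample columns of the table leaves traits unchanged
  perm <- sample(ncol(ds$table$counts))
  tab_p <- ds$table
  tab_p$counts <- ds$table$counts[, perm]
  traits3 <- prepare_traits(tab_p, pairs)
  expect_equal(traits3$values, traits$values, tolerance = 1e-12)
})
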