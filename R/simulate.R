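#' Simulate latent twin traits with known ACE structure
#'
#' Draws one standardized trait per twin: `z = sqrt(A) g + sqrt(C) c +
#' sqrt(E) e` with the additive genetic value `g` correlated 1 within MZ
#' pairs and 0.5 within DZ pairs, the common-environment value `c` shared
#' exactly within a pair and `e` independent.  The marginal variance is 1,
#' the within-pair covariance `A + C` for MZ and `A/2 + C` for DZ pairs.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param A,C,E Non-negative variance proportions summing to 1.
#' @param seed Optional integer seed.
#' @return A [paired_trait].
#' @examples
#' sim <- simulate_twin_traits(473, 402, A = 0.3, C = 0.1, E = 0.6, seed = 1)
#' cor(sim$mz)[1, 2]   # near A + C
#' @export
simulate_twin_traits <- function(n_mz, n_dz, A, C, E, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (min(A, C, E) < 0 || abs(A + C + E - 1) > 1e-8)
    stop("A, C, E must be non-negative and sum to 1")
  draw <- function(n, r_g) {
    g1 <- stats::rnorm(n)
    g2 <- r_g * g1 + sqrt(1 - r_g^2) * stats::rnorm(n)
    cc <- stats::rnorm(n)
    y1 <- sqrt(A) * g1 + sqrt(C) * cc + sqrt(E) * stats::rnorm(n)
    y2 <- sqrt(A) * g2 + sqrt(C) * cc + sqrt(E) * stats::rnorm(n)
    cbind(y1, y2, deparse.level = 0)
  }
  paired_trait(draw(n_mz, 1), draw(n_dz, 0.5))
}

#' Simulation configuration for a synthetic twin OTU table
#'
#' Defaults emulate the study design that motivates the package: 473 MZ
#' and 402 DZ complete pairs (1,750 samples) and a mean post-QC library
#' size of 81,318 reads per sample.  Per-OTU variance components default
#' to A cycling over 0, 0.1, 0.2, 0.3, 0.4 with C = 0.1.
#'
#' @param n_mz,n_dz Pair counts.
#' @param n_otus Number of OTUs.
#' @param A,C Per-OTU variance proportions (recycled to `n_otus`);
#'   `E = 1 - A - C`.
#' @param base_abundance Per-OTU mean log-abundance (recycled); relative
#'   abundances are proportional to `exp(base_abundance + scale * latent +
#'   covariate effects)` within each sample.
#' @param scale Latent-to-log-abundance scale. Default 1.
#' @param zero_inflation Per-OTU probability of structural absence in a
#'   sample (recycled). Default 0.
#' @param age_slope,run_effect Covariate effects on the latent log scale:
#'   slope on standardized age and additive offset for the second
#'   sequencing run (recycled per OTU).  Nonzero defaults exercise the
#'   residualization stage.
#' @param library_size Mean reads per sample (Poisson). Default 81318.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_mz = 473L, n_dz = 402L, n_otus = 50L,
                              A = c(0, 0.1, 0.2, 0.3, 0.4), C = 0.1,
                              base_abundance = NULL, scale = 1,
                              zero_inflation = 0,
                              age_slope = 0.1, run_effect = 0.3,
                              library_size = 81318, seed = 1L) {
  A <- rep_len(A, n_otus); C <- rep_len(C, n_otus)
  E <- 1 - A - C
  if (any(c(A, C, E) < 0)) stop("A, C and E = 1 - A - C must all be >= 0")
  if (is.null(base_abundance))
    base_abundance <- seq(-2, 2, length.out = n_otus)
  structure(list(
    n_mz = n_mz, n_dz = n_dz, n_otus = n_otus,
    A = A, C = C, E = E,
    base_abundance = rep_len(base_abundance, n_otus),
    scale = scale,
    zero_inflation = rep_len(zero_inflation, n_otus),
    age_slope = rep_len(age_slope, n_otus),
    run_effect = rep_len(run_effect, n_otus),
    library_size = library_size, seed = seed
  ), class = "sim_config")
}

#' Simulate a twin-paired OTU count table
#'
#' Generates, per OTU, a latent twin trait with the configured A/C/E
#' structure ([simulate_twin_traits]), adds covariate effects on the
#' latent log scale, maps latent values to expected within-sample relative
#' abundances through a log-linear link, applies structural zeros, and
#' draws counts multinomially at a Poisson-distributed library size.
#' Generated metadata covariates: gender (balanced, shared within pair),
#' age (uniform 20-80, shared within pair), sequencing_run (2 runs),
#' sequencing_depth (the realized library size), collection_method and
#' technician (2 levels each).
#'
#' @param config A [simulation_config].
#' @return List of class `sim_dataset` with `table` (an [otu_table]),
#'   `records` (metadata data frame as from [read_metadata]) and `truth`
#'   (the config plus the realized latent trait matrix, OTUs x samples).
#' @export
simulate_twin_otu_table <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pairs <- config$n_mz + config$n_dz
  n_samples <- 2L * n_pairs
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  family_id <- sprintf("F%04d", rep(seq_len(n_pairs), each = 2L))
  zygosity <- rep(c("MZ", "DZ"), c(2L * config$n_mz, 2L * config$n_dz))

  age_fam <- stats::runif(n_pairs, 20, 80)
  records <- data.frame(
    sample_id = sample_id, family_id = family_id, zygosity = zygosity,
    gender = rep(rep_len(c("F", "M"), n_pairs), each = 2L),
    age = rep(age_fam, each = 2L),
    sequencing_run = sample(c("run1", "run2"), n_samples, replace = TRUE),
    sequencing_depth = NA_real_,
    collection_method = sample(c("home", "clinic"), n_samples,
                               replace = TRUE),
    technician = sample(c("tech1", "tech2"), n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## latent traits, one row per OTU; sample order is pair-interleaved
  ## (twin 1, twin 2) matching `records`
  latent <- matrix(NA_real_, config$n_otus, n_samples,
                   dimnames = list(sprintf("OTU%03d",
                                           seq_len(config$n_otus)),
                                   sample_id))
  mz_cols1 <- seq(1L, 2L * config$n_mz, by = 2L)
  dz_cols1 <- seq(2L * config$n_mz + 1L, n_samples, by = 2L)
  for (j in seq_len(config$n_otus)) {
    pt <- simulate_twin_traits(config$n_mz, config$n_dz,
                               config$A[j], config$C[j], config$E[j])
    latent[j, mz_cols1] <- pt$mz[, 1L]; latent[j, mz_cols1 + 1L] <- pt$mz[, 2L]
    latent[j, dz_cols1] <- pt$dz[, 1L]; latent[j, dz_cols1 + 1L] <- pt$dz[, 2L]
  }

  age_std <- (records$age - 50) / 17.32          # sd of U(20, 80)
  run2 <- as.numeric(records$sequencing_run == "run2")
  eta <- config$base_abundance + config$scale * latent +
    outer(config$age_slope, age_std) + outer(config$run_effect, run2)

  present <- matrix(stats::runif(length(eta)) >= config$zero_inflation,
                    nrow(eta), ncol(eta))
  w <- exp(eta) * present
  lib <- stats::rpois(n_samples, config$library_size)
  counts <- matrix(0L, config$n_otus, n_samples, dimnames = dimnames(latent))
  for (i in seq_len(n_samples)) {
    if (lib[i] == 0L || sum(w[, i]) == 0) next
    counts[, i] <- stats::rmultinom(1L, lib[i], w[, i])[, 1L]
  }
  records$sequencing_depth <- colSums(counts)

  structure(list(
    table = otu_table(counts, "truth"),
    records = as_sample_records(records,
                                factor_covariates = c("sequencing_run",
                                                      "collection_method",
                                                      "technician",
                                                      "gender")),
    truth = list(config = config, latent = latent)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic twin microbiome dataset:\n  ")
  print(x$table)
  cat("  ", x$truth$config$n_mz, " MZ / ", x$truth$config$n_dz,
      " DZ pairs\n", sep = "")
  invisible(x)
}

## Dirichlet weights for k children: concentration alpha = 1/noise - 1,
## so noise -> 0 gives deterministic equal shares and noise = 0.5 a
## uniform Dirichlet.
rdirichlet_row <- function(n, k, noise) {
  alpha <- 1 / noise - 1
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  bad <- rowSums(g) == 0
  g[bad, ] <- 1
  g / rowSums(g)
}

#' Perturb an OTU table to emulate an alternative clustering method
#'
#' `mode = "split"` reassigns each selected OTU's reads among `k` child
#' OTUs: per sample, the child proportions are drawn from a symmetric
#' Dirichlet whose concentration is controlled by `noise`
#' (`noise = 0` gives exact equal shares; larger values give noisier,
#' sample-dependent fractions), and reads are distributed multinomially.
#' This mimics a clustering method that splits one biological unit across
#' several OTUs, diluting its abundance signal.  `mode = "merge"` sums
#' randomly chosen unrelated OTUs in groups of `k`, mimicking a method
#' that lumps distinct units together.  Per-sample column totals are
#' conserved in both modes.
#'
#' @param table An [otu_table].
#' @param mode `"split"` or `"merge"`.
#' @param k Children per split (>= 2) or group size for merge.
#' @param noise Split noise level in \[0, 1). Default 0.5.
#' @param seed Integer seed.
#' @param otus OTU ids to perturb (split mode); default all.
#' @return An [otu_table] with method label
#'   `"<label>_split<k>"` or `"<label>_merge<k>"`.
#' @export
perturb_clustering <- function(table, mode = c("split", "merge"), k = 2L,
                               noise = 0.5, seed = 1L, otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  mode <- match.arg(mode)
  set.seed(seed)
  m <- table$counts
  n_s <- ncol(m)

  if (mode == "split") {
    if (k < 2L) stop("split requires k >= 2")
    if (is.null(otus)) otus <- rownames(m)
    out <- vector("list", length(otus))
    names(out) <- otus
    for (id in otus) {
      parent <- m[id, ]
      child <- matrix(0L, k, n_s,
                      dimnames = list(paste0(id, "_c", seq_len(k)), NULL))
      if (noise <= 0) {
        base <- parent %/% k
        rem <- parent %% k
        for (j in seq_len(k))
          child[j, ] <- as.integer(base + (rem >= j))
      } else {
        w <- rdirichlet_row(n_s, k, noise)
        remaining <- parent
        wsum <- rep(1, n_s)
        for (j in seq_len(k - 1L)) {
          pj <- pmin(pmax(w[, j] / wsum, 0), 1)
          draw <- stats::rbinom(n_s, remaining, pj)
          child[j, ] <- as.integer(draw)
          remaining <- remaining - draw
          wsum <- wsum - w[, j]
        }
        child[k, ] <- as.integer(remaining)
      }
      out[[id]] <- child
    }
    keep <- m[setdiff(rownames(m), otus), , drop = FALSE]
    res <- rbind(keep, do.call(rbind, out))
    colnames(res) <- colnames(m)
    return(otu_table(res, paste0(table$method_label, "_split", k)))
  }

  ## merge
  if (nrow(m) < 2L) stop("merge requires at least 2 OTUs")
  ord <- sample(nrow(m))
  grp <- ceiling(seq_along(ord) / k)
  key <- character(nrow(m))
  for (g in unique(grp)) {
    members <- rownames(m)[ord[grp == g]]
    key[ord[grp == g]] <- paste(members, collapse = "+")
  }
  res <- rowsum(m, group = key, reorder = TRUE)
  storage.mode(res) <- "integer"
  otu_table(res, paste0(table$method_label, "_merge", k))
}
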