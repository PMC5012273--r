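#' Rarefy a count vector to fixed depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric),
#' so the output sums to exactly `depth`.
#'
#' @param counts Non-negative integer vector with `sum(counts) >= depth`.
#' @param depth Target number of reads.
#' @param seed Optional integer seed (set before drawing).
#' @return Integer vector, same length as `counts`, summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(counts) < depth)
    stop("total count below rarefaction depth")
  ## vegan warns when no count equals 1 (a heuristic for non-count data);
  ## totals are validated above, so that warning is spurious here
  suppressWarnings(drop(vegan::rrarefy(matrix(counts, nrow = 1L), depth)))
}

#' Shannon diversity index
#'
#' `H = -sum p_i log_base(p_i)` over the nonzero proportions.  Base 2 by
#' default (the convention of common 16S pipelines); use `base = exp(1)`
#' for nats.
#'
#' @param counts Non-negative count (or proportion) vector with positive
#'   sum.
#' @param base Logarithm base. Default 2.
#' @return Scalar diversity.
#' @export
shannon <- function(counts, base = 2) {
  if (sum(counts) <= 0) stop("empty community")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Simpson diversity index
#'
#' `1 - sum p_i^2`: the probability that two reads drawn at random are
#' from different OTUs.
#'
#' @inheritParams shannon
#' @return Scalar in \[0, 1).
#' @export
simpson <- function(counts) {
  if (sum(counts) <= 0) stop("empty community")
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Chao1 richness estimate
#'
#' With `S_obs` observed OTUs, `F1` singletons and `F2` doubletons, the
#' bias-corrected form is `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` and the
#' classic form `S_obs + F1^2 / (2 F2)`.  The classic form is undefined at
#' `F2 = 0` with singletons present; it then falls back to the
#' bias-corrected form with a warning.
#'
#' @param counts Non-negative integer vector with positive sum.
#' @param bias_corrected Use the bias-corrected form. Default TRUE.
#' @return Scalar richness estimate.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (sum(counts) <= 0) stop("empty community")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (!bias_corrected) {
    if (f2 == 0 && f1 > 0) {
      warning("no doubletons: classic Chao1 undefined, ",
              "using bias-corrected form")
    } else if (f2 > 0) {
      return(s_obs + f1^2 / (2 * f2))
    } else {
      return(s_obs)
    }
  }
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Observed OTU count
#'
#' @param counts Non-negative count vector.
#' @return Integer number of OTUs with a positive count.
#' @export
observed_otus <- function(counts) sum(counts > 0)

#' Rarefaction-based alpha diversity per sample
#'
#' Each sample is rarefied to `depth` reads `reps` times (replicate `r`
#' seeds the RNG with `seed + r`) and each metric is averaged over the
#' replicates.  Samples whose total count is below `depth` are dropped and
#' listed in the result.
#'
#' @param table An [otu_table].
#' @param depth Rarefaction depth in reads. Default 10000.
#' @param reps Number of rarefaction replicates. Default 25.
#' @param seed Base RNG seed. Default 1.
#' @param shannon_base Log base for the Shannon index. Default 2.
#' @param chao1_bias_corrected Chao1 variant flag. Default TRUE.
#' @return Object of class `diversity_profile`: list with `method_label`,
#'   `values` (data frame: sample_id and mean shannon, simpson, chao1,
#'   observed_otus), `depth`, `n_reps`, `dropped_samples`.
#' @export
alpha_diversity <- function(table, depth = 10000L, reps = 25L, seed = 1L,
                            shannon_base = 2,
                            chao1_bias_corrected = TRUE) {
  stopifnot(inherits(table, "otu_table"), depth >= 1, reps >= 1)
  tot <- colSums(table$counts)
  dropped <- colnames(table$counts)[tot < depth]
  keep <- tot >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  m <- t(table$counts[, keep, drop = FALSE])    # samples x OTUs for vegan

  acc <- matrix(0, nrow(m), 4L,
                dimnames = list(rownames(m),
                                c("shannon", "simpson", "chao1",
                                  "observed_otus")))
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    rf <- suppressWarnings(vegan::rrarefy(m, depth))
    acc[, "shannon"] <- acc[, "shannon"] +
      vegan::diversity(rf, "shannon", base = shannon_base)
    acc[, "simpson"] <- acc[, "simpson"] + vegan::diversity(rf, "simpson")
    acc[, "chao1"] <- acc[, "chao1"] +
      apply(rf, 1L, chao1, bias_corrected = chao1_bias_corrected)
    acc[, "observed_otus"] <- acc[, "observed_otus"] + rowSums(rf > 0)
  }
  vals <- data.frame(sample_id = rownames(m), acc / reps,
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(method_label = table$method_label, values = vals,
                 depth = depth, n_reps = reps,
                 dropped_samples = dropped),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("Alpha diversity [", x$method_label, "]: ", nrow(x$values),
      " samples, depth ", x$depth, " x ", x$n_reps, " rarefactions\n",
      sep = "")
  if (length(x$dropped_samples))
    cat("  dropped (below depth):", length(x$dropped_samples), "samples\n")
  invisible(x)
}

#' Kendall tau-b rank correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar tau-b (tie-corrected).
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  stats::cor(x, y, method = "kendall")
}

#' Cross-method concordance of alpha diversity
#'
#' For one metric, compares profiles over their shared (non-dropped)
#' samples: Mann-Whitney U tests with BH correction contrast the absolute
#' values between methods, and a Kendall tau-b matrix measures the
#' concordance of the sample rankings.
#'
#' @param profiles List of `diversity_profile` objects.
#' @param metric One of `"shannon"`, `"simpson"`, `"chao1"`,
#'   `"observed_otus"`.
#' @return List with `tests` (data frame: method_a, method_b, metric, U,
#'   p, q), `tau` (symmetric matrix of tau-b values), `shared_samples`.
#' @export
compare_alpha <- function(profiles, metric = c("shannon", "simpson",
                                               "chao1", "observed_otus")) {
  metric <- match.arg(metric)
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1),
                       "diversity_profile")))
  labs <- vapply(profiles, `[[`, character(1), "method_label")
  shared <- Reduce(intersect, lapply(profiles, function(p)
    p$values$sample_id))
  if (length(shared) < 3L)
    stop("fewer than 3 samples shared across profiles")
  vals <- vapply(profiles, function(p)
    p$values[[metric]][match(shared, p$values$sample_id)],
    numeric(length(shared)))
  colnames(vals) <- labs

  idx <- utils::combn(length(profiles), 2L)
  rows <- apply(idx, 2L, function(ij) {
    mw <- mann_whitney_u(vals[, ij[1L]], vals[, ij[2L]])
    data.frame(method_a = labs[ij[1L]], method_b = labs[ij[2L]],
               metric = metric, U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$q <- bh_adjust(tests$p)

  tau <- stats::cor(vals, method = "kendall")
  list(tests = tests, tau = tau, shared_samples = shared)
}
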