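#' Filter OTUs by prevalence
#'
#' Prevalence is the fraction of samples in which an OTU has a nonzero
#' count.  It must be computed on the raw counts, before any pseudo-count
#' is added.  The comparison is inclusive: an OTU present in exactly
#' `min_fraction` of samples is retained.
#'
#' @param table An [otu_table] of raw counts.
#' @param min_fraction Minimum fraction of samples with a nonzero count,
#'   in (0, 1]. Default 0.5.
#' @return An [otu_table] restricted to the prevalent OTUs; the sample set
#'   is unchanged.  May contain zero OTUs.
#' @export
prevalence_filter <- function(table, min_fraction = 0.5) {
  stopifnot(inherits(table, "otu_table"),
            min_fraction > 0, min_fraction <= 1)
  prev <- rowMeans(table$counts > 0)
  keep <- prev >= min_fraction
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  out
}

#' Add a pseudo-count to every cell
#'
#' Removes zeros ahead of the relative-abundance and power-transform steps.
#'
#' @param table An [otu_table].
#' @param value Positive integer added to every cell. Default 1.
#' @return An [otu_table] with all cells incremented by `value`.
#' @export
add_pseudocount <- function(table, value = 1L) {
  stopifnot(inherits(table, "otu_table"), value >= 1, value == round(value))
  out <- table
  out$counts <- table$counts + as.integer(value)
  out
}

#' Convert counts to within-sample relative abundances
#'
#' @param table An [otu_table]; every sample (column) total must be positive.
#' @return A list of class `abundance_table` with `rel_abundance` (matrix of
#'   proportions; columns sum to 1), `method_label` and the dimnames of the
#'   input.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  structure(list(
    rel_abundance = sweep(table$counts, 2L, tot, "/"),
    method_label = table$method_label
  ), class = "abundance_table")
}

## Box-Cox power transform of a positive vector.
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

## Profile log-likelihood of the normal linear model y(lambda) ~ design,
## with the Jacobian term (lambda - 1) * sum(log y).  `qrx` is a precomputed
## qr() of the design matrix.
boxcox_profile_loglik <- function(lambda, y, qrx, sum_log_y) {
  n <- length(y)
  rss <- sum(qr.resid(qrx, boxcox_transform(y, lambda))^2)
  -(n / 2) * log(rss / n) + (lambda - 1) * sum_log_y
}

#' Estimate a Box-Cox lambda by profile likelihood
#'
#' Finds the power-transform exponent maximizing the profile log-likelihood
#' of the linear model `y(lambda) ~ design`, where
#' `y(lambda) = (y^lambda - 1) / lambda` (natural log at `lambda = 0`).
#' A coarse grid over the search range brackets the optimum, which is then
#' refined by bounded scalar optimization.
#'
#' @param y Positive response values.
#' @param design Design matrix including an intercept column.
#' @param range Search range for lambda. Default `c(-5, 5)`.
#' @param grid_step Coarse grid step. Default 0.1.
#' @return List with `lambda`, `loglik` (profile log-likelihood at the
#'   optimum) and `n`.
#' @export
boxcox_lambda <- function(y, design, range = c(-5, 5), grid_step = 0.1) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values")
  design <- as.matrix(design)
  stopifnot(length(y) == nrow(design))
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    drop_cols <- colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  sly <- sum(log(y))
  grid <- seq(range[1L], range[2L], by = grid_step)
  ll <- vapply(grid, boxcox_profile_loglik, numeric(1),
               y = y, qrx = qrx, sum_log_y = sly)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(boxcox_profile_loglik, c(lo, hi), maximum = TRUE,
                         y = y, qrx = qrx, sum_log_y = sly,
                         tol = .Machine$double.eps^0.5)
  list(lambda = opt$maximum, loglik = opt$objective, n = length(y))
}

#' Covariate-adjusted, standardized residuals
#'
#' Ordinary least-squares residuals of `y` on the design, centred (exactly,
#' through the intercept) and scaled to unit sample variance.
#'
#' @param y Numeric response (typically a Box-Cox transformed abundance).
#' @param design Design matrix including an intercept column.
#' @return Numeric vector of standardized residuals, with attribute
#'   `"degenerate"` set to TRUE when the residual variance is below 1e-12
#'   (the residuals are then returned unscaled).
#' @export
covariate_residuals <- function(y, design) {
  design <- as.matrix(design)
  stopifnot(length(y) == nrow(design))
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    drop_cols <- colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  r <- qr.resid(qrx, y)
  v <- stats::var(r)
  if (!is.finite(v) || v < 1e-12) {
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  r <- r / sqrt(v)
  attr(r, "degenerate") <- FALSE
  r
}

#' Build a covariate design matrix from sample metadata
#'
#' Numeric covariates enter as-is; categorical covariates are one-hot
#' encoded with the alphabetically first level as reference (dropped).
#' An intercept column is always included.
#'
#' @param records Metadata data frame (rows in the desired sample order).
#' @param covariate_names Covariate columns to include.
#' @return Numeric design matrix with one row per record.
#' @export
build_design <- function(records, covariate_names) {
  stopifnot(all(covariate_names %in% colnames(records)))
  df <- records[, covariate_names, drop = FALSE]
  for (cv in covariate_names)
    if (!is.numeric(df[[cv]]))
      df[[cv]] <- factor(df[[cv]], levels = sort(unique(df[[cv]])))
  if (length(covariate_names) == 0L)
    return(matrix(1, nrow(records), 1L,
                  dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = df)
}

#' Prepare per-OTU residual traits for heritability modelling
#'
#' Runs the preprocessing pipeline: prevalence is recorded on raw counts,
#' a pseudo-count is added, counts become within-sample relative
#' abundances, the table is subset to the prevalent OTUs, and each OTU is
#' Box-Cox transformed (lambda by profile likelihood against the covariate
#' model) and residualized on the covariates, the residuals standardized to
#' unit variance.
#'
#' @param table An [otu_table] of raw counts.
#' @param pairs A [pair_samples] result; traits are computed on its samples
#'   only, in pair order.
#' @param covariate_names Covariates to adjust for; defaults to the set
#'   recorded in `pairs`.
#' @param min_fraction Prevalence threshold (see [prevalence_filter]).
#' @param pseudocount Pseudo-count value (see [add_pseudocount]).
#' @param lambda_range,grid_step Passed to [boxcox_lambda].
#' @return Object of class `trait_matrix`: list with `values` (matrix, OTUs
#'   x samples, standardized residuals), `method_label`, `pairs` and
#'   `transform_log` (data frame: otu_id, lambda, loglik, n_samples,
#'   degenerate).  Degenerate OTUs (residual variance < 1e-12) are dropped
#'   with a warning.
#' @export
prepare_traits <- function(table, pairs, covariate_names = NULL,
                           min_fraction = 0.5, pseudocount = 1L,
                           lambda_range = c(-5, 5), grid_step = 0.1) {
  stopifnot(inherits(table, "otu_table"), inherits(pairs, "twin_pairs"))
  if (is.null(covariate_names)) covariate_names <- pairs$covariate_names

  samp <- c(rbind(pairs$pairs$sample_1, pairs$pairs$sample_2))
  missing <- setdiff(samp, sample_ids(table))
  if (length(missing))
    stop("paired sample(s) absent from table: ",
         paste(missing, collapse = ", "))
  sub <- table
  sub$counts <- table$counts[, samp, drop = FALSE]

  prevalent <- otu_ids(prevalence_filter(sub, min_fraction))
  if (length(prevalent) == 0L)
    stop("no OTUs pass the prevalence filter")
  rel <- to_relative_abundance(add_pseudocount(sub, pseudocount))
  ab <- rel$rel_abundance[prevalent, , drop = FALSE]

  rec <- pairs$records[match(samp, pairs$records$sample_id), , drop = FALSE]
  design <- build_design(rec, covariate_names)

  values <- matrix(NA_real_, nrow(ab), ncol(ab),
                   dimnames = dimnames(ab))
  log_df <- data.frame(otu_id = rownames(ab),
                       lambda = NA_real_, loglik = NA_real_,
                       n_samples = ncol(ab), degenerate = FALSE,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ab))) {
    y <- ab[i, ]
    bc <- boxcox_lambda(y, design, range = lambda_range,
                        grid_step = grid_step)
    r <- covariate_residuals(boxcox_transform(y, bc$lambda), design)
    log_df$lambda[i] <- bc$lambda
    log_df$loglik[i] <- bc$loglik
    log_df$degenerate[i] <- isTRUE(attr(r, "degenerate"))
    values[i, ] <- r
  }
  if (any(log_df$degenerate)) {
    warning(sum(log_df$degenerate),
            " OTU(s) with degenerate residual variance excluded: ",
            paste(log_df$otu_id[log_df$degenerate], collapse = ", "))
    values <- values[!log_df$degenerate, , drop = FALSE]
  }
  structure(list(values = values,
                 method_label = table$method_label,
                 pairs = pairs,
                 covariate_names = covariate_names,
                 transform_log = log_df),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix [", x$method_label, "]: ", nrow(x$values),
      " OTU traits x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Write the per-OTU transform log as TSV
#' @param x A `trait_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_log <- function(x, path) {
  stopifnot(inherits(x, "trait_matrix"))
  utils::write.table(x$transform_log[, c("otu_id", "lambda", "loglik",
                                         "n_samples")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
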