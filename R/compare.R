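#' Mann-Whitney U test
#'
#' The U statistic counts, over all cross pairs, the times an `x` value
#' exceeds a `y` value, with ties counted one half (midranks).  The
#' p-value is exact (full enumeration) when `length(x) + length(y) <= 12`
#' and there are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative Only `"two.sided"` is offered.
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, "two.sided")
  if (length(x) < 1L || length(y) < 1L) stop("empty input")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
  list(U = U, p = min(p, 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' original input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare heritability-estimate distributions between methods
#'
#' Pairwise Mann-Whitney U tests on the OTU-level estimates of one variance
#' component, with one Benjamini-Hochberg adjustment across the whole
#' family of pairwise tests for that component.
#'
#' @param profiles List of `herit_profile` objects (see [fit_all]).
#' @param component `"A"`, `"C"` or `"E"`.
#' @return Data frame of class `comparison_table`: `method_a`, `method_b`,
#'   `component`, `U`, `p`, `q`, one row per unordered method pair.
#' @export
compare_profiles <- function(profiles, component = c("A", "C", "E")) {
  component <- match.arg(component)
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "herit_profile")))
  ok <- vapply(profiles, function(p)
    sum(is.finite(p$estimates[[component]])) >= 2L, logical(1))
  if (any(!ok)) {
    warning("profile(s) with < 2 estimates excluded: ",
            paste(vapply(profiles[!ok], `[[`, character(1), "method_label"),
                  collapse = ", "))
    profiles <- profiles[ok]
  }
  if (length(profiles) < 2L) stop("fewer than 2 usable profiles")
  labs <- vapply(profiles, `[[`, character(1), "method_label")
  idx <- utils::combn(length(profiles), 2L)
  rows <- apply(idx, 2L, function(ij) {
    xa <- profiles[[ij[1L]]]$estimates[[component]]
    xb <- profiles[[ij[2L]]]$estimates[[component]]
    mw <- mann_whitney_u(xa[is.finite(xa)], xb[is.finite(xb)])
    data.frame(method_a = labs[ij[1L]], method_b = labs[ij[2L]],
               component = component, U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Select heritable units from a profile
#'
#' Keeps units whose A estimate strictly exceeds `global_mean` (typically
#' the mean A over the pooled OTUs of all methods under comparison) and
#' whose lower 95% profile CI for A is at least `ci_floor`.
#'
#' @param profile A `herit_profile` whose estimates carry `ci_A_lower`.
#' @param global_mean Threshold on A (strict inequality).
#' @param ci_floor Minimum lower CI bound (inclusive). Default 0.01.
#' @return A `herit_profile` restricted to the selected units.
#' @export
heritable_subset <- function(profile, global_mean, ci_floor = 0.01) {
  stopifnot(inherits(profile, "herit_profile"))
  est <- profile$estimates
  keep <- !is.na(est$A) & !is.na(est$ci_A_lower) &
    est$A > global_mean & est$ci_A_lower >= ci_floor
  out <- profile
  out$estimates <- est[keep, , drop = FALSE]
  out$mean_A <- mean(out$estimates$A)
  out
}

#' Pooled mean heritability across profiles
#'
#' The single global threshold used by the heritable-unit filter: the mean
#' of the A estimates pooled over the OTUs of every profile.
#'
#' @param profiles List of `herit_profile` objects.
#' @return Scalar mean A.
#' @export
pooled_mean_A <- function(profiles) {
  a <- unlist(lapply(profiles, function(p) p$estimates$A))
  mean(a, na.rm = TRUE)
}

#' Summarize a heritability profile
#'
#' Location summaries per component plus a Gaussian kernel density export
#' (bandwidth by Silverman's rule of thumb) suitable for plotting the
#' distribution of estimates.
#'
#' @param profile A `herit_profile`.
#' @return List with `stats` (data frame: component, n, mean, median, q1,
#'   q3) and `density` (data frame: component, grid, value).
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "herit_profile"),
            nrow(profile$estimates) >= 1L)
  comps <- intersect(c("A", "C", "E"), colnames(profile$estimates))
  stats_df <- do.call(rbind, lapply(comps, function(cc) {
    v <- profile$estimates[[cc]]
    v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(component = cc, n = length(v), mean = mean(v),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               stringsAsFactors = FALSE)
  }))
  dens_df <- do.call(rbind, lapply(comps, function(cc) {
    v <- profile$estimates[[cc]]
    v <- v[is.finite(v)]
    if (length(v) < 2L || stats::sd(v) == 0) return(NULL)
    d <- stats::density(v, bw = "nrd0")
    data.frame(component = cc, grid = d$x, value = d$y,
               stringsAsFactors = FALSE)
  }))
  list(method_label = profile$method_label, stats = stats_df,
       density = dens_df)
}
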