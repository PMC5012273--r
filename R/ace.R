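#' Paired twin trait data
#'
#' Container for one quantitative trait measured on complete MZ and DZ twin
#' pairs, the unit of data for the ACE model.
#'
#' @param mz Two-column numeric matrix of MZ pair values (one row per pair).
#' @param dz Two-column numeric matrix of DZ pair values.
#' @param otu_id Optional identifier for the trait.
#' @return Object of class `paired_trait`.
#' @export
paired_trait <- function(mz, dz, otu_id = NA_character_) {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  stopifnot(ncol(mz) == 2L, ncol(dz) == 2L,
            !anyNA(mz), !anyNA(dz))
  structure(list(mz = mz, dz = dz, otu_id = otu_id),
            class = "paired_trait")
}

#' @export
print.paired_trait <- function(x, ...) {
  cat("Paired trait", if (!is.na(x$otu_id)) paste0("[", x$otu_id, "]"),
      ":", nrow(x$mz), "MZ pairs,", nrow(x$dz), "DZ pairs\n")
  invisible(x)
}

## Sufficient statistics per zygosity group.  The bivariate-normal
## log-likelihood with common mean depends on the data only through
## n, sum(y1 + y2), sum(y1^2 + y2^2) and sum(y1 * y2), which makes each
## likelihood evaluation O(1) regardless of the number of pairs.
pair_suffstats <- function(m) {
  list(n  = nrow(m),
       s1 = sum(m),
       s2 = sum(m^2),
       sx = sum(m[, 1L] * m[, 2L]))
}

## log-likelihood of one zygosity group given total variance v,
## within-pair covariance cv and mean mu.
group_loglik <- function(ss, v, cv, mu) {
  det <- v * v - cv * cv
  if (!is.finite(det) || det <= 0 || v <= 0) return(-Inf)
  qsum <- ss$s2 - 2 * mu * ss$s1 + 2 * ss$n * mu^2          # sum (d1^2+d2^2)
  qcross <- ss$sx - mu * ss$s1 + ss$n * mu^2                # sum d1*d2
  -ss$n * log(2 * pi) - (ss$n / 2) * log(det) -
    (v * qsum - 2 * cv * qcross) / (2 * det)
}

#' ACE model log-likelihood
#'
#' Log-likelihood of a twin ACE model at path coefficients `(a, c, e)` and
#' common mean `mu`.  Both twins have variance `a^2 + c^2 + e^2`; the
#' within-pair covariance is `a^2 + c^2` for MZ pairs (identical genomes)
#' and `a^2 / 2 + c^2` for DZ pairs, who share on average half their
#' segregating genetic material; the shared-environment covariance `c^2`
#' is assumed equal across zygosities.  Returns `-Inf` when the implied
#' 2x2 covariance matrix is numerically singular.
#'
#' @param a,c,e Path coefficients (additive genetic, common environment,
#'   unique environment).
#' @param mu Common mean.
#' @param data A [paired_trait].
#' @return Scalar log-likelihood.
#' @export
ace_loglik <- function(a, c, e, mu, data) {
  stopifnot(inherits(data, "paired_trait"))
  v  <- a^2 + c^2 + e^2
  group_loglik(pair_suffstats(data$mz), v, a^2 + c^2, mu) +
    group_loglik(pair_suffstats(data$dz), v, a^2 / 2 + c^2, mu)
}

#' Falconer closed-form ACE estimates
#'
#' Classical estimates from double-entered Pearson within-pair
#' correlations: `A = 2 (rMZ - rDZ)`, `C = 2 rDZ - rMZ`, `E = 1 - rMZ`.
#' Values are not clipped and may fall outside \[0, 1\]; callers using them
#' as starting values clip them.
#'
#' @param data A [paired_trait] with at least 2 pairs per zygosity.
#' @return Named vector `c(A =, C =, E =)`.
#' @export
falconer_estimate <- function(data) {
  stopifnot(inherits(data, "paired_trait"),
            nrow(data$mz) >= 2L, nrow(data$dz) >= 2L)
  r_de <- function(m) {
    x <- c(m[, 1L], m[, 2L]); y <- c(m[, 2L], m[, 1L])
    if (stats::sd(x) == 0) stop("zero variance within a zygosity group")
    stats::cor(x, y)
  }
  r_mz <- r_de(data$mz); r_dz <- r_de(data$dz)
  c(A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz, E = 1 - r_mz)
}

## negative log-likelihood over theta = (a, c, e, mu) using precomputed
## sufficient statistics; large finite value instead of Inf for L-BFGS-B.
ace_nll <- function(theta, ss_mz, ss_dz) {
  v <- theta[1L]^2 + theta[2L]^2 + theta[3L]^2
  ll <- group_loglik(ss_mz, v, theta[1L]^2 + theta[2L]^2, theta[4L]) +
    group_loglik(ss_dz, v, theta[1L]^2 / 2 + theta[2L]^2, theta[4L])
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the twin ACE model by maximum likelihood
#'
#' Maximizes the bivariate-normal ACE likelihood over the path coefficients
#' `(a, c, e)` and a single common mean, with `a, c, e >= 0` so that all
#' variance components are non-negative by construction.  Bounded
#' quasi-Newton optimization is run from several starts: one derived from
#' the (clipped) Falconer estimates, the rest jittered around it; the best
#' solution is returned.
#'
#' @param data A [paired_trait] with at least 2 pairs per zygosity.
#' @param multistart Number of optimization starts. Default 5.
#' @param tol Relative convergence tolerance passed to [stats::optim].
#' @param seed Optional integer; when given, the start-point jitter is
#'   drawn reproducibly without disturbing the global RNG stream.
#' @param ci Compute the profile-likelihood CI for A (see
#'   [confint.ace_fit]) and store it in the fit. Default FALSE.
#' @param level Confidence level for `ci`.
#' @return Object of class `ace_fit`: path coefficients `a`, `c`, `e`,
#'   standardized variance proportions `A`, `C`, `E`, mean `mu`, `loglik`,
#'   `converged`, pair counts `n_mz`/`n_dz`, and the data (for profiling).
#' @examples
#' set.seed(1)
#' sim <- simulate_twin_traits(200, 200, A = 0.4, C = 0.2, E = 0.4)
#' fit <- fit_ace(sim)
#' coef(fit)
#' @export
fit_ace <- function(data, multistart = 5L, tol = 1e-8, seed = NULL,
                    ci = FALSE, level = 0.95) {
  stopifnot(inherits(data, "paired_trait"))
  if (nrow(data$mz) < 2L || nrow(data$dz) < 2L)
    stop("need at least 2 pairs per zygosity group")
  all_y <- c(data$mz, data$dz)
  vtot <- stats::var(all_y)
  if (vtot < 1e-12) stop("trait has (near) zero variance")
  mu0 <- mean(all_y)

  ## optimize on the standardized scale so that the fit (and hence the
  ## standardized A/C/E) is exactly invariant to affine rescaling of the
  ## trait; path coefficients and mean are mapped back afterwards
  s_tot <- sqrt(vtot)
  zdata <- paired_trait((data$mz - mu0) / s_tot, (data$dz - mu0) / s_tot)
  ss_mz <- pair_suffstats(zdata$mz)
  ss_dz <- pair_suffstats(zdata$dz)

  falc <- tryCatch(falconer_estimate(data),
                   error = function(e) c(A = 1/3, C = 1/3, E = 1/3))
  props <- pmin(pmax(falc, 0.02), 0.96)
  props <- props / sum(props)
  start0 <- c(sqrt(props), 0)

  jit <- matrix(0, multistart, 4L)
  if (multistart > 1L) {
    rng <- if (is.null(seed)) stats::runif((multistart - 1L) * 3L) else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      u <- stats::runif((multistart - 1L) * 3L)
      if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
        rm(".Random.seed", envir = globalenv())
      u
    }
    jit[-1L, 1:3] <- matrix(rng - 0.5, ncol = 3L)
  }

  lower <- c(0, 0, 1e-8, -Inf)
  best <- NULL
  converged <- FALSE
  start_ll <- -Inf
  for (k in seq_len(multistart)) {
    st <- start0 * c(exp(jit[k, 1:3]), 1) + c(0, 0, 0, jit[k, 4L])
    st[1:3] <- pmax(st[1:3], c(lower[1:3]))
    start_ll <- max(start_ll, -ace_nll(st, ss_mz, ss_dz))
    o <- tryCatch(
      stats::optim(st, ace_nll, method = "L-BFGS-B", lower = lower,
                   ss_mz = ss_mz, ss_dz = ss_dz,
                   control = list(factr = 10, pgtol = tol * 1e-4,
                                  maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) {
      best <- o
      converged <- o$convergence == 0L
    }
  }
  if (is.null(best)) stop("all optimization starts failed")

  theta <- abs(unname(best$par[1:3]))
  v <- sum(theta^2)
  n_obs <- 2 * (nrow(data$mz) + nrow(data$dz))
  fit <- structure(list(
    a = theta[1L] * s_tot, c = theta[2L] * s_tot, e = theta[3L] * s_tot,
    A = theta[1L]^2 / v, C = theta[2L]^2 / v, E = theta[3L]^2 / v,
    mu = mu0 + unname(best$par[4L]) * s_tot,
    loglik = -best$value - n_obs * log(s_tot),
    start_loglik = start_ll - n_obs * log(s_tot),
    converged = converged,
    n_mz = nrow(data$mz), n_dz = nrow(data$dz),
    otu_id = data$otu_id,
    data = data
  ), class = "ace_fit")
  if (ci) fit$ci_A <- profile_ci(fit, "A", level = level)
  fit
}

#' @export
print.ace_fit <- function(x, digits = 3, ...) {
  cat("Twin ACE model fit",
      if (!is.na(x$otu_id)) paste0("[", x$otu_id, "]"), "\n")
  cat("  pairs: ", x$n_mz, " MZ, ", x$n_dz, " DZ\n", sep = "")
  cat("  A = ", format(x$A, digits = digits),
      "  C = ", format(x$C, digits = digits),
      "  E = ", format(x$E, digits = digits), "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = digits + 3),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, type = c("proportions", "paths"), ...) {
  type <- match.arg(type)
  if (type == "proportions")
    c(A = object$A, C = object$C, E = object$E)
  else
    c(a = object$a, c = object$c, e = object$e, mu = object$mu)
}

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$n_mz + object$n_dz,
            class = "logLik")
}

#' @export
summary.ace_fit <- function(object, level = 0.95, ...) {
  ci <- rbind(A = profile_ci(object, "A", level),
              C = profile_ci(object, "C", level),
              E = profile_ci(object, "E", level))
  structure(list(fit = object, ci = ci, level = level),
            class = "summary.ace_fit")
}

#' @export
print.summary.ace_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  tab <- cbind(estimate = coef(x$fit), x$ci)
  colnames(tab)[2:3] <- paste0(c("lower", "upper"), " ",
                               format(100 * x$level), "%")
  print(round(tab, digits))
  invisible(x)
}

## Profile negative log-likelihood with one standardized component fixed
## at value `v`.  Free parameters: total variance V, the split `s` of the
## remaining proportion between the other two components, and the mean.
profile_nll <- function(par, v, component, ss_mz, ss_dz) {
  V <- par[1L]; s <- par[2L]; mu <- par[3L]
  rest <- (1 - v) * V
  comp <- switch(component,
                 A = c(v * V, s * rest, (1 - s) * rest),
                 C = c(s * rest, v * V, (1 - s) * rest),
                 E = c(s * rest, (1 - s) * rest, v * V))
  vt <- sum(comp)
  ll <- group_loglik(ss_mz, vt, comp[1L] + comp[2L], mu) +
    group_loglik(ss_dz, vt, comp[1L] / 2 + comp[2L], mu)
  if (!is.finite(ll)) return(1e10)
  -ll
}

## maximized log-likelihood subject to component == v
profile_loglik_at <- function(fit, component, v, ss_mz, ss_dz) {
  V0 <- fit$a^2 + fit$c^2 + fit$e^2
  others <- switch(component, A = c(fit$C, fit$E), C = c(fit$A, fit$E),
                   E = c(fit$A, fit$C))
  s0 <- if (sum(others) > 1e-10) others[1L] / sum(others) else 0.5
  best <- Inf
  for (st in list(c(V0, s0, fit$mu), c(V0, 0.5, fit$mu))) {
    o <- tryCatch(
      stats::optim(st, profile_nll, method = "L-BFGS-B",
                   lower = c(1e-10, 0, -Inf), upper = c(Inf, 1, Inf),
                   v = v, component = component,
                   ss_mz = ss_mz, ss_dz = ss_dz),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  -best
}

#' Profile-likelihood confidence interval for a variance proportion
#'
#' The interval is the set of values `v` of the standardized component for
#' which the likelihood-ratio statistic
#' `2 (loglik_max - max loglik | component = v)` does not exceed the
#' chi-square(1) critical value (3.841 at 95%).  The boundary is located by
#' root-finding on each side of the estimate, and the interval is clipped
#' to \[0, 1\].
#'
#' @param fit An [fit_ace] result.
#' @param component `"A"`, `"C"` or `"E"`.
#' @param level Confidence level. Default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
profile_ci <- function(fit, component = c("A", "C", "E"), level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  component <- match.arg(component)
  ss_mz <- pair_suffstats(fit$data$mz)
  ss_dz <- pair_suffstats(fit$data$dz)
  cutoff <- stats::qchisq(level, df = 1L)
  hat <- switch(component, A = fit$A, C = fit$C, E = fit$E)
  llmax <- fit$loglik

  g <- function(v)
    2 * (llmax - profile_loglik_at(fit, component, v, ss_mz, ss_dz)) - cutoff

  eps <- 1e-6
  lo_end <- 0; hi_end <- 1 - eps
  lower <- if (hat <= lo_end + eps || g(lo_end) <= 0) 0 else
    stats::uniroot(g, c(lo_end, hat), tol = 1e-5)$root
  upper <- if (hat >= hi_end || g(hi_end) <= 0) 1 else
    stats::uniroot(g, c(hat, hi_end), tol = 1e-5)$root
  c(lower = max(0, lower), upper = min(1, upper))
}

#' @export
confint.ace_fit <- function(object, parm = c("A", "C", "E"),
                            level = 0.95, ...) {
  parm <- match.arg(parm, c("A", "C", "E"), several.ok = TRUE)
  out <- t(vapply(parm, function(p) profile_ci(object, p, level),
                  numeric(2)))
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2)), " %")
  out
}

#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_tot <- sqrt(object$a^2 + object$c^2 + object$e^2)
  lapply(seq_len(nsim), function(i) {
    s <- simulate_twin_traits(object$n_mz, object$n_dz,
                              A = object$A, C = object$C, E = object$E)
    s$mz <- s$mz * sd_tot + object$mu
    s$dz <- s$dz * sd_tot + object$mu
    s$otu_id <- object$otu_id
    s
  })
}

#' Extract one OTU's paired trait from a trait matrix
#'
#' @param traits A [prepare_traits] result.
#' @param otu OTU id or row index.
#' @return A [paired_trait].
#' @export
extract_paired_trait <- function(traits, otu) {
  stopifnot(inherits(traits, "trait_matrix"))
  p <- traits$pairs$pairs
  y1 <- traits$values[otu, p$sample_1]
  y2 <- traits$values[otu, p$sample_2]
  mz <- p$zygosity == "MZ"
  paired_trait(cbind(y1[mz], y2[mz]), cbind(y1[!mz], y2[!mz]),
               otu_id = if (is.character(otu)) otu else
                 rownames(traits$values)[otu])
}

#' Fit the ACE model to every OTU trait
#'
#' Runs [fit_ace] and the profile-likelihood CI for A on each row of a
#' trait matrix.  Per-OTU failures are recorded (`converged = NA` row) but
#' are not fatal.
#'
#' @param traits A [prepare_traits] result (or any `trait_matrix`).
#' @param multistart,tol Passed to [fit_ace].
#' @param seed Integer base seed; OTU `j` uses `seed + j` for its start
#'   jitter, making the whole profile reproducible.
#' @param ci Compute the A profile CI per OTU. Default TRUE.
#' @param level Confidence level for the CI.
#' @return Object of class `herit_profile`: list with `method_label`,
#'   `estimates` (data frame: otu_id, A, C, E, ci_A_lower, ci_A_upper,
#'   loglik, converged), `mean_A` and `n_mz`/`n_dz`.
#' @export
fit_all <- function(traits, multistart = 5L, tol = 1e-8, seed = 1L,
                    ci = TRUE, level = 0.95) {
  stopifnot(inherits(traits, "trait_matrix"))
  ids <- rownames(traits$values)
  if (length(ids) == 0L) stop("empty trait matrix")
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    pt <- extract_paired_trait(traits, ids[j])
    row <- data.frame(otu_id = ids[j], A = NA_real_, C = NA_real_,
                      E = NA_real_, ci_A_lower = NA_real_,
                      ci_A_upper = NA_real_, loglik = NA_real_,
                      converged = NA, stringsAsFactors = FALSE)
    f <- tryCatch(fit_ace(pt, multistart = multistart, tol = tol,
                          seed = if (is.null(seed)) NULL else seed + j),
                  error = function(e) NULL)
    if (!is.null(f)) {
      row[, c("A", "C", "E", "loglik")] <-
        c(f$A, f$C, f$E, f$loglik)
      row$converged <- f$converged
      if (ci) {
        interval <- tryCatch(profile_ci(f, "A", level),
                             error = function(e) c(NA_real_, NA_real_))
        row$ci_A_lower <- interval[1L]
        row$ci_A_upper <- interval[2L]
      }
    }
    rows[[j]] <- row
  }
  est <- do.call(rbind, rows)
  pt1 <- extract_paired_trait(traits, ids[1L])
  structure(list(method_label = traits$method_label,
                 estimates = est,
                 mean_A = mean(est$A, na.rm = TRUE),
                 n_mz = nrow(pt1$mz), n_dz = nrow(pt1$dz)),
            class = "herit_profile")
}

#' Construct a heritability profile from a data frame
#'
#' Mostly useful for assembling profiles from externally computed
#' estimates (e.g. collapsed-taxon fits).
#'
#' @param estimates Data frame with at least columns `otu_id` and `A`.
#' @param method_label Provenance label.
#' @return A `herit_profile`.
#' @export
herit_profile <- function(estimates, method_label) {
  stopifnot(is.data.frame(estimates),
            all(c("otu_id", "A") %in% colnames(estimates)))
  for (col in c("C", "E", "ci_A_lower", "ci_A_upper", "loglik"))
    if (is.null(estimates[[col]])) estimates[[col]] <- NA_real_
  if (is.null(estimates$converged)) estimates$converged <- TRUE
  structure(list(method_label = method_label, estimates = estimates,
                 mean_A = mean(estimates$A, na.rm = TRUE),
                 n_mz = NA_integer_, n_dz = NA_integer_),
            class = "herit_profile")
}

#' @export
print.herit_profile <- function(x, digits = 3, ...) {
  cat("Heritability profile [", x$method_label, "]: ",
      nrow(x$estimates), " units, mean A = ",
      format(x$mean_A, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.herit_profile <- function(x, ...) x$estimates

#' @export
summary.herit_profile <- function(object, ...) summarize_profile(object)

#' @export
plot.herit_profile <- function(x, component = "A", ...) {
  v <- x$estimates[[component]]
  v <- v[is.finite(v)]
  plot(stats::density(v, bw = "nrd0"),
       main = paste0(x$method_label, ": ", component, " estimates"),
       xlab = component, ...)
  invisible(x)
}

#' Write a heritability profile as TSV
#' @param x A `herit_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_herit_profile <- function(x, path) {
  stopifnot(inherits(x, "herit_profile"))
  utils::write.table(x$estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
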