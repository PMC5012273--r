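#' Run the full heritability benchmark across OTU tables
#'
#' End-to-end orchestration over competing OTU tables built from the same
#' samples: per method, preprocessing ([prepare_traits]) and per-OTU ACE
#' fits ([fit_all]); across methods, pairwise distribution comparisons for
#' each variance component ([compare_profiles]), the heritable-unit filter
#' against the pooled mean A ([heritable_subset]) with comparisons on the
#' subset, optional taxonomic collapsing with shared-taxon selection and
#' the heritability linear model, and rarefaction alpha diversity with
#' rank-concordance analysis.  When `output_dir` is given, all result
#' tables are written as TSV together with a JSON manifest declaring every
#' file, the configuration and the seeds in force.
#'
#' @param tables Named list of [otu_table] objects over the same samples
#'   (names override the tables' method labels when given).
#' @param records Twin metadata data frame (see [read_metadata]).
#' @param taxonomy Optional named lineage vector (see [read_taxonomy])
#'   keyed by the OTU ids of the *first* table; taxonomic collapsing is
#'   run on that table's ids only when every table shares them, otherwise
#'   supply `taxonomy_tables` yourself.
#' @param covariate_names Covariates to adjust for; default all present.
#' @param min_fraction Prevalence threshold. Default 0.5.
#' @param pseudocount Pseudo-count. Default 1.
#' @param depth,reps Rarefaction depth and replicate count. Defaults
#'   10000 and 25.
#' @param ci_floor Heritable-filter lower-CI floor. Default 0.01.
#' @param level CI level. Default 0.95.
#' @param tax_levels Ranks for taxonomic collapsing. Default genus and
#'   phylum endpoints of the genus..phylum range.
#' @param seed Base seed for all stochastic stages. Default 1.
#' @param run_diversity,run_taxonomy Toggle those stages.
#' @param output_dir Optional directory for TSV outputs and manifest.
#' @return List of class `benchmark_report`: `profiles`, `summaries`,
#'   `comparisons` (per component), `pooled_mean_A`, `heritable`
#'   (filtered profiles), `heritable_comparison`, `taxonomy` (collapsed
#'   profiles, shared taxa, `herit_glm`), `diversity` (profiles and
#'   per-metric concordance), `config`.
#' @export
run_benchmark <- function(tables, records, taxonomy = NULL,
                          covariate_names = NULL,
                          min_fraction = 0.5, pseudocount = 1L,
                          depth = 10000L, reps = 25L,
                          ci_floor = 0.01, level = 0.95,
                          tax_levels = c("genus", "phylum"),
                          seed = 1L,
                          run_diversity = TRUE,
                          run_taxonomy = !is.null(taxonomy),
                          output_dir = NULL) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "otu_table")))
  if (!is.null(names(tables)))
    for (i in seq_along(tables))
      if (nzchar(names(tables)[i]))
        tables[[i]]$method_label <- names(tables)[i]
  labs <- vapply(tables, `[[`, character(1), "method_label")
  names(tables) <- labs

  config <- list(methods = labs, min_fraction = min_fraction,
                 pseudocount = pseudocount, depth = depth, reps = reps,
                 ci_floor = ci_floor, level = level, seed = seed,
                 covariate_names = covariate_names,
                 tax_levels = tax_levels)

  ## per-method heritability profiles
  profiles <- vector("list", length(tables)); names(profiles) <- labs
  for (i in seq_along(tables)) {
    pairs <- pair_samples(tables[[i]], records, covariate_names)
    traits <- prepare_traits(tables[[i]], pairs,
                             covariate_names = covariate_names,
                             min_fraction = min_fraction,
                             pseudocount = pseudocount)
    profiles[[i]] <- fit_all(traits, seed = seed, level = level)
  }
  summaries <- lapply(profiles, summarize_profile)

  comparisons <- heritable_comparison <- NULL
  heritable <- NULL
  pooled <- pooled_mean_A(profiles)
  if (length(profiles) >= 2L) {
    comparisons <- lapply(stats::setNames(nm = c("A", "C", "E")),
                          function(cc) compare_profiles(profiles, cc))
    heritable <- lapply(profiles, heritable_subset,
                        global_mean = pooled, ci_floor = ci_floor)
    usable <- vapply(heritable, function(p) nrow(p$estimates) >= 2L,
                     logical(1))
    if (sum(usable) >= 2L)
      heritable_comparison <- compare_profiles(heritable[usable], "A")
  } else {
    heritable <- lapply(profiles, heritable_subset,
                        global_mean = pooled, ci_floor = ci_floor)
  }

  ## taxonomy: collapse each table at each level, refit, shared taxa, GLM
  taxonomy_res <- NULL
  if (run_taxonomy) {
    if (is.null(taxonomy)) stop("run_taxonomy = TRUE but no taxonomy given")
    tax_profiles <- list()
    for (lev in tax_levels) {
      for (i in seq_along(tables)) {
        col <- collapse_by_taxonomy(tables[[i]], taxonomy, lev)
        pairs <- pair_samples(col, records, covariate_names)
        traits <- prepare_traits(col, pairs,
                                 covariate_names = covariate_names,
                                 min_fraction = min_fraction,
                                 pseudocount = pseudocount)
        pr <- fit_all(traits, seed = seed, ci = FALSE, level = level)
        pr$method_label <- labs[i]      # method, not method:level
        tax_profiles[[paste(lev, labs[i], sep = ":")]] <- pr
      }
    }
    obs <- do.call(rbind, lapply(names(tax_profiles), function(nm) {
      pr <- tax_profiles[[nm]]
      data.frame(taxon = pr$estimates$otu_id, method = pr$method_label,
                 A = pr$estimates$A, level = sub(":.*", "", nm),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    shared <- if (length(labs) >= 2L) {
      by_method <- split(obs$taxon, obs$method)
      sort(Reduce(intersect, by_method))
    } else unique(obs$taxon)
    glm_res <- if (length(labs) >= 2L && length(shared) >= 2L)
      heritability_glm(obs[obs$taxon %in% shared, , drop = FALSE])
    else NULL
    taxonomy_res <- list(profiles = tax_profiles, shared_taxa = shared,
                         observations = obs, glm = glm_res)
  }

  ## alpha diversity + concordance
  diversity_res <- NULL
  if (run_diversity) {
    div_profiles <- lapply(tables, alpha_diversity, depth = depth,
                           reps = reps, seed = seed)
    concordance <- if (length(div_profiles) >= 2L)
      lapply(stats::setNames(nm = c("shannon", "simpson", "chao1",
                                    "observed_otus")),
             function(mm) compare_alpha(div_profiles, mm))
    else NULL
    diversity_res <- list(profiles = div_profiles,
                          concordance = concordance)
  }

  report <- structure(list(
    profiles = profiles, summaries = summaries,
    comparisons = comparisons, pooled_mean_A = pooled,
    heritable = heritable, heritable_comparison = heritable_comparison,
    taxonomy = taxonomy_res, diversity = diversity_res,
    config = config
  ), class = "benchmark_report")

  if (!is.null(output_dir)) write_benchmark(report, output_dir)
  report
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  cat("Heritability benchmark across", length(x$profiles), "method(s)\n")
  mA <- vapply(x$profiles, `[[`, numeric(1), "mean_A")
  for (nm in names(sort(mA, decreasing = TRUE)))
    cat("  ", format(nm, width = 20), " mean A = ",
        format(mA[nm], digits = digits), " (",
        nrow(x$profiles[[nm]]$estimates), " OTUs)\n", sep = "")
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons$A[x$comparisons$A$q < 0.05, , drop = FALSE]
    cat("  significant pairwise A differences (q < 0.05): ",
        nrow(sig), " of ", nrow(x$comparisons$A), "\n", sep = "")
  }
  invisible(x)
}

## write all report tables as TSV plus a JSON manifest declaring them
write_benchmark <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name)
  }
  for (nm in names(report$profiles))
    put(report$profiles[[nm]]$estimates, paste0("heritability_", nm, ".tsv"))
  for (nm in names(report$summaries)) {
    put(report$summaries[[nm]]$stats, paste0("summary_", nm, ".tsv"))
    if (!is.null(report$summaries[[nm]]$density))
      put(report$summaries[[nm]]$density, paste0("density_", nm, ".tsv"))
  }
  if (!is.null(report$comparisons))
    put(do.call(rbind, report$comparisons), "comparisons.tsv")
  if (!is.null(report$heritable_comparison))
    put(report$heritable_comparison, "comparisons_heritable_subset.tsv")
  if (!is.null(report$taxonomy)) {
    put(report$taxonomy$observations, "taxon_heritability.tsv")
    if (!is.null(report$taxonomy$glm))
      put(report$taxonomy$glm$coefficients, "taxon_glm_coefficients.tsv")
  }
  if (!is.null(report$diversity)) {
    for (nm in names(report$diversity$profiles))
      put(report$diversity$profiles[[nm]]$values,
          paste0("diversity_", nm, ".tsv"))
    if (!is.null(report$diversity$concordance))
      for (mm in names(report$diversity$concordance)) {
        put(report$diversity$concordance[[mm]]$tests,
            paste0("diversity_tests_", mm, ".tsv"))
        tau <- report$diversity$concordance[[mm]]$tau
        put(data.frame(method = rownames(tau), tau, check.names = FALSE,
                       row.names = NULL), paste0("tau_", mm, ".tsv"))
      }
  }
  manifest <- list(package = "otuherit",
                   version = as.character(utils::packageVersion("otuherit")),
                   config = report$config,
                   pooled_mean_A = report$pooled_mean_A,
                   files = files)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}
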