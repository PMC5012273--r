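TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__")

## Parse Greengenes-style lineage strings ("k__Bacteria; p__Firmicutes; ...")
## into a character matrix with one column per rank; missing or
## prefix-only ranks become "".
parse_lineages <- function(lineages) {
  out <- matrix("", length(lineages), length(TAX_RANKS),
                dimnames = list(names(lineages), TAX_RANKS))
  parts <- strsplit(as.character(lineages), ";")
  for (i in seq_along(parts)) {
    for (tok in trimws(parts[[i]])) {
      j <- match(substr(tok, 1L, 3L), TAX_PREFIXES)
      if (!is.na(j)) out[i, j] <- trimws(substring(tok, 4L))
    }
  }
  out
}

## Lineage label at `level`, applying the unclassified rule: an empty rank
## is keyed by the deepest assigned parent so unrelated unclassified taxa
## are not merged.
lineage_key <- function(ranks_mat, level_idx) {
  apply(ranks_mat, 1L, function(r) {
    pref <- r[seq_len(level_idx)]
    if (!nzchar(pref[level_idx])) {
      assigned <- which(nzchar(pref))
      parent <- if (length(assigned))
        paste(paste0(TAX_PREFIXES[seq_len(max(assigned))],
                     pref[seq_len(max(assigned))]), collapse = "; ")
      else "unassigned"
      return(paste0("unclassified_", parent))
    }
    paste(paste0(TAX_PREFIXES[seq_len(level_idx)], pref), collapse = "; ")
  })
}

#' Collapse an OTU table by taxonomic assignment
#'
#' Rows of the collapsed table are the unique lineage prefixes up to the
#' requested rank; counts of member OTUs are summed, so per-sample column
#' totals are preserved.  OTUs with an empty rank at the requested level
#' are grouped as `unclassified_<deepest assigned parent lineage>`.
#'
#' @param table An [otu_table].
#' @param taxonomy Named character vector of lineage strings per OTU id
#'   (see [read_taxonomy]); every OTU in the table must be mapped.
#' @param level Rank to collapse at: one of `"phylum"`, `"class"`,
#'   `"order"`, `"family"`, `"genus"`.
#' @return An [otu_table] whose row ids are lineage strings; the method
#'   label is suffixed with the level.
#' @export
collapse_by_taxonomy <- function(table, taxonomy,
                                 level = c("genus", "family", "order",
                                           "class", "phylum")) {
  stopifnot(inherits(table, "otu_table"))
  level <- match.arg(level)
  level_idx <- match(level, TAX_RANKS)
  unmapped <- setdiff(otu_ids(table), names(taxonomy))
  if (length(unmapped))
    stop("OTU(s) without taxonomy: ", paste(utils::head(unmapped, 5L),
                                            collapse = ", "))
  lin <- parse_lineages(taxonomy[otu_ids(table)])
  key <- lineage_key(lin, level_idx)
  collapsed <- rowsum(table$counts, group = key, reorder = TRUE)
  storage.mode(collapsed) <- "integer"
  otu_table(collapsed, paste0(table$method_label, ":", level))
}

#' Taxa shared by every profile
#'
#' @param profiles List of `herit_profile` objects over collapsed tables.
#' @return Character vector (alphabetical) of unit ids present in every
#'   profile.
#' @export
shared_taxa <- function(profiles) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "herit_profile")))
  ids <- lapply(profiles, function(p) p$estimates$otu_id)
  sort(Reduce(intersect, ids))
}

#' Model heritability on taxon and clustering method
#'
#' Gaussian linear model `A ~ taxon + method` with treatment coding and
#' alphabetically first reference levels; per-coefficient two-sided Wald
#' t-tests.  Taxa observed under a single method only would make the
#' design collinear and are dropped with a warning.
#'
#' @param observations Data frame with columns `taxon`, `method`, `A`.
#' @return Object of class `herit_glm`: list with `coefficients` (data
#'   frame: term, estimate, std_error, t_value, p_value), the underlying
#'   `lm` fit, `reference_levels`, `n_obs`, `r_squared`, and counts of
#'   significant taxa at `alpha`.
#' @param alpha Two-sided significance threshold for the per-term Wald
#'   tests used in the significance tally. Default 0.05.
#' @export
heritability_glm <- function(observations, alpha = 0.05) {
  stopifnot(all(c("taxon", "method", "A") %in% colnames(observations)))
  df <- data.frame(taxon = as.character(observations$taxon),
                   method = as.character(observations$method),
                   A = as.numeric(observations$A),
                   stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$taxon)) < 2L || length(unique(df$method)) < 2L)
    stop("need at least 2 taxa and 2 methods")
  n_methods <- tapply(df$method, df$taxon, function(m) length(unique(m)))
  single <- names(n_methods)[n_methods < 2L]
  if (length(single)) {
    warning("taxa observed under a single method dropped: ",
            paste(utils::head(single, 5L), collapse = ", "))
    df <- df[!(df$taxon %in% single), , drop = FALSE]
  }
  df$taxon <- factor(df$taxon, levels = sort(unique(df$taxon)))
  df$method <- factor(df$method, levels = sort(unique(df$method)))
  fit <- stats::lm(A ~ taxon + method, data = df)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  coefs <- data.frame(term = rownames(co), estimate = co[[1L]],
                      std_error = co[[2L]], t_value = co[[3L]],
                      p_value = co[[4L]], stringsAsFactors = FALSE,
                      row.names = NULL)
  is_taxon <- startsWith(coefs$term, "taxon")
  is_method <- startsWith(coefs$term, "method")
  structure(list(
    coefficients = coefs,
    lm_fit = fit,
    reference_levels = c(taxon = levels(df$taxon)[1L],
                         method = levels(df$method)[1L]),
    n_obs = nrow(df),
    n_taxa = nlevels(df$taxon),
    n_methods = nlevels(df$method),
    r_squared = sm$r.squared,
    alpha = alpha,
    ## reference level is counted as significant if any taxon term is:
    ## significance of "taxon as predictor" is per non-reference level
    n_taxa_significant = sum(is_taxon & coefs$p_value < alpha),
    n_methods_significant = sum(is_method & coefs$p_value < alpha)
  ), class = "herit_glm")
}

#' @export
print.herit_glm <- function(x, ...) {
  cat("Linear model of heritability on taxon + method\n")
  cat("  ", x$n_obs, " observations, ", x$n_taxa, " taxa, ",
      x$n_methods, " methods; R^2 = ", format(x$r_squared, digits = 3),
      "\n", sep = "")
  cat("  taxon terms with p < ", x$alpha, ": ", x$n_taxa_significant,
      " of ", x$n_taxa - 1L, "\n", sep = "")
  cat("  method terms with p < ", x$alpha, ": ", x$n_methods_significant,
      " of ", x$n_methods - 1L, "\n", sep = "")
  invisible(x)
}

#' @export
coef.herit_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
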