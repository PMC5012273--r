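#' Construct an OTU table
#'
#' An `otu_table` holds a non-negative integer count matrix (OTUs in rows,
#' samples in columns) together with a provenance label naming the clustering
#' method that produced it.
#'
#' @param counts Integer matrix of counts, with row names (OTU ids) and
#'   column names (sample ids).
#' @param method_label Character scalar identifying the clustering method
#'   (e.g. `"vsearch_97"`).
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `method_label`.
#' @examples
#' m <- matrix(c(1L, 2L, 0L, 3L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' otu_table(m, "example")
#' @export
otu_table <- function(counts, method_label = "unlabelled") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("need at least 1 OTU and 2 samples")
  if (any(is.na(counts))) stop("missing values in counts")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.double(counts)) {
    if (any(counts != round(counts)))
      stop("non-integral counts are not allowed")
    storage.mode(counts) <- "integer"
  }
  structure(list(counts = counts, method_label = as.character(method_label)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table [", x$method_label, "]: ", nrow(x$counts), " OTUs x ",
      ncol(x$counts), " samples, ", sum(x$counts), " total reads\n", sep = "")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' OTU ids and sample ids of a table
#' @param x An `otu_table`.
#' @return Character vector of ids.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read an OTU table from TSV or BIOM-JSON
#'
#' The TSV dialect has the OTU id in the first column (header cell
#' `#OTU_ID`), one column per sample, tab separated integer counts.
#' BIOM-JSON v1.0 (dense or sparse) is read through the biomformat package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom_json"`.
#' @param method_label Provenance label; defaults to the file name without
#'   extension.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom_json"),
                           method_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(method_label))
    method_label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate OTU ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    nm <- colnames(df)[-1L]
    if (anyDuplicated(nm))
      stop("duplicate sample column in ", path, ": ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    dimnames(m) <- list(ids, nm)
    return(otu_table(m, method_label))
  }
  otu_table(read_biom_json_matrix(path), method_label)
}

## BIOM-JSON v1.0 reader (dense and sparse triplet encodings).
read_biom_json_matrix <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  shape <- as.integer(b$shape)
  rid <- vapply(b$rows, function(r) as.character(r$id), character(1))
  cid <- vapply(b$columns, function(c) as.character(c$id), character(1))
  m <- matrix(0, shape[1L], shape[2L], dimnames = list(rid, cid))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- as.numeric(unlist(b$data[[i]]))
  } else {
    for (trip in b$data) {
      trip <- as.numeric(unlist(trip))
      m[trip[1L] + 1L, trip[2L] + 1L] <- trip[3L]
    }
  }
  m
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table] for the TSV dialect; a read/write round trip
#' preserves counts and row/column order exactly.
#'
#' @param x An [otu_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(`#OTU_ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read twin sample metadata
#'
#' Expects a TSV with header `sample_id`, `family_id`, `zygosity` followed by
#' covariate columns.  Zygosity is parsed case-insensitively into MZ/DZ.
#' Covariate columns are typed numeric when every value parses as a number
#' and categorical otherwise; `factor_covariates` forces named columns to be
#' treated as categorical (e.g. a sequencing run coded 1/2).
#'
#' @param path Path to the metadata TSV.
#' @param factor_covariates Character vector of covariate columns to force
#'   categorical.
#' @return A data frame with one row per sample: `sample_id`, `family_id`,
#'   `zygosity` (factor MZ/DZ) and the covariate columns.
#' @export
read_metadata <- function(path, factor_covariates = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "family_id", "zygosity")
  if (!all(need %in% colnames(df)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  as_sample_records(df, factor_covariates)
}

## Shared validation/typing for metadata, whether read from file or built
## in memory.
as_sample_records <- function(df, factor_covariates = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  zyg <- toupper(trimws(as.character(df$zygosity)))
  bad <- setdiff(unique(zyg), c("MZ", "DZ"))
  if (length(bad))
    stop("unknown zygosity code(s): ", paste(bad, collapse = ", "))
  df$zygosity <- factor(zyg, levels = c("MZ", "DZ"))
  sizes <- table(df$family_id)
  if (any(sizes > 2L))
    stop("family with more than 2 samples: ",
         paste(names(sizes)[sizes > 2L], collapse = ", "))
  mixed <- tapply(as.character(df$zygosity), df$family_id,
                  function(z) length(unique(z)) > 1L)
  if (any(mixed))
    stop("inconsistent zygosity within family: ",
         paste(names(mixed)[mixed], collapse = ", "))
  covs <- setdiff(colnames(df), c("sample_id", "family_id", "zygosity"))
  for (cv in covs) {
    v <- as.character(df[[cv]])
    num <- suppressWarnings(as.numeric(v))
    if (!(cv %in% factor_covariates) && !anyNA(num[!is.na(v) & nzchar(v)]))
      df[[cv]] <- num
    else
      df[[cv]] <- ifelse(nzchar(v), v, NA_character_)
  }
  df
}

#' Assemble complete twin pairs
#'
#' Retains only families with exactly two samples that are both present in
#' the OTU table and have complete values for the requested covariates.
#' Singleton twins and samples with missing covariates are excluded together
#' with their co-twin; exclusion counts are reported in the result.
#'
#' @param table An [otu_table].
#' @param records Metadata data frame from [read_metadata].
#' @param covariate_names Covariate columns that must be complete; defaults
#'   to all covariate columns present.
#' @return An object of class `twin_pairs`: a list with `pairs` (data frame
#'   `sample_1`, `sample_2`, `family_id`, `zygosity`), `n_mz`, `n_dz`,
#'   `records` (retained metadata rows) and `exclusions` (named counts).
#' @export
pair_samples <- function(table, records, covariate_names = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(covariate_names))
    covariate_names <- setdiff(colnames(records),
                               c("sample_id", "family_id", "zygosity"))
  missing_cov <- setdiff(covariate_names, colnames(records))
  if (length(missing_cov))
    stop("covariate column(s) absent from metadata: ",
         paste(missing_cov, collapse = ", "))

  in_table <- records$sample_id %in% sample_ids(table)
  complete <- rep(TRUE, nrow(records))
  for (cv in covariate_names) complete <- complete & !is.na(records[[cv]])
  usable <- in_table & complete

  keep_fam <- tapply(usable, records$family_id, function(u)
    length(u) == 2L && all(u))
  keep_fam <- names(keep_fam)[keep_fam]
  kept <- records[records$family_id %in% keep_fam, , drop = FALSE]
  kept <- kept[order(kept$family_id, kept$sample_id), , drop = FALSE]

  exclusions <- c(
    not_in_table   = sum(!in_table),
    missing_covariates = sum(in_table & !complete),
    cotwin_dropped = sum(usable & !(records$family_id %in% keep_fam))
  )
  if (nrow(kept) == 0L)
    stop("no complete twin pairs remain after matching and exclusions")

  first <- !duplicated(kept$family_id)
  pairs <- data.frame(
    sample_1  = kept$sample_id[first],
    sample_2  = kept$sample_id[!first],
    family_id = kept$family_id[first],
    zygosity  = kept$zygosity[first],
    stringsAsFactors = FALSE
  )
  structure(list(
    pairs = pairs,
    n_mz = sum(pairs$zygosity == "MZ"),
    n_dz = sum(pairs$zygosity == "DZ"),
    records = kept,
    covariate_names = covariate_names,
    exclusions = exclusions
  ), class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat("Twin pair set: ", x$n_mz, " MZ and ", x$n_dz, " DZ complete pairs (",
      2L * nrow(x$pairs), " samples)\n", sep = "")
  if (any(x$exclusions > 0))
    cat("  excluded samples:",
        paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Read a taxonomy map
#'
#' Two-column TSV: OTU id, then a Greengenes-style lineage string
#' `"k__Bacteria; p__Firmicutes; ..."`.
#'
#' @param path Path to the taxonomy TSV (no header, or header starting
#'   with `#`).
#' @return Named character vector: lineage string per OTU id.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file must have two tab-separated columns")
  if (anyDuplicated(df[[1L]])) stop("duplicate OTU ids in taxonomy map")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
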