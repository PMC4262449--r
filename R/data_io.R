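#' Construct an expression dataset
#'
#' The single carrier for all expression data in the package: a numeric
#' gene-by-sample matrix plus a per-sample metadata table. The same container
#' holds multi-region atlas donors (one column per region), developmental
#' donors, and case/control cohorts (one column per subject).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with one row per sample. Must contain `sample_id`;
#'   recognised optional columns are `donor_id`, `age_years` (real, negative
#'   before birth), `region` and `condition` (`"control"` / `"case"`).
#' @param ranked logical: have columns already been rank-normalised?
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, meta, ranked = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers in expression matrix")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("meta must contain sample_id")
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata")
  only_mat <- setdiff(colnames(values), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(values))
  if (length(only_mat) || length(only_meta))
    stop(sprintf(
      "sample mismatch between matrix and metadata: matrix-only [%s], metadata-only [%s]",
      paste(only_mat, collapse = ","), paste(only_meta, collapse = ",")))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if ("condition" %in% names(meta)) {
    bad <- !is.na(meta$condition) & meta$condition != "" &
      !meta$condition %in% c("control", "case")
    if (any(bad)) stop("condition must be 'control' or 'case'")
  }
  structure(list(values = values, meta = meta, ranked = isTRUE(ranked)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (x$ranked) " (rank-normalised)" else ""))
  extra <- intersect(c("donor_id", "age_years", "region", "condition"),
                     names(x$meta))
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expression_dataset
#' @param x an `expression_dataset`.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname expression_dataset
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression dataset by samples or genes
#'
#' @param x an `expression_dataset`.
#' @param idx sample indices, logical mask, or sample ids.
#' @return A new `expression_dataset`.
#' @export
subset_samples <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(x$values))
  expression_dataset(x$values[, idx, drop = FALSE],
                     x$meta[idx, , drop = FALSE], ranked = x$ranked)
}

#' @rdname subset_samples
#' @param gene_ids gene symbols or indices to keep.
#' @export
subset_genes <- function(x, gene_ids) {
  expression_dataset(x$values[gene_ids, , drop = FALSE], x$meta,
                     ranked = FALSE)
}

#' Rank-normalise a dataset in place
#'
#' Applies [rank_within_sample] to the value matrix and flags the dataset as
#' ranked. Ranking a ranked dataset is a no-op (ranks of ranks are the same
#' ranks).
#'
#' @param x an `expression_dataset`.
#' @return The dataset with ranked values.
#' @export
rank_dataset <- function(x) {
  x$values <- rank_within_sample(x$values)
  x$ranked <- TRUE
  x
}

#' Read an expression matrix with its sample metadata
#'
#' The matrix file is tab-separated with a header row of sample ids and gene
#' symbols in the first column; the metadata file is tab-separated and keyed
#' by `sample_id`. Samples present in only one of the two files are an
#' error. Non-numeric or blank expression cells raise a parse error naming
#' the offending gene and sample.
#'
#' @param matrix_path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @return An `expression_dataset` (not yet ranked).
#' @export
read_expression <- function(matrix_path, meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", na.strings = "NA")
  if (ncol(raw) < 2L) stop("expression matrix needs gene column plus samples")
  gene_col <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(cells, 2L, as.numeric))
  dim(num) <- dim(cells)
  # "NA" means missing (handled by prefilter_genes); blank or garbage cells
  # are parse errors and are reported by coordinate
  bad <- which((is.na(num) & !is.na(cells)) | (!is.na(cells) & cells == ""),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    at <- bad[1L, ]
    stop(sprintf("unparseable expression cell at gene '%s', sample '%s'",
                 gene_col[at[1L]], colnames(cells)[at[2L]]))
  }
  rownames(num) <- gene_col
  colnames(num) <- colnames(cells)
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = NA, na.strings = c("NA", ""))
  expression_dataset(num, meta)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression]; `read_expression(write_expression(x))`
#' round-trips valid datasets.
#'
#' @param x an `expression_dataset`.
#' @param matrix_path,meta_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(x, matrix_path, meta_path) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Construct a gene set
#'
#' @param name set label.
#' @param genes_vec character vector of gene symbols; duplicates are dropped
#'   with a warning, an empty set is an error.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes_vec) {
  genes_vec <- as.character(genes_vec)
  genes_vec <- genes_vec[genes_vec != "" & !is.na(genes_vec)]
  if (length(genes_vec) == 0L) stop(sprintf("gene set '%s' is empty", name))
  if (anyDuplicated(genes_vec)) {
    warning(sprintf("gene set '%s': %d duplicate symbol(s) dropped",
                    name, sum(duplicated(genes_vec))))
    genes_vec <- unique(genes_vec)
  }
  structure(list(name = name, genes = genes_vec), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read one gene set from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols.
#'
#' @param gmt_path path to a GMT file.
#' @param name name of the set to extract.
#' @return A [gene_set].
#' @export
read_gene_set <- function(gmt_path, name) {
  lines <- readLines(gmt_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hit <- vapply(fields, function(f) length(f) >= 1L && f[1L] == name,
                logical(1))
  if (!any(hit)) stop(sprintf("gene set '%s' not found in %s", name, gmt_path))
  f <- fields[[which(hit)[1L]]]
  if (length(f) < 3L) stop(sprintf("gene set '%s' has no genes", name))
  gene_set(name, f[-(1:2)])
}

#' @rdname read_gene_set
#' @param sets list of [gene_set] objects to write.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, gmt_path, descriptions = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s$name, d, s$genes), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

#' Collapse probe-level values to gene level
#'
#' Averages, per sample, all probes mapped to the same gene symbol; the
#' averaging happens on the expression scale, before any ranking. Probes
#' without a mapping are dropped and counted in a message.
#'
#' @param probe_matrix numeric probe-by-sample matrix (probe ids as
#'   rownames).
#' @param probe_to_gene data.frame with columns `probe` and `gene`; each
#'   retained probe must map to exactly one symbol.
#' @param meta per-sample metadata forwarded to the resulting dataset.
#' @return An `expression_dataset` at gene level.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene, meta) {
  probe_matrix <- as.matrix(probe_matrix)
  map <- probe_to_gene[!is.na(probe_to_gene$gene) & probe_to_gene$gene != "", ]
  if (anyDuplicated(map$probe)) stop("a probe maps to more than one gene")
  keep <- intersect(rownames(probe_matrix), map$probe)
  dropped <- nrow(probe_matrix) - length(keep)
  if (dropped > 0L)
    message(sprintf("collapse_probes: %d unmapped probe(s) dropped", dropped))
  if (length(keep) == 0L) stop("no probes left after applying the map")
  sub <- probe_matrix[keep, , drop = FALSE]
  grp <- map$gene[match(keep, map$probe)]
  sums <- rowsum(sub, grp)
  counts <- as.vector(table(grp)[rownames(sums)])
  expression_dataset(sums / counts, meta)
}

#' Average samples of the same region within a donor
#'
#' Collapses a single donor's samples to one column per named region by
#' averaging expression over all samples mapped to that region. Averaging is
#' done on the expression scale; rank-normalisation is applied afterwards by
#' the caller.
#'
#' @param x one-donor `expression_dataset` with a `region` metadata column.
#' @param level_map optional data.frame with columns `region` (sample-level
#'   label) and `named_region`; defaults to the identity map.
#' @param on_unmapped what to do with samples whose region label is missing
#'   from the map: `"drop"` (default) or `"error"`.
#' @return An `expression_dataset` with one sample per (donor, named
#'   region); sample ids are `<donor>_<region>`.
#' @export
aggregate_regions <- function(x, level_map = NULL,
                              on_unmapped = c("drop", "error")) {
  on_unmapped <- match.arg(on_unmapped)
  if (!"region" %in% names(x$meta)) stop("dataset has no region labels")
  donors <- unique(x$meta$donor_id)
  if (length(donors) != 1L) stop("aggregate_regions works one donor at a time")
  labels <- x$meta$region
  if (!is.null(level_map)) {
    idx <- match(labels, level_map$region)
    if (anyNA(idx)) {
      missing_lab <- unique(labels[is.na(idx)])
      if (on_unmapped == "error")
        stop(sprintf("region label(s) not in map: %s",
                     paste(missing_lab, collapse = ", ")))
      message(sprintf("aggregate_regions: dropping %d sample(s) with unmapped regions",
                      sum(is.na(idx))))
    }
    keep <- !is.na(idx)
    x <- subset_samples(x, keep)
    labels <- level_map$named_region[idx[keep]]
  }
  if (ncol(x$values) == 0L) stop("no samples left to aggregate")
  regions <- sort(unique(labels))
  vals <- vapply(regions, function(r) {
    rowMeans(x$values[, labels == r, drop = FALSE])
  }, numeric(nrow(x$values)))
  colnames(vals) <- paste(donors, regions, sep = "_")
  meta <- data.frame(sample_id = colnames(vals), donor_id = donors,
                     region = regions, stringsAsFactors = FALSE)
  if ("age_years" %in% names(x$meta))
    meta$age_years <- x$meta$age_years[1L]
  expression_dataset(vals, meta)
}

#' Restrict donors to their common regions
#'
#' Given one aggregated dataset per donor, keeps only the regions assayed in
#' every donor and puts regions in the same order everywhere, so that
#' per-donor profiles are directly comparable.
#'
#' @param donor_datasets list of one-donor `expression_dataset`s with region
#'   labels.
#' @return List of datasets, each restricted to the common regions in
#'   identical order.
#' @export
filter_common_regions <- function(donor_datasets) {
  if (length(donor_datasets) < 2L) stop("need at least 2 donors")
  region_sets <- lapply(donor_datasets, function(d) d$meta$region)
  common <- sort(Reduce(intersect, region_sets))
  if (length(common) == 0L) stop("no region is shared by all donors")
  lapply(donor_datasets, function(d) {
    subset_samples(d, match(common, d$meta$region))
  })
}

#' Drop low-level and missing-heavy genes
#'
#' A declared, simple low-level filter: removes genes whose median expression
#' falls below a quantile of the per-gene medians, and genes carrying more
#' missing values than a cap; any missing values surviving the filter are
#' imputed with the gene's median (counted in a message). Median imputation
#' is used because downstream analysis is entirely rank-based and the median
#' is rank-neutral.
#'
#' @param x an `expression_dataset` (values may contain NA).
#' @param min_expression_quantile genes with median expression below this
#'   quantile of all gene medians are removed; 0 disables.
#' @param max_missing_fraction genes with a larger fraction of missing
#'   values are removed; 1 disables.
#' @return A filtered, NA-free `expression_dataset`.
#' @export
prefilter_genes <- function(x, min_expression_quantile = 0,
                            max_missing_fraction = 1) {
  stopifnot(min_expression_quantile >= 0, min_expression_quantile <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  vals <- x$values
  med <- apply(vals, 1L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- -Inf  # all-missing gene: only the missing cap applies
  miss <- rowMeans(is.na(vals))
  thr <- stats::quantile(med, min_expression_quantile, na.rm = TRUE)
  keep <- (min_expression_quantile == 0 | med >= thr) &
    miss <= max_missing_fraction
  if (!any(keep)) stop("prefilter removed every gene")
  vals <- vals[keep, , drop = FALSE]
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0L) {
    message(sprintf("prefilter_genes: imputing %d missing value(s) with gene medians",
                    n_imputed))
    med_keep <- apply(vals, 1L, stats::median, na.rm = TRUE)
    na_idx <- which(is.na(vals), arr.ind = TRUE)
    vals[na_idx] <- med_keep[na_idx[, 1L]]
  }
  expression_dataset(vals, x$meta)
}

#' Split a multi-donor dataset into per-donor datasets
#'
#' @param x an `expression_dataset` with a `donor_id` column.
#' @return Named list of one-donor `expression_dataset`s.
#' @export
split_by_donor <- function(x) {
  if (!"donor_id" %in% names(x$meta)) stop("dataset has no donor_id column")
  ids <- unique(x$meta$donor_id)
  out <- lapply(ids, function(d) subset_samples(x, x$meta$donor_id == d))
  names(out) <- ids
  out
}
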