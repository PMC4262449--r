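#' Within-group seed-to-gene correlations in a case/control cohort
#'
#' For a cohort whose samples are subjects labelled `control` / `case`,
#' computes for every gene of the set the Spearman correlation between the
#' seed gene's expression and that gene's expression across subjects,
#' separately within each condition group. Computed on rank-normalised data,
#' so results are invariant to monotone per-subject transforms.
#'
#' @param x rank-normalised `expression_dataset` with a `condition` column.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @return data.frame with columns `gene`, `rho_control`, `rho_case`,
#'   `delta` (case minus control) and `inverted` (strictly negative in
#'   controls and strictly positive in cases).
#' @export
within_group_correlations <- function(x, seed, set) {
  if (!x$ranked) stop("dataset must be rank-normalised first")
  if (!"condition" %in% names(x$meta)) stop("dataset has no condition labels")
  idx_ctrl <- which(x$meta$condition == "control")
  idx_case <- which(x$meta$condition == "case")
  if (length(idx_ctrl) < 2L || length(idx_case) < 2L)
    stop("need at least 2 subjects per condition")
  if (length(idx_ctrl) < 5L || length(idx_case) < 5L)
    warning("fewer than 5 subjects in a group: correlations are unstable")
  members <- setdiff(intersect(set$genes, rownames(x$values)), seed)
  if (length(members) == 0L) stop("no set gene present in the cohort")
  if (length(members) < 10L)
    warning(sprintf("only %d set gene(s) measured in the cohort",
                    length(members)))
  group_rho <- function(idx) {
    sv <- x$values[seed, idx]
    if (diff(range(sv)) == 0)
      stop("seed gene is constant within a condition group")
    suppressWarnings(stats::cor(sv, t(x$values[members, idx, drop = FALSE]),
                                method = "spearman"))[1L, ]
  }
  rc <- group_rho(idx_ctrl)
  rk <- group_rho(idx_case)
  data.frame(gene = members, rho_control = unname(rc), rho_case = unname(rk),
             delta = unname(rk - rc),
             inverted = unname(rc < 0 & rk > 0),
             stringsAsFactors = FALSE)
}

#' Proportion of set genes switching from negative to positive correlation
#'
#' Strict sign change: rho < 0 in controls AND rho > 0 in cases; a zero on
#' either side does not count. The denominator is the number of set genes
#' actually evaluated in the cohort.
#'
#' @param per_gene data.frame from [within_group_correlations].
#' @return Fraction in \[0, 1\] with attribute `n_evaluated`.
#' @export
inversion_fraction <- function(per_gene) {
  ok <- !is.na(per_gene$rho_control) & !is.na(per_gene$rho_case)
  structure(mean(per_gene$rho_control[ok] < 0 & per_gene$rho_case[ok] > 0),
            n_evaluated = sum(ok))
}

#' Differential co-expression statistics for one cohort
#'
#' The four summary statistics of a case/control differential co-expression
#' table:
#' \enumerate{
#'   \item paired Wilcoxon signed-rank over the per-gene (control, case)
#'     correlation pairs;
#'   \item label-permutation p-value of the mean correlation change
#'     `mean_case - mean_control`, against a null built by shuffling the
#'     condition labels (group sizes preserved) and recomputing;
#'   \item the inversion fraction (strict negative-to-positive switches);
#'   \item label-permutation p-value of the inversion fraction against the
#'     same shuffled-label null.
#' }
#'
#' The inversion fraction's extremeness is one-sided by construction (an
#' excess of switches), so its permutation test defaults to the upper tail;
#' the mean-change test defaults to two-sided.
#'
#' @param x rank-normalised cohort `expression_dataset` with conditions.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @param n_permutations number of label shuffles (>= 100; default 1000).
#' @param delta_tail tail for the mean-change permutation test.
#' @param rng_seed optional integer seed for the shuffles.
#' @param dataset_label label carried into outputs.
#' @param include_in_meta should this cohort enter meta-combination
#'   (contrast cohorts, e.g. a non-target tissue, are flagged FALSE)?
#' @return An object of class `differential_result`.
#' @export
differential_statistics <- function(x, seed, set, n_permutations = 1000L,
                                    delta_tail = c("two_sided", "upper",
                                                   "lower"),
                                    rng_seed = NULL,
                                    dataset_label = "cohort",
                                    include_in_meta = TRUE) {
  delta_tail <- match.arg(delta_tail)
  if (n_permutations < 100L) stop("need at least 100 permutations")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  per_gene <- within_group_correlations(x, seed, set)
  mean_control <- mean(per_gene$rho_control)
  mean_case <- mean(per_gene$rho_case)
  obs_delta <- mean_case - mean_control
  inv <- inversion_fraction(per_gene)
  wilcoxon <- suppressWarnings(
    paired_wilcoxon(per_gene$rho_control, per_gene$rho_case))

  members <- per_gene$gene
  labels <- x$meta$condition
  n <- length(labels)
  n_case <- sum(labels == "case")
  seed_row <- x$values[seed, ]
  set_mat <- t(x$values[members, , drop = FALSE])
  perm_stats <- vapply(seq_len(n_permutations), function(i) {
    shuffled <- sample(n, n_case)
    is_case <- logical(n); is_case[shuffled] <- TRUE
    rc <- suppressWarnings(stats::cor(seed_row[!is_case],
                                      set_mat[!is_case, , drop = FALSE],
                                      method = "spearman"))[1L, ]
    rk <- suppressWarnings(stats::cor(seed_row[is_case],
                                      set_mat[is_case, , drop = FALSE],
                                      method = "spearman"))[1L, ]
    ok <- !is.na(rc) & !is.na(rk)
    c(mean(rk[ok]) - mean(rc[ok]), mean(rc[ok] < 0 & rk[ok] > 0))
  }, numeric(2))
  failed <- sum(is.na(perm_stats[1L, ]))
  if (failed > 0.01 * n_permutations)
    stop(sprintf("permutation failed on %d/%d shuffles",
                 failed, n_permutations))
  label_perm <- empirical_p(obs_delta, perm_stats[1L, ], tail = delta_tail,
                            method = "label permutation (mean correlation change)")
  inversion_perm <- empirical_p(as.numeric(inv), perm_stats[2L, ],
                                tail = "upper",
                                method = "label permutation (inversion fraction)")
  structure(
    list(dataset = dataset_label, per_gene = per_gene,
         n_subjects = n, n_control = n - n_case, n_case = n_case,
         n_evaluated = attr(inv, "n_evaluated"),
         mean_control = mean_control, mean_case = mean_case,
         delta = obs_delta, wilcoxon = wilcoxon, label_perm = label_perm,
         inversion_fraction = as.numeric(inv),
         inversion_perm = inversion_perm,
         include_in_meta = include_in_meta),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> %s (%d control / %d case, %d set genes)\n",
              x$dataset, x$n_control, x$n_case, x$n_evaluated))
  cat(sprintf("  mean rho: control %.3f -> case %.3f (delta %+.3f)\n",
              x$mean_control, x$mean_case, x$delta))
  cat(sprintf("  Wilcoxon p = %.3g; permutation p = %.3g\n",
              x$wilcoxon$p_value, x$label_perm$p_value))
  cat(sprintf("  inversions: %.1f%% (permutation p = %.3g)\n",
              100 * x$inversion_fraction, x$inversion_perm$p_value))
  invisible(x)
}

#' Genome-wide differential co-expression scan
#'
#' Specificity analysis for the seed: for every gene of the shared universe,
#' taken in turn as the seed, computes the change in mean set correlation
#' `mean_case - mean_control` in each cohort, and counts the genes whose
#' change strictly exceeds the designated seed's change in EVERY cohort.
#'
#' @param datasets list of rank-normalised cohort datasets with conditions.
#' @param set a [gene_set].
#' @param seed the designated seed gene symbol.
#' @return List with `k`, `n_universe`, `extreme_genes`, `p_plain` (k/N),
#'   `p` ((k+1)/(N+1)) and the per-cohort delta matrix.
#' @export
genome_wide_delta_scan <- function(datasets, set, seed) {
  universe <- Reduce(intersect,
                     lapply(datasets, function(d) rownames(d$values)))
  if (length(universe) < 100L)
    warning("shared universe below 100 genes: scan resolution is poor")
  if (!seed %in% universe) stop("designated seed not in the shared universe")
  members_all <- intersect(set$genes, universe)
  if (length(members_all) < 2L) stop("set barely present in shared universe")
  message(sprintf("genome_wide_delta_scan: universe of %d genes, %d set genes",
                  length(universe), length(members_all)))
  delta_mat <- vapply(datasets, function(d) {
    if (!d$ranked) stop("datasets must be rank-normalised")
    idx_ctrl <- d$meta$condition == "control"
    idx_case <- d$meta$condition == "case"
    A <- d$values[universe, , drop = FALSE]
    S <- d$values[members_all, , drop = FALSE]
    grp_mean <- function(idx) {
      M <- suppressWarnings(stats::cor(t(A[, idx, drop = FALSE]),
                                       t(S[, idx, drop = FALSE]),
                                       method = "spearman"))
      .set_mean_rows(M, universe, members_all)
    }
    grp_mean(idx_case) - grp_mean(idx_ctrl)
  }, numeric(length(universe)))
  rownames(delta_mat) <- universe
  seed_delta <- delta_mat[seed, ]
  others <- setdiff(universe, seed)
  beats_all <- rowSums(sweep(delta_mat[others, , drop = FALSE], 2L,
                             seed_delta, `>`)) == ncol(delta_mat)
  k <- sum(beats_all, na.rm = TRUE)
  n_total <- sum(stats::complete.cases(delta_mat))
  list(k = k, n_universe = n_total,
       extreme_genes = others[which(beats_all)],
       p_plain = k / n_total, p = (k + 1) / (n_total + 1),
       delta_matrix = delta_mat, seed_delta = seed_delta)
}

#' Random-gene-set specificity for a cohort's differential statistic
#'
#' Compares the observed mean correlation change (or inversion fraction) of
#' the real set against random gene sets of the same size drawn from the
#' cohort's universe (seed excluded). The seed's correlation with every gene
#' is computed once per group; random sets only average precomputed values.
#'
#' @param x rank-normalised cohort dataset with conditions.
#' @param seed seed gene symbol.
#' @param set the real [gene_set].
#' @param n_sets number of random sets (>= 100).
#' @param statistic `"delta"` (mean_case - mean_control, default) or
#'   `"inversion"`.
#' @param tail tail of the empirical p (default `"upper"`: the real set
#'   rewires more than random sets).
#' @param rng_seed optional integer seed.
#' @return A [test_result] with the null vector attached as
#'   `attr(, "null_values")`.
#' @export
random_set_specificity <- function(x, seed, set, n_sets = 1000L,
                                   statistic = c("delta", "inversion"),
                                   tail = c("upper", "lower", "two_sided"),
                                   rng_seed = NULL) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  if (n_sets < 100L) stop("need at least 100 random sets")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  universe_set <- gene_set("universe", setdiff(rownames(x$values), seed))
  all_rho <- within_group_correlations(x, seed, universe_set)
  rownames(all_rho) <- all_rho$gene
  ok <- !is.na(all_rho$rho_control) & !is.na(all_rho$rho_case)
  all_rho <- all_rho[ok, , drop = FALSE]
  members <- intersect(setdiff(set$genes, seed), all_rho$gene)
  set_size <- length(members)
  if (set_size == 0L) stop("no set gene measured in the cohort")
  stat_fun <- switch(statistic,
    delta = function(gs) mean(all_rho[gs, "rho_case"]) -
      mean(all_rho[gs, "rho_control"]),
    inversion = function(gs) mean(all_rho[gs, "rho_control"] < 0 &
                                    all_rho[gs, "rho_case"] > 0))
  observed <- stat_fun(members)
  nulls <- vapply(seq_len(n_sets), function(i) {
    stat_fun(sample(all_rho$gene, set_size))
  }, numeric(1))
  res <- empirical_p(observed, nulls, tail = tail,
                     method = sprintf("random-gene-set specificity (%s, %d sets of %d)",
                                      statistic, n_sets, set_size))
  attr(res, "null_values") <- nulls
  res
}

#' Rank set genes by their average co-expression change across cohorts
#'
#' Averages each set gene's control and case correlations over the cohorts
#' in which it was measured and sorts by the case-minus-control difference,
#' largest increase first. Genes present in fewer than 2 cohorts are dropped
#' with a warning.
#'
#' @param datasets list of rank-normalised cohort datasets with conditions.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @return data.frame with columns `gene`, `mean_rho_control`,
#'   `mean_rho_case`, `difference`, `n_datasets`.
#' @export
per_gene_change_ranking <- function(datasets, seed, set) {
  if (length(datasets) < 2L) stop("need at least 2 cohorts")
  tabs <- lapply(datasets, within_group_correlations, seed = seed, set = set)
  all_genes <- unique(unlist(lapply(tabs, function(t) t$gene)))
  rows <- lapply(all_genes, function(g) {
    rc <- unlist(lapply(tabs, function(t) t$rho_control[t$gene == g]))
    rk <- unlist(lapply(tabs, function(t) t$rho_case[t$gene == g]))
    ok <- !is.na(rc) & !is.na(rk)
    if (sum(ok) < 2L) return(NULL)
    data.frame(gene = g, mean_rho_control = mean(rc[ok]),
               mean_rho_case = mean(rk[ok]),
               difference = mean(rk[ok]) - mean(rc[ok]),
               n_datasets = sum(ok), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(sprintf("per_gene_change_ranking: %d gene(s) present in <2 cohorts dropped",
                    dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene measured in >= 2 cohorts")
  out[order(-out$difference), , drop = FALSE]
}

#' Combine per-cohort differential p-values across studies
#'
#' Fisher or direction-aware Fisher ("trend") combination of one chosen
#' p-value column across the cohorts flagged for inclusion; contrast cohorts
#' (`include_in_meta = FALSE`) are left out, and the included set is
#' recorded. For the trend variant, each cohort's direction is the sign of
#' its mean correlation change.
#'
#' @param results list of [differential_statistics] results.
#' @param which `"label_perm"`, `"wilcoxon"` or `"inversion_perm"`.
#' @param method `"fisher"` or `"fisher_trend"`.
#' @return List of class `meta_result` with fields `statistic_name`,
#'   `datasets`, `p_values`, `directions`, `combined` (a [test_result]).
#' @export
meta_combine <- function(results,
                         which = c("label_perm", "wilcoxon",
                                   "inversion_perm"),
                         method = c("fisher_trend", "fisher")) {
  which <- match.arg(which)
  method <- match.arg(method)
  included <- Filter(function(r) isTRUE(r$include_in_meta), results)
  if (length(included) < 2L)
    stop("need at least 2 cohorts flagged for meta-combination")
  ps <- vapply(included, function(r) r[[which]]$p_value, numeric(1))
  dirs <- vapply(included, function(r) {
    d <- sign(r$mean_case - r$mean_control)
    if (d == 0) 1 else d
  }, numeric(1))
  combined <- combine_pvalues(ps,
                              directions = if (method == "fisher_trend") dirs,
                              method = method)
  structure(
    list(statistic_name = which,
         datasets = vapply(included, function(r) r$dataset, character(1)),
         p_values = ps, directions = dirs, combined = combined),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s over %d cohorts: combined p = %.3g\n",
              x$statistic_name, length(x$datasets), x$combined$p_value))
  invisible(x)
}

#' Cohort-level differential co-expression summary table
#'
#' One row per cohort with the sample size, the two group mean correlations,
#' the paired-Wilcoxon and label-permutation p-values, the inversion
#' percentage and its permutation p-value — the standard shape for
#' reporting a multi-study differential co-expression analysis.
#'
#' @param results list of [differential_statistics] results.
#' @return data.frame with columns `dataset`, `samples`, `mean_control`,
#'   `mean_case`, `wilcoxon_p`, `perm_p`, `inversion_pct`,
#'   `inversion_perm_p`, `include_in_meta`.
#' @export
differential_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(dataset = r$dataset, samples = r$n_subjects,
               mean_control = r$mean_control, mean_case = r$mean_case,
               wilcoxon_p = r$wilcoxon$p_value,
               perm_p = r$label_perm$p_value,
               inversion_pct = 100 * r$inversion_fraction,
               inversion_perm_p = r$inversion_perm$p_value,
               include_in_meta = r$include_in_meta,
               stringsAsFactors = FALSE)
  }))
}

#' Summarise a cohort-level differential table
#'
#' Computes, over the cohorts flagged for inclusion, the mean correlation
#' increase (mean of `mean_case - mean_control`) and the mean inversion
#' percentage. Works on any table with the [differential_table] columns,
#' including hand-entered published summary tables.
#'
#' @param tbl data.frame with at least `mean_control`, `mean_case`,
#'   `inversion_pct` and optionally `include_in_meta`.
#' @return List with `mean_correlation_increase`, `mean_inversion_pct`,
#'   `n_datasets`.
#' @export
summarize_differential_table <- function(tbl) {
  if ("include_in_meta" %in% names(tbl))
    tbl <- tbl[as.logical(tbl$include_in_meta), , drop = FALSE]
  if (nrow(tbl) == 0L) stop("no cohort included")
  list(mean_correlation_increase = mean(tbl$mean_case - tbl$mean_control),
       mean_inversion_pct = mean(tbl$inversion_pct),
       n_datasets = nrow(tbl))
}
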