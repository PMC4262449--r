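#' Run one stage of the seed-gene co-expression pipeline
#'
#' End-to-end orchestration over TSV/GMT inputs. The configuration is a
#' named list (or the path to a YAML file holding one) with fields:
#' \describe{
#'   \item{mode}{`"simulate"`, `"spatial"`, `"develop"`, `"disease"` or
#'     `"meta"`.}
#'   \item{out_dir}{output directory; every result table, the resolved
#'     configuration, and the run log are written here and nowhere else.}
#'   \item{seed_gene}{seed gene symbol (all modes but simulate/meta).}
#'   \item{gene_set_gmt, gene_set_name}{gene-set location.}
#'   \item{donors}{for spatial/develop: list of `list(expr=, meta=)` paths,
#'     one per donor.}
#'   \item{cohorts}{for disease: list of `list(label=, expr=, meta=,
#'     include_in_meta=)`.}
#'   \item{table}{for meta: path to a cohort-level summary TSV written by
#'     disease mode (columns of [differential_table]).}
#'   \item{n_permutations, n_random_sets}{resampling sizes (defaults 1000).}
#'   \item{rng_seed}{root seed; each stochastic stage derives and logs its
#'     own seed from it.}
#'   \item{prefilter_quantile, max_missing_fraction}{gene filter thresholds
#'     (defaults 0 and 1 = off).}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @param ... fields overriding the config (e.g. `mode`, `out_dir`).
#' @return Invisibly, a list of the stage's main results; all tables are
#'   also written under `out_dir`.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  mode <- match.arg(config$mode,
                    c("simulate", "spatial", "develop", "disease", "meta"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$rng_seed <- as.integer(config$rng_seed %||% 1L)
  config$n_permutations <- as.integer(config$n_permutations %||% 1000L)
  config$n_random_sets <- as.integer(config$n_random_sets %||% 1000L)
  config$prefilter_quantile <- config$prefilter_quantile %||% 0
  config$max_missing_fraction <- config$max_missing_fraction %||% 1

  log_path <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  jsonlite::write_json(config, file.path(out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("mode=%s rng_seed=%d", mode, config$rng_seed)

  result <- switch(mode,
    simulate = .stage_simulate(config, log_line),
    spatial = .stage_spatial(config, log_line),
    develop = .stage_develop(config, log_line),
    disease = .stage_disease(config, log_line),
    meta = .stage_meta(config, log_line))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.load_donors <- function(config, log_line) {
  set <- read_gene_set(config$gene_set_gmt, config$gene_set_name)
  donors <- lapply(config$donors, function(d) {
    ds <- read_expression(d$expr, d$meta)
    ds <- prefilter_genes(ds, config$prefilter_quantile,
                          config$max_missing_fraction)
    rank_dataset(ds)
  })
  log_line("loaded %d donor(s); gene universe sizes: %s; set '%s' (%d genes)",
           length(donors),
           paste(vapply(donors, function(d) nrow(d$values), integer(1)),
                 collapse = ","),
           set$name, length(set$genes))
  list(donors = donors, set = set)
}

.stage_simulate <- function(config, log_line) {
  manifest <- write_fixture_suite(file.path(config$out_dir, "fixtures"),
                                  rng_seed = config$rng_seed,
                                  overwrite = isTRUE(config$overwrite))
  log_line("fixture suite written (%d spatial donors, %d cohorts)",
           length(manifest$spatial_donors), length(manifest$cohorts))
  manifest
}

.stage_spatial <- function(config, log_line) {
  inp <- .load_donors(config, log_line)
  donors <- filter_common_regions(inp$donors)
  log_line("common regions: %d", ncol(donors[[1L]]$values))
  profiles <- lapply(donors, seed_profile, seed = config$seed_gene)
  coex <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(donor_id = p$donor_id, gene = names(p$rho_by_gene),
               rho = unname(p$rho_by_gene), stringsAsFactors = FALSE)
  }))
  .write_tsv(coex, file.path(config$out_dir, "seed_coexpression.tsv"))
  set_means <- vapply(profiles, function(p)
    as.numeric(set_mean_correlation(p, inp$set)), numeric(1))
  per_donor <- data.frame(
    donor_id = vapply(profiles, function(p) p$donor_id, character(1)),
    n_regions = vapply(profiles, function(p) p$n_regions, integer(1)),
    set_mean_rho = set_means, stringsAsFactors = FALSE)
  .write_tsv(per_donor, file.path(config$out_dir, "per_donor_set_mean.tsv"))
  log_line("grand mean seed-to-set rho over donors: %.4f", mean(set_means))
  attribution <- do.call(rbind, lapply(seq_along(donors), function(i) {
    if (ncol(donors[[i]]$values) < 4L) return(NULL)
    loro <- leave_one_region_out(donors[[i]], config$seed_gene, inp$set)
    cbind(donor_id = per_donor$donor_id[i], as.data.frame(loro))
  }))
  if (!is.null(attribution))
    .write_tsv(attribution, file.path(config$out_dir,
                                      "region_attribution.tsv"))
  summary <- list(grand_mean_rho = mean(set_means),
                  per_donor = per_donor$set_mean_rho,
                  rng_seed = config$rng_seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(profiles = profiles, per_donor = per_donor,
       attribution = attribution)
}

.stage_develop <- function(config, log_line) {
  inp <- .load_donors(config, log_line)
  rows <- per_donor_set_correlation(inp$donors, config$seed_gene, inp$set)
  trend <- age_trend(rows)
  .write_tsv(trend$rows, file.path(config$out_dir, "per_donor_trend.tsv"))
  log_line("age trend: rho=%.4f, analytic p=%.3g",
           trend$trend_rho, trend$trend_p$p_value)
  per_gene <- per_gene_age_trend(inp$donors, config$seed_gene)
  .write_tsv(per_gene, file.path(config$out_dir, "per_gene_trend.tsv"))
  null_seed <- config$rng_seed + 11L
  rsn <- random_set_null(inp$donors, config$seed_gene, inp$set,
                         n_sets = config$n_random_sets,
                         rng_seed = null_seed)
  log_line("random-set null (seed %d): p=%.4g", null_seed, rsn$p_value)
  scan <- seed_replacement_scan(inp$donors, inp$set, config$seed_gene)
  log_line("seed-replacement scan: k=%d of %d genes (p=%.4g)",
           scan$k, scan$n_universe, scan$p)
  ages <- vapply(inp$donors, function(d) d$meta$age_years[1L], numeric(1))
  contrast <- if (sum(ages < 0) >= 2L && sum(ages >= 0) >= 2L) {
    prenatal_postnatal_contrast(inp$donors, config$seed_gene, inp$set)
  }
  if (!is.null(contrast))
    log_line("prenatal mean %.4f vs postnatal mean %.4f (rank-sum p=%.3g)",
             contrast$prenatal, contrast$postnatal, contrast$test$p_value)
  summary <- list(trend_rho = trend$trend_rho,
                  trend_p = trend$trend_p$p_value,
                  random_set_p = rsn$p_value,
                  scan_k = scan$k, scan_n = scan$n_universe, scan_p = scan$p,
                  prenatal = contrast$prenatal,
                  postnatal = contrast$postnatal,
                  rng_seed = config$rng_seed, null_seed = null_seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(trend = trend, per_gene = per_gene, random_set_null = rsn,
       scan = scan, contrast = contrast)
}

.stage_disease <- function(config, log_line) {
  set <- read_gene_set(config$gene_set_gmt, config$gene_set_name)
  results <- lapply(seq_along(config$cohorts), function(i) {
    co <- config$cohorts[[i]]
    ds <- rank_dataset(prefilter_genes(read_expression(co$expr, co$meta),
                                       config$prefilter_quantile,
                                       config$max_missing_fraction))
    stage_seed <- config$rng_seed + 20L + i
    r <- differential_statistics(ds, config$seed_gene, set,
                                 n_permutations = config$n_permutations,
                                 rng_seed = stage_seed,
                                 dataset_label = co$label %||%
                                   sprintf("cohort%02d", i),
                                 include_in_meta =
                                   !isFALSE(co$include_in_meta))
    log_line("%s: n=%d, denominators %d set genes, delta=%+.4f, perm seed %d",
             r$dataset, r$n_subjects, r$n_evaluated, r$delta, stage_seed)
    r
  })
  tbl <- differential_table(results)
  .write_tsv(tbl, file.path(config$out_dir, "differential_table.tsv"))
  per_gene <- do.call(rbind, lapply(results, function(r)
    cbind(dataset = r$dataset, r$per_gene)))
  .write_tsv(per_gene, file.path(config$out_dir,
                                 "per_gene_correlations.tsv"))
  summ <- summarize_differential_table(tbl)
  log_line("included cohorts: mean correlation increase %.4f, mean inversions %.2f%%",
           summ$mean_correlation_increase, summ$mean_inversion_pct)
  jsonlite::write_json(c(summ, list(rng_seed = config$rng_seed)),
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(results = results, table = tbl, summary = summ)
}

.stage_meta <- function(config, log_line) {
  tbl <- utils::read.delim(config$table, stringsAsFactors = FALSE)
  inc <- tbl[as.logical(tbl$include_in_meta), , drop = FALSE]
  if (nrow(inc) < 2L) stop("need >= 2 cohorts flagged include_in_meta")
  log_line("meta over %d of %d cohorts: %s", nrow(inc), nrow(tbl),
           paste(inc$dataset, collapse = ", "))
  dirs <- sign(inc$mean_case - inc$mean_control)
  dirs[dirs == 0] <- 1
  combos <- list()
  for (col in c("wilcoxon_p", "perm_p", "inversion_perm_p")) {
    for (m in c("fisher", "fisher_trend")) {
      combos[[paste(col, m, sep = ".")]] <-
        combine_pvalues(inc[[col]], directions = dirs, method = m)$p_value
    }
  }
  summary <- c(list(datasets = inc$dataset,
                    mean_correlation_increase =
                      mean(inc$mean_case - inc$mean_control),
                    mean_inversion_pct = mean(inc$inversion_pct)),
               combos)
  jsonlite::write_json(summary, file.path(config$out_dir,
                                          "meta_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("combined (fisher_trend) permutation p: %.3g",
           combos[["perm_p.fisher_trend"]])
  summary
}
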