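#' Per-donor seed-to-set correlation table
#'
#' One row per donor: the mean Spearman correlation between the seed gene
#' and the gene set across that donor's regions, together with the donor's
#' age. Donors with a single region cannot support a correlation and are
#' skipped with a warning; donors with exactly two regions are kept (their
#' value is forced to -1 or +1) but flagged, and can be excluded via
#' `include_two_region`.
#'
#' @param donors list of one-donor rank-normalised `expression_dataset`s
#'   with `age_years` metadata.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @param include_two_region keep flagged 2-region donors (default TRUE).
#' @return data.frame with columns `donor_id`, `age_years`, `n_regions`,
#'   `value`, `flagged_two_regions`.
#' @export
per_donor_set_correlation <- function(donors, seed, set,
                                      include_two_region = TRUE) {
  rows <- lapply(donors, function(d) {
    if (!"age_years" %in% names(d$meta))
      stop("developmental analysis requires age_years metadata")
    if (ncol(d$values) < 2L) {
      warning(sprintf("donor '%s' has a single region; skipped",
                      unique(d$meta$donor_id)))
      return(NULL)
    }
    prof <- seed_profile(d, seed)
    if (prof$flagged_two_regions && !include_two_region) return(NULL)
    data.frame(donor_id = prof$donor_id,
               age_years = d$meta$age_years[1L],
               n_regions = prof$n_regions,
               value = as.numeric(set_mean_correlation(prof, set)),
               flagged_two_regions = prof$flagged_two_regions,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no donor yielded a seed-to-set correlation")
  rownames(out) <- NULL
  out
}

#' Trend of a per-donor quantity over age
#'
#' Spearman correlation of the per-donor values against donor age, with the
#' analytic two-sided p-value. Spearman (rather than a linear fit) is used
#' because ages span prenatal weeks to decades on one signed axis and only
#' monotonicity is claimed.
#'
#' @param rows data.frame with columns `age_years` and `value` (one row per
#'   donor), e.g. from [per_donor_set_correlation].
#' @return An object of class `age_trend`: list with `rows`, `trend_rho`,
#'   `trend_p` (a [test_result]).
#' @export
age_trend <- function(rows) {
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  if (nrow(rows) < 4L) stop("need at least 4 donors for an age trend")
  if (length(unique(rows$age_years)) < 2L) stop("all donor ages are tied")
  ct <- suppressWarnings(
    stats::cor.test(rows$age_years, rows$value, method = "spearman",
                    exact = FALSE))
  structure(
    list(rows = rows,
         trend_rho = unname(ct$estimate),
         trend_p = test_result(unname(ct$estimate),
                               max(ct$p.value, .Machine$double.xmin),
                               tail = "two_sided",
                               method = "Spearman trend over age (analytic)")),
    class = "age_trend"
  )
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("<age_trend> %d donors: rho = %.3f, p = %.3g\n",
              nrow(x$rows), x$trend_rho, x$trend_p$p_value))
  invisible(x)
}

#' Row means of a candidate-by-setgene correlation matrix, excluding each
#' set gene's self-correlation and ignoring undefined (NA) correlations
#' from genes that are constant in a donor or group.
#' @noRd
.set_mean_rows <- function(M, universe, members) {
  tot <- rowSums(M, na.rm = TRUE)
  cnt <- rowSums(!is.na(M))
  in_set <- universe %in% members
  sel <- cbind(which(in_set), match(universe[in_set], members))
  self <- M[sel]
  tot[in_set] <- tot[in_set] - ifelse(is.na(self), 0, self)
  cnt[in_set] <- cnt[in_set] - ifelse(is.na(self), 0L, 1L)
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Per-donor correlation of the seed with every gene
#'
#' Internal workhorse: matrix of seed-to-gene Spearman correlations, one row
#' per donor, one column per gene (seed excluded).
#' @noRd
.donor_gene_rho_matrix <- function(donors, seed) {
  profs <- lapply(donors, seed_profile, seed = seed)
  genes <- Reduce(intersect, lapply(profs, function(p) names(p$rho_by_gene)))
  mat <- t(vapply(profs, function(p) p$rho_by_gene[genes],
                  numeric(length(genes))))
  rownames(mat) <- vapply(profs, function(p) p$donor_id, character(1))
  list(rho = mat,
       ages = vapply(donors, function(d) d$meta$age_years[1L], numeric(1)))
}

#' Age trend of the seed's correlation with each individual gene
#'
#' Computes, for every gene (or the genes of a set), the trend over donor
#' age of the per-donor seed-to-gene Spearman correlation. Sorting the
#' resulting table exposes the genes whose coupling to the seed most
#' decreases or increases with age. Genes whose correlation is undefined in
#' some donors are dropped when fewer than `min_donors` values remain.
#'
#' @param donors list of one-donor rank-normalised datasets with ages.
#' @param seed seed gene symbol.
#' @param set optional [gene_set]; default uses every gene.
#' @param min_donors minimum donors with a defined correlation (default 4).
#' @return data.frame with columns `gene`, `trend_rho`, `trend_p`,
#'   `n_donors`, sorted by `trend_rho` ascending (strongest decrease first).
#' @export
per_gene_age_trend <- function(donors, seed, set = NULL, min_donors = 4L) {
  dm <- .donor_gene_rho_matrix(donors, seed)
  genes_use <- colnames(dm$rho)
  if (!is.null(set)) genes_use <- intersect(genes_use, setdiff(set$genes, seed))
  if (length(genes_use) == 0L) stop("no usable gene")
  rows <- lapply(genes_use, function(g) {
    v <- dm$rho[, g]
    ok <- !is.na(v)
    if (sum(ok) < min_donors) return(NULL)
    ct <- suppressWarnings(
      stats::cor.test(dm$ages[ok], v[ok], method = "spearman", exact = FALSE))
    data.frame(gene = g, trend_rho = unname(ct$estimate),
               trend_p = max(ct$p.value, .Machine$double.xmin),
               n_donors = sum(ok),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    message(sprintf("per_gene_age_trend: %d gene(s) dropped (<%d donors)",
                    dropped, min_donors))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("every gene was dropped")
  out[order(out$trend_rho), , drop = FALSE]
}

#' Prenatal versus postnatal seed-to-set correlation
#'
#' Splits at age 0 (birth). Two modes:
#' \describe{
#'   \item{per_donor}{one seed-to-set value per donor, then a Wilcoxon
#'     rank-sum test between the prenatal and postnatal donor groups;}
#'   \item{pooled}{all prenatal samples pooled into one group and all
#'     postnatal samples into another, the seed-to-set correlation computed
#'     across the pooled samples of each group, and a paired Wilcoxon over
#'     the per-set-gene correlations between the two groups.}
#' }
#'
#' @param donors list of one-donor rank-normalised datasets with ages.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @param mode `"per_donor"` or `"pooled"`.
#' @return List with `prenatal`, `postnatal` (group correlation summaries),
#'   `n_prenatal`, `n_postnatal`, and `test` (a [test_result]).
#' @export
prenatal_postnatal_contrast <- function(donors, seed, set,
                                        mode = c("per_donor", "pooled")) {
  mode <- match.arg(mode)
  ages <- vapply(donors, function(d) d$meta$age_years[1L], numeric(1))
  pre <- donors[ages < 0]
  post <- donors[ages >= 0]
  if (length(pre) == 0L) stop("prenatal group is empty")
  if (length(post) == 0L) stop("postnatal group is empty")
  if (mode == "per_donor") {
    if (length(pre) < 2L || length(post) < 2L)
      stop("per-donor mode needs >= 2 donors on each side of birth")
    rows_pre <- per_donor_set_correlation(pre, seed, set)
    rows_post <- per_donor_set_correlation(post, seed, set)
    list(prenatal = mean(rows_pre$value), postnatal = mean(rows_post$value),
         n_prenatal = nrow(rows_pre), n_postnatal = nrow(rows_post),
         per_donor = rbind(cbind(rows_pre, group = "prenatal"),
                           cbind(rows_post, group = "postnatal")),
         test = ranksum_test(rows_pre$value, rows_post$value))
  } else {
    pool <- function(ds_list) {
      vals <- do.call(cbind, lapply(ds_list, function(d) d$values))
      meta <- data.frame(sample_id = colnames(vals), donor_id = "pooled",
                         stringsAsFactors = FALSE)
      structure(list(values = vals, meta = meta, ranked = TRUE),
                class = "expression_dataset")
    }
    prof_pre <- seed_profile(pool(pre), seed)
    prof_post <- seed_profile(pool(post), seed)
    members <- setdiff(set$genes, seed)
    common <- intersect(intersect(members, names(prof_pre$rho_by_gene)),
                        names(prof_post$rho_by_gene))
    if (length(common) == 0L) stop("no set gene measured in both groups")
    list(prenatal = mean(prof_pre$rho_by_gene[common], na.rm = TRUE),
         postnatal = mean(prof_post$rho_by_gene[common], na.rm = TRUE),
         n_prenatal = prof_pre$n_regions, n_postnatal = prof_post$n_regions,
         test = paired_wilcoxon(prof_pre$rho_by_gene[common],
                                prof_post$rho_by_gene[common]))
  }
}

#' Random-gene-set specificity null for a developmental statistic
#'
#' Tests whether the observed statistic for the real gene set (by default
#' the Spearman trend over age of the per-donor seed-to-set correlation) is
#' extreme relative to random gene sets of the same size drawn from the
#' measured gene universe. The seed is excluded from the universe; the real
#' set's genes are not (their overlap expectation with a random draw is
#' negligible). Per-donor seed-to-gene correlations are computed once, so
#' each random set only averages precomputed values.
#'
#' @param donors list of one-donor rank-normalised datasets with ages.
#' @param seed seed gene symbol.
#' @param set the real [gene_set].
#' @param n_sets number of random sets (>= 100).
#' @param statistic `"trend_rho"` (default) or `"prenatal_postnatal"` (the
#'   postnatal-minus-prenatal difference of per-donor group means).
#' @param tail tail for the empirical p-value; defaults to `"lower"`, i.e.
#'   testing for a more negative statistic than random sets give.
#' @param rng_seed optional integer seed for reproducible draws.
#' @return A [test_result]; the null vector is attached as attribute
#'   `null_values` for auditing.
#' @export
random_set_null <- function(donors, seed, set, n_sets = 1000L,
                            statistic = c("trend_rho", "prenatal_postnatal"),
                            tail = c("lower", "upper", "two_sided"),
                            rng_seed = NULL) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  if (n_sets < 100L) stop("need at least 100 random sets")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dm <- .donor_gene_rho_matrix(donors, seed)
  universe <- colnames(dm$rho)[colSums(is.na(dm$rho)) == 0]
  members <- intersect(setdiff(set$genes, seed), universe)
  set_size <- length(members)
  if (set_size == 0L) stop("no set gene in the measured universe")
  if (length(universe) < 10L * set_size)
    warning("gene universe is less than 10x the set size; null is coarse")
  stat_fun <- switch(statistic,
    trend_rho = function(gs) {
      vals <- rowMeans(dm$rho[, gs, drop = FALSE])
      stats::cor(dm$ages, vals, method = "spearman")
    },
    prenatal_postnatal = function(gs) {
      vals <- rowMeans(dm$rho[, gs, drop = FALSE])
      mean(vals[dm$ages >= 0]) - mean(vals[dm$ages < 0])
    })
  observed <- stat_fun(members)
  nulls <- vapply(seq_len(n_sets), function(i) {
    stat_fun(sample(universe, set_size))
  }, numeric(1))
  failed <- sum(is.na(nulls))
  if (failed > 0.01 * n_sets)
    stop(sprintf("statistic failed on %d/%d null sets", failed, n_sets))
  res <- empirical_p(observed, nulls, tail = tail,
                     method = sprintf("random-gene-set null (%s, %d sets of %d)",
                                      statistic, n_sets, set_size))
  attr(res, "null_values") <- nulls
  res
}

#' Seed-replacement specificity scan
#'
#' Recomputes the chosen statistic with every gene of the universe playing
#' the seed role against the same gene set, and counts how many genes give a
#' strictly more extreme statistic than the designated seed. Candidate genes
#' belonging to the set are correlated against the set minus themselves,
#' mirroring the seed-excluded-from-set rule. Two p-value conventions are
#' reported: the plain proportion k/N and the add-one (k+1)/(N+1), the
#' latter being the decision value because it can never be zero. Ties with
#' the seed's statistic are not counted as beating it; their number is
#' recorded.
#'
#' @param donors list of one-donor rank-normalised datasets with ages.
#' @param set the [gene_set].
#' @param seed the designated seed gene symbol.
#' @param statistic `"trend_rho"` or `"prenatal_postnatal"` as in
#'   [random_set_null].
#' @param tail `"lower"` (default): more extreme = smaller statistic.
#' @return List with `k` (count of genes beating the seed), `n_universe`,
#'   `extreme_genes`, `n_ties`, `p_plain` (k/N), `p` ((k+1)/(N+1)),
#'   `statistics` (named vector over the universe), `seed_statistic`.
#' @export
seed_replacement_scan <- function(donors, set, seed,
                                  statistic = c("trend_rho",
                                                "prenatal_postnatal"),
                                  tail = c("lower", "upper")) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  ages <- vapply(donors, function(d) d$meta$age_years[1L], numeric(1))
  universe <- Reduce(intersect, lapply(donors, function(d) rownames(d$values)))
  members_all <- intersect(set$genes, universe)
  if (length(members_all) == 0L) stop("no set gene in the shared universe")
  if (length(universe) < 100L)
    warning("universe below 100 genes: scan p-value resolution is poor")
  if (!seed %in% universe) stop("designated seed not in the shared universe")
  # per donor: candidate-by-setgene Spearman correlation matrix
  per_donor_mean <- vapply(donors, function(d) {
    A <- d$values[universe, , drop = FALSE]
    S <- d$values[members_all, , drop = FALSE]
    M <- suppressWarnings(stats::cor(t(A), t(S), method = "spearman"))
    .set_mean_rows(M, universe, members_all)
  }, numeric(length(universe)))
  stats_vec <- switch(statistic,
    trend_rho = apply(per_donor_mean, 1L, function(v) {
      ok <- !is.na(v)
      if (sum(ok) < 4L) return(NA_real_)
      stats::cor(ages[ok], v[ok], method = "spearman")
    }),
    prenatal_postnatal = apply(per_donor_mean, 1L, function(v)
      mean(v[ages >= 0], na.rm = TRUE) - mean(v[ages < 0], na.rm = TRUE)))
  names(stats_vec) <- universe
  seed_stat <- stats_vec[[seed]]
  others <- stats_vec[setdiff(universe, seed)]
  beats <- if (tail == "lower") others < seed_stat else others > seed_stat
  ties <- sum(others == seed_stat, na.rm = TRUE)
  if (ties > 0L)
    message(sprintf("seed_replacement_scan: %d tie(s) with the seed statistic (not counted as more extreme)",
                    ties))
  k <- sum(beats, na.rm = TRUE)
  n_total <- sum(!is.na(stats_vec))
  list(k = k, n_universe = n_total,
       extreme_genes = names(others)[which(beats)],
       n_ties = ties,
       p_plain = k / n_total,
       p = (k + 1) / (n_total + 1),
       statistics = stats_vec, seed_statistic = seed_stat)
}
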