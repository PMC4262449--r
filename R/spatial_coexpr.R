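#' Per-donor spatial co-expression profile of a seed gene
#'
#' For one donor whose samples are brain regions, computes the Spearman
#' correlation across regions between the seed gene and every other gene.
#' The input is expected to be rank-normalised per sample (the global
#' preprocessing); Spearman then re-ranks each gene's profile across regions,
#' so the result is invariant to any monotone per-sample transform.
#'
#' Genes that are constant across the donor's regions have no defined
#' correlation and get NA (counted in a message). The seed's own entry is
#' excluded rather than reported as a guaranteed 1. Donors with exactly two
#' regions are flagged: every correlation is then forced to -1 or +1 and
#' carries no magnitude information.
#'
#' @param x a one-donor, rank-normalised `expression_dataset` whose samples
#'   are regions.
#' @param seed seed gene symbol (must be a row of the dataset).
#' @return An object of class `coexpression_profile` with fields `donor_id`,
#'   `seed`, `rho_by_gene` (named vector, seed excluded), `n_regions`,
#'   `flagged_two_regions`.
#' @export
seed_profile <- function(x, seed) {
  if (!x$ranked) stop("dataset must be rank-normalised first (rank_dataset)")
  if (!seed %in% rownames(x$values)) stop(sprintf("seed gene '%s' absent", seed))
  donors <- unique(x$meta$donor_id)
  if (length(donors) > 1L) stop("seed_profile works one donor at a time")
  n_regions <- ncol(x$values)
  if (n_regions < 2L) stop("need at least 2 regions")
  seed_vec <- x$values[seed, ]
  if (diff(range(seed_vec)) == 0)
    stop(sprintf("seed gene '%s' is constant across regions", seed))
  others <- x$values[setdiff(rownames(x$values), seed), , drop = FALSE]
  const <- apply(others, 1L, function(r) diff(range(r)) == 0)
  rho <- rep(NA_real_, nrow(others))
  names(rho) <- rownames(others)
  if (any(!const)) {
    rho[!const] <- suppressWarnings(
      stats::cor(seed_vec, t(others[!const, , drop = FALSE]),
                 method = "spearman"))[1L, ]
    # perfectly (anti)correlated profiles must report exactly +/-1, not a
    # value floating-point epsilon away (two-region donors in particular)
    unit <- !is.na(rho) & abs(abs(rho) - 1) < 1e-12
    rho[unit] <- sign(rho[unit])
  }
  if (any(const))
    message(sprintf("seed_profile: %d constant gene(s) have undefined rho",
                    sum(const)))
  structure(
    list(donor_id = if (length(donors)) donors else NA_character_,
         seed = seed, rho_by_gene = rho, n_regions = n_regions,
         flagged_two_regions = n_regions == 2L),
    class = "coexpression_profile"
  )
}

#' @export
print.coexpression_profile <- function(x, ...) {
  cat(sprintf("<coexpression_profile> donor %s, seed %s, %d genes, %d regions%s\n",
              x$donor_id, x$seed, length(x$rho_by_gene), x$n_regions,
              if (x$flagged_two_regions) " [2-region donor: rho is +/-1]" else ""))
  invisible(x)
}

#' Mean seed-to-set correlation
#'
#' Arithmetic mean of the profile correlations over the genes of a set. Set
#' genes absent from the profile (or with undefined correlation) are skipped
#' and counted in a message; the seed itself is excluded from the set if
#' present. The number of genes actually evaluated is attached as attribute
#' `n_evaluated` so denominators are always auditable.
#'
#' @param profile a [seed_profile] result.
#' @param set a [gene_set].
#' @return Mean Spearman rho (numeric scalar) with attribute `n_evaluated`.
#' @export
set_mean_correlation <- function(profile, set) {
  members <- setdiff(set$genes, profile$seed)
  rhos <- profile$rho_by_gene[intersect(members, names(profile$rho_by_gene))]
  skipped <- length(members) - sum(!is.na(rhos))
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0L)
    stop(sprintf("no gene of set '%s' has a defined correlation", set$name))
  if (skipped > 0L)
    message(sprintf("set_mean_correlation: %d set gene(s) skipped", skipped))
  structure(mean(rhos), n_evaluated = length(rhos))
}

#' Rank regions by a gene's expression across donors
#'
#' For each region shared by the donors, takes the median across donors of
#' the gene's within-sample rank in that region, and orders regions from
#' highest to lowest. Tied medians are broken alphabetically by region label
#' (noted in a message).
#'
#' @param donor_datasets list of rank-normalised one-donor datasets already
#'   restricted to common regions ([filter_common_regions]).
#' @param gene gene symbol to rank regions by.
#' @return data.frame with columns `region`, `median_rank`, and `rank_order`
#'   (1 = highest median expression rank).
#' @export
regional_expression_ranking <- function(donor_datasets, gene) {
  mats <- lapply(donor_datasets, function(d) {
    if (!d$ranked) stop("datasets must be rank-normalised")
    if (!gene %in% rownames(d$values))
      stop(sprintf("gene '%s' absent from a donor", gene))
    stats::setNames(d$values[gene, ], d$meta$region)
  })
  regions <- names(mats[[1L]])
  per_donor <- vapply(mats, function(v) v[regions], numeric(length(regions)))
  med <- apply(as.matrix(per_donor), 1L, stats::median)
  if (anyDuplicated(med))
    message("regional_expression_ranking: tied medians broken alphabetically")
  ord <- order(-med, regions)
  data.frame(region = regions[ord], median_rank = med[ord],
             rank_order = seq_along(regions), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Leave-one-region-out attribution of the seed-to-set correlation
#'
#' For each region r of a donor, recomputes the seed-to-set mean correlation
#' with r excluded and reports delta(r) = full - without(r). With the
#' negative correlations this analysis targets, a large negative delta means
#' removing the region moves the mean correlation toward zero, i.e. the
#' region contributes strongly to the anti-correlation; the sign convention
#' is recorded in the `sign_convention` attribute.
#'
#' @param x one-donor rank-normalised `expression_dataset` with >= 4
#'   regions.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @return data.frame of class `region_attribution` with columns `region`
#'   and `delta`, ordered as the dataset's regions.
#' @export
leave_one_region_out <- function(x, seed, set) {
  if (ncol(x$values) < 4L) stop("need at least 4 regions for leave-one-out")
  full <- as.numeric(set_mean_correlation(seed_profile(x, seed), set))
  regions <- x$meta$region
  deltas <- vapply(seq_along(regions), function(i) {
    reduced <- subset_samples(x, -i)
    full - as.numeric(set_mean_correlation(seed_profile(reduced, seed), set))
  }, numeric(1))
  out <- data.frame(region = regions, delta = deltas,
                    stringsAsFactors = FALSE)
  attr(out, "full_correlation") <- full
  attr(out, "sign_convention") <-
    "delta = corr(all regions) - corr(without region); for a negative full correlation, the most negative delta marks the top-contributing region"
  class(out) <- c("region_attribution", "data.frame")
  out
}

#' Seed-to-set correlation within major brain divisions
#'
#' Computes [set_mean_correlation] separately within each major division's
#' regions (telencephalon, metencephalon, ...). Divisions with fewer than 3
#' regions are skipped with a warning: a 2-region correlation is forced to
#' +/-1 and carries no information.
#'
#' @param x one-donor rank-normalised `expression_dataset`.
#' @param seed seed gene symbol.
#' @param set a [gene_set].
#' @param division_map data.frame with columns `region` and `division`.
#' @return data.frame with columns `division`, `n_regions`, `mean_rho`.
#' @export
division_correlations <- function(x, seed, set, division_map) {
  div <- division_map$division[match(x$meta$region, division_map$region)]
  if (anyNA(div)) stop("some regions are missing from the division map")
  out <- lapply(unique(div), function(d) {
    idx <- which(div == d)
    if (length(idx) < 3L) {
      warning(sprintf("division '%s' has %d region(s) (<3); skipped",
                      d, length(idx)))
      return(NULL)
    }
    sub <- subset_samples(x, idx)
    rho <- as.numeric(set_mean_correlation(seed_profile(sub, seed), set))
    data.frame(division = d, n_regions = length(idx), mean_rho = rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
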