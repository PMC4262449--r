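#' Specification for a simulated multi-region spatial donor
#'
#' Single-latent-factor Gaussian model for one donor: every region r has a
#' latent activity z_r ~ N(0, 1); the seed gene tracks z with unit loading,
#' each set gene tracks z with an age-dependent loading
#' c(age) = c0 + c1 * age, and background genes are pure noise. All genes
#' receive independent Gaussian noise of standard deviation `noise_sd`, and
#' the emitted expression values are exponentiated so that the matrix is on
#' a positive, skewed scale and downstream rank-normalisation is exercised
#' realistically.
#'
#' The planted Pearson correlation between seed and a set gene at loading c
#' is c / sqrt((1 + sd^2) (c^2 + sd^2)); the corresponding population
#' Spearman value is 6/pi * asin(rho_pearson / 2) (bivariate normal), see
#' [planted_spearman].
#'
#' @param n_genes total genes (seed + set + background).
#' @param n_set_genes number of planted set genes (default 73, the size of
#'   an interferon-gamma signaling pathway set).
#' @param n_regions regions per donor; a single number, or a vector (one
#'   per donor) consumed by [simulate_spatial_study].
#' @param ages donor ages in years, signed (negative = prenatal; a donor at
#'   8 post-conception weeks is (8 - 40) * 7 / 365.25 = -0.61 years).
#' @param c0,c1 intercept and slope of the set-gene loading over age.
#' @param noise_sd per-gene Gaussian noise standard deviation (> 0).
#' @param rng_seed base RNG seed; donor i of a study uses rng_seed + i.
#' @return A validated `spatial_sim_spec` list.
#' @export
spatial_sim_spec <- function(n_genes = 500L, n_set_genes = 73L,
                             n_regions = 14L, ages = default_study_ages(),
                             c0 = 0.15, c1 = -0.016, noise_sd = 1,
                             rng_seed = 1L) {
  stopifnot(n_set_genes < n_genes, noise_sd > 0, all(n_regions >= 2L),
            length(ages) >= 1L)
  structure(list(n_genes = as.integer(n_genes),
                 n_set_genes = as.integer(n_set_genes),
                 n_regions = as.integer(n_regions), ages = as.numeric(ages),
                 c0 = c0, c1 = c1, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "spatial_sim_spec")
}

#' Default donor ages for a simulated developmental study
#'
#' 41 ages spanning 8 post-conception weeks (-0.61 years) to 40 years,
#' denser before birth and in childhood, mirroring the donor age structure
#' of public developmental brain expression resources.
#'
#' @return Numeric vector of 41 signed ages in years.
#' @export
default_study_ages <- function() {
  c(-0.61, -0.56, -0.52, -0.48, -0.44, -0.40, -0.36, -0.33, -0.29, -0.25,
    -0.21, -0.17, -0.13, -0.10, -0.06, -0.02,
    0.10, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8,
    10, 11, 13, 15, 18, 19, 21, 23, 30, 36, 37, 40)
}

.gene_names <- function(spec) {
  c("SEED",
    sprintf("SETG%03d", seq_len(spec$n_set_genes)),
    sprintf("BG%04d", seq_len(spec$n_genes - spec$n_set_genes - 1L)))
}

#' Planted population Spearman correlation
#'
#' Closed form for the model of [spatial_sim_spec]: the Pearson correlation
#' between seed (unit loading) and a set gene with loading `c`, both with
#' noise sd `noise_sd`, converted to the population Spearman value via the
#' bivariate-normal relation 6/pi * asin(rho/2).
#'
#' @param c set-gene loading.
#' @param noise_sd noise standard deviation.
#' @return Population Spearman correlation.
#' @export
planted_spearman <- function(c, noise_sd) {
  rho_p <- c / sqrt((1 + noise_sd^2) * (c^2 + noise_sd^2))
  6 / pi * asin(rho_p / 2)
}

#' Simulate one spatial donor
#'
#' @param spec a [spatial_sim_spec].
#' @param age donor age in signed years (sets the set-gene loading).
#' @param donor_id donor label.
#' @param n_regions number of regions for this donor (defaults to
#'   `spec$n_regions[1]`).
#' @param rng_seed RNG seed for this donor (defaults to `spec$rng_seed`).
#' @return An unranked `expression_dataset` with regions R01..Rnn and full
#'   metadata; attribute `truth` records the planted loading.
#' @export
simulate_spatial_donor <- function(spec, age, donor_id = "D01",
                                   n_regions = spec$n_regions[1L],
                                   rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "spatial_sim_spec"), n_regions >= 2L)
  set.seed(rng_seed)
  R <- as.integer(n_regions)
  loading <- spec$c0 + spec$c1 * age
  z <- stats::rnorm(R)
  noise <- matrix(stats::rnorm(spec$n_genes * R, sd = spec$noise_sd),
                  nrow = spec$n_genes)
  signal <- rbind(z,
                  matrix(rep(loading * z, each = spec$n_set_genes),
                         nrow = spec$n_set_genes, byrow = FALSE),
                  matrix(0, nrow = spec$n_genes - spec$n_set_genes - 1L,
                         ncol = R))
  vals <- exp(signal + noise)
  rownames(vals) <- .gene_names(spec)
  regions <- sprintf("R%02d", seq_len(R))
  colnames(vals) <- paste(donor_id, regions, sep = "_")
  meta <- data.frame(sample_id = colnames(vals), donor_id = donor_id,
                     age_years = age, region = regions,
                     stringsAsFactors = FALSE)
  out <- expression_dataset(vals, meta)
  attr(out, "truth") <- list(loading = loading, age = age,
                             rng_seed = rng_seed,
                             planted_spearman = planted_spearman(loading,
                                                                 spec$noise_sd))
  out
}

#' Simulate a whole multi-donor developmental study
#'
#' One donor per age in `spec$ages`; donor i uses seed `spec$rng_seed + i`
#' and the i-th entry of `spec$n_regions` (recycled).
#'
#' @param spec a [spatial_sim_spec].
#' @return Named list of unranked one-donor `expression_dataset`s.
#' @export
simulate_spatial_study <- function(spec) {
  n <- length(spec$ages)
  regions <- rep_len(spec$n_regions, n)
  out <- lapply(seq_len(n), function(i) {
    simulate_spatial_donor(spec, age = spec$ages[i],
                           donor_id = sprintf("D%02d", i),
                           n_regions = regions[i],
                           rng_seed = spec$rng_seed + i)
  })
  names(out) <- sprintf("D%02d", seq_len(n))
  out
}

#' Specification for a simulated case/control cohort
#'
#' Per-subject latent factor model: subject s has z_s ~ N(0, 1); the seed
#' tracks z with unit loading; a fraction `rewired_fraction` of the set
#' genes use `loading_control` in controls and `loading_case` in cases (the
#' planted rewiring), the remaining set genes use `loading_control` in both
#' groups; background genes are noise. Values are exponentiated as in the
#' spatial model.
#'
#' @param n_control,n_case group sizes (>= 2).
#' @param loading_control,loading_case set-gene loadings per condition.
#' @param rewired_fraction fraction f of set genes whose loading switches
#'   between groups, in \[0, 1\].
#' @param n_genes,n_set_genes,rng_seed as in [spatial_sim_spec].
#' @param noise_sd per-gene noise standard deviation (default 0.8, giving a
#'   planted within-group Spearman correlation of about 0.33 at loading 0.4).
#' @return A validated `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_control, n_case, loading_control = -0.4,
                            loading_case = 0.4, rewired_fraction = 0.5,
                            n_genes = 500L, n_set_genes = 73L,
                            noise_sd = 0.8, rng_seed = 1L) {
  stopifnot(n_control >= 2L, n_case >= 2L,
            rewired_fraction >= 0, rewired_fraction <= 1,
            n_set_genes < n_genes, noise_sd > 0)
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 loading_control = loading_control,
                 loading_case = loading_case,
                 rewired_fraction = rewired_fraction,
                 n_genes = as.integer(n_genes),
                 n_set_genes = as.integer(n_set_genes),
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "cohort_sim_spec")
}

#' Simulate a case/control cohort
#'
#' @param spec a [cohort_sim_spec].
#' @param dataset_label label stored in the subject ids.
#' @return An unranked `expression_dataset` with a `condition` column;
#'   attribute `truth` records the planted loadings, the rewired gene names
#'   and the RNG seed.
#' @export
simulate_cohort <- function(spec, dataset_label = "cohort") {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_control + spec$n_case
  condition <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
  z <- stats::rnorm(n)
  n_rewired <- round(spec$rewired_fraction * spec$n_set_genes)
  # loadings: set gene x subject
  loading <- matrix(spec$loading_control, nrow = spec$n_set_genes, ncol = n)
  if (n_rewired > 0L)
    loading[seq_len(n_rewired), condition == "case"] <- spec$loading_case
  signal <- rbind(z,
                  loading * matrix(rep(z, each = spec$n_set_genes),
                                   nrow = spec$n_set_genes),
                  matrix(0, nrow = spec$n_genes - spec$n_set_genes - 1L,
                         ncol = n))
  noise <- matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                  nrow = spec$n_genes)
  vals <- exp(signal + noise)
  rownames(vals) <- .gene_names(spec)
  colnames(vals) <- sprintf("%s_S%03d", dataset_label, seq_len(n))
  meta <- data.frame(sample_id = colnames(vals),
                     donor_id = colnames(vals), condition = condition,
                     stringsAsFactors = FALSE)
  out <- expression_dataset(vals, meta)
  gene_names <- .gene_names(spec)
  attr(out, "truth") <- list(
    loading_control = spec$loading_control,
    loading_case = spec$loading_case,
    rewired_fraction = spec$rewired_fraction,
    rewired_genes = gene_names[1L + seq_len(n_rewired)],
    rng_seed = spec$rng_seed)
  out
}

#' Write the standard synthetic test corpus
#'
#' Emits a complete fixture suite with known ground truth:
#' \itemize{
#'   \item 10 spatial donors with ages from -0.5 to 40 years and region
#'     counts from 2 to 16 (one deliberately two-region donor);
#'   \item 4 target-tissue case/control cohorts with the sample sizes of
#'     published substantia-nigra cohort studies (25, 39, 29, 33) and
#'     planted rewiring, plus one 105-subject contrast cohort with no
#'     rewiring (blood-like negative control);
#'   \item a GMT file with the 73 synthetic set gene symbols;
#'   \item a JSON manifest listing every file, its RNG seed and the planted
#'     ground-truth parameters.
#' }
#'
#' @param out_dir output directory.
#' @param rng_seed base seed; every file's own seed is derived from it and
#'   recorded in the manifest.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
write_fixture_suite <- function(out_dir, rng_seed = 20260101L,
                                overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop(sprintf("directory '%s' is not empty (set overwrite = TRUE)",
                 out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rng_seed <- as.integer(rng_seed)

  spatial_ages <- c(-0.5, -0.3, -0.1, 0.5, 2, 8, 15, 25, 33, 40)
  spatial_regions <- c(14L, 12L, 10L, 2L, 14L, 16L, 14L, 15L, 16L, 14L)
  sp_spec <- spatial_sim_spec(n_genes = 300L, n_set_genes = 73L,
                              n_regions = spatial_regions,
                              ages = spatial_ages, rng_seed = rng_seed)
  donors <- simulate_spatial_study(sp_spec)
  spatial_files <- lapply(seq_along(donors), function(i) {
    base <- file.path(out_dir, sprintf("spatial_donor_%02d", i))
    write_expression(donors[[i]], paste0(base, "_expr.tsv"),
                     paste0(base, "_meta.tsv"))
    list(expr = paste0(base, "_expr.tsv"), meta = paste0(base, "_meta.tsv"),
         donor_id = names(donors)[i], age_years = spatial_ages[i],
         n_regions = spatial_regions[i],
         rng_seed = rng_seed + i,
         loading = sp_spec$c0 + sp_spec$c1 * spatial_ages[i])
  })

  cohort_layout <- data.frame(
    label = c("cohortA", "cohortB", "cohortC", "cohortD", "contrast_blood"),
    n_control = c(12L, 19L, 14L, 17L, 55L),
    n_case = c(13L, 20L, 15L, 16L, 50L),
    rewired_fraction = c(0.5, 0.5, 0.5, 0.5, 0),
    loading_control = c(-0.4, -0.4, -0.4, -0.4, -0.2),
    loading_case = c(0.4, 0.4, 0.4, 0.4, -0.2),
    include_in_meta = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  cohort_files <- lapply(seq_len(nrow(cohort_layout)), function(i) {
    row <- cohort_layout[i, ]
    cs <- cohort_sim_spec(n_control = row$n_control, n_case = row$n_case,
                          loading_control = row$loading_control,
                          loading_case = row$loading_case,
                          rewired_fraction = row$rewired_fraction,
                          n_genes = 300L, n_set_genes = 73L,
                          rng_seed = rng_seed + 100L + i)
    ds <- simulate_cohort(cs, dataset_label = row$label)
    base <- file.path(out_dir, row$label)
    write_expression(ds, paste0(base, "_expr.tsv"), paste0(base, "_meta.tsv"))
    c(list(expr = paste0(base, "_expr.tsv"),
           meta = paste0(base, "_meta.tsv")),
      as.list(row), list(rng_seed = rng_seed + 100L + i))
  })

  set <- gene_set("PLANTED_SET_73", sprintf("SETG%03d", 1:73))
  gmt_path <- file.path(out_dir, "synthetic_set_73.gmt")
  write_gene_sets(set, gmt_path,
                  descriptions = "synthetic 73-gene planted set")

  manifest <- list(
    base_rng_seed = rng_seed,
    seed_gene = "SEED",
    gene_set = list(file = gmt_path, name = "PLANTED_SET_73", size = 73L),
    loading_model = list(c0 = sp_spec$c0, c1 = sp_spec$c1,
                         noise_sd = sp_spec$noise_sd,
                         note = "set-gene loading = c0 + c1 * age; negative loadings encode anti-correlation with the seed"),
    spatial_donors = spatial_files,
    cohorts = cohort_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
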