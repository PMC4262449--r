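make_cohort <- function(n_control = 30, n_case = 30, f = 0.5,
                        lc = -0.4, lk = 0.4, n_genes = 300, n_set = 73,
                        seed = 1) {
  rank_dataset(simulate_cohort(cohort_sim_spec(
    n_control = n_control, n_case = n_case, loading_control = lc,
    loading_case = lk, rewired_fraction = f, n_genes = n_genes,
    n_set_genes = n_set, rng_seed = seed)))
}

test_that("within-group correlations match a hand oracle and group relabeling", {
  # toy: 2 set genes, 6 control + 6 case subjects, hand-checkable
  vals <- rbind(SEED = c(1, 2, 3, 4, 5, 6, 6, 5, 4, 3, 2, 1),
                SETG001 = c(2, 1, 4, 3, 6, 5, 1, 2, 3, 4, 5, 6),
                SETG002 = c(6, 5, 4, 3, 2, 1, 2, 4, 6, 1, 3, 5),
                BG = rep(c(1, 2), 6))
  colnames(vals) <- sprintf("s%02d", 1:12)
  ds <- toy_dataset(vals, condition = rep(c("control", "case"), each = 6),
                    ranked = TRUE)
  tab <- suppressWarnings(
    within_group_correlations(ds, "SEED", planted_set(2)))
  expect_equal(tab$rho_control[tab$gene == "SETG001"],
               oracle_spearman(vals["SEED", 1:6], vals["SETG001", 1:6]))
  expect_equal(tab$rho_case[tab$gene == "SETG002"],
               oracle_spearman(vals["SEED", 7:12], vals["SETG002", 7:12]))
  # relabeling the control group as cases reproduces the same correlations
  copy <- ds
  copy$meta$condition <- rep(c("case", "control"), each = 6)
  swapped <- suppressWarnings(
    within_group_correlations(copy, "SEED", planted_set(2)))
  expect_equal(swapped$rho_case, tab$rho_control)
  expect_equal(swapped$rho_control, tab$rho_case)
})

test_that("planted opposite loadings are recovered gene by gene", {
  ds <- make_cohort(f = 1, seed = 5)
  tab <- within_group_correlations(ds, "SEED", planted_set(73))
  expect_gte(mean(tab$rho_control < 0), 0.9)
  expect_gte(mean(tab$rho_case > 0), 0.9)
})

test_that("inversion fraction counts strict sign switches only", {
  per_gene <- data.frame(gene = c("a", "b", "c"),
                         rho_control = c(-0.2, -0.1, 0.3),
                         rho_case = c(0.1, -0.05, 0.4))
  expect_equal(as.numeric(inversion_fraction(per_gene)), 1 / 3)
  # zeros on either side never count
  zero <- data.frame(gene = c("a", "b"), rho_control = c(0, -0.5),
                     rho_case = c(0.5, 0))
  expect_equal(as.numeric(inversion_fraction(zero)), 0)
  expect_equal(attr(inversion_fraction(per_gene), "n_evaluated"), 3L)
})

test_that("differential statistics degenerate correctly when nothing changes", {
  ds <- make_cohort(f = 0, lc = -0.3, lk = -0.3, n_control = 12, n_case = 12,
                    n_genes = 120, n_set = 20, seed = 9)
  # force case group to be an exact relabeled copy of the controls
  vals <- ds$values
  vals[, 13:24] <- vals[, 1:12]
  copy <- expression_dataset(vals, ds$meta, ranked = TRUE)
  res <- suppressWarnings(
    differential_statistics(copy, "SEED", planted_set(20),
                            n_permutations = 199, rng_seed = 3))
  expect_equal(res$inversion_fraction, 0)
  expect_equal(res$wilcoxon$p_value, 1)
  expect_equal(res$delta, 0)
  expect_identical(res$per_gene$rho_case, res$per_gene$rho_control)
})

test_that("planted rewiring is detected by all four statistics", {
  ds <- make_cohort(n_control = 40, n_case = 40, f = 0.5, seed = 1)
  res <- differential_statistics(ds, "SEED", planted_set(73),
                                 n_permutations = 499, rng_seed = 11)
  expect_gt(res$delta, 0.1)
  expect_lt(res$wilcoxon$p_value, 0.001)
  expect_lt(res$label_perm$p_value, 0.05)
  expect_lt(res$inversion_perm$p_value, 0.05)
  # planted f = 0.5 recovered within +/-0.15
  expect_equal(res$inversion_fraction, 0.5, tolerance = 0.3)
  expect_equal(res$n_evaluated, 73L)
  # permutations are reproducible under the same seed
  res2 <- differential_statistics(ds, "SEED", planted_set(73),
                                  n_permutations = 499, rng_seed = 11)
  expect_identical(res2$label_perm$p_value, res$label_perm$p_value)
})

test_that("inversion fraction is invariant to monotone per-subject transforms", {
  raw <- simulate_cohort(cohort_sim_spec(20, 20, rewired_fraction = 0.5,
                                         n_genes = 150, n_set_genes = 30,
                                         rng_seed = 21))
  a <- within_group_correlations(rank_dataset(raw), "SEED", planted_set(30))
  warped <- raw
  # squash each subject's values through its own monotone transform
  for (j in seq_len(ncol(warped$values)))
    warped$values[, j] <- log1p(warped$values[, j]) ^ (1 + j %% 3)
  b <- within_group_correlations(rank_dataset(warped), "SEED",
                                 planted_set(30))
  expect_equal(a$rho_control, b$rho_control)
  expect_equal(a$rho_case, b$rho_case)
  expect_equal(as.numeric(inversion_fraction(a)),
               as.numeric(inversion_fraction(b)))
})

test_that("genome-wide delta scan agrees with the exhaustive double loop", {
  sets <- planted_set(8)
  cohorts <- list(make_cohort(n_control = 10, n_case = 10, f = 0.5,
                              n_genes = 30, n_set = 8, seed = 31),
                  make_cohort(n_control = 12, n_case = 12, f = 0.5,
                              n_genes = 30, n_set = 8, seed = 32))
  scan <- suppressWarnings(suppressMessages(
    genome_wide_delta_scan(cohorts, sets, "SEED")))
  # oracle: per candidate gene and cohort, mean rank-then-Pearson
  # correlation with the set (minus itself) within each group
  universe <- rownames(cohorts[[1]]$values)
  oracle_delta <- sapply(cohorts, function(d) {
    ctrl <- d$meta$condition == "control"
    vapply(universe, function(g) {
      members <- setdiff(sets$genes, g)
      rho_g <- function(idx) mean(vapply(members, function(m)
        oracle_spearman(d$values[g, idx], d$values[m, idx]), numeric(1)))
      rho_g(!ctrl) - rho_g(ctrl)
    }, numeric(1))
  })
  seed_delta <- oracle_delta["SEED", ]
  beats <- rowSums(oracle_delta > matrix(seed_delta, nrow(oracle_delta),
                                         2, byrow = TRUE)) == 2
  beats <- beats[setdiff(universe, "SEED")]
  expect_equal(scan$k, sum(beats))
  expect_setequal(scan$extreme_genes, names(which(beats)))
  expect_equal(scan$p, (scan$k + 1) / (scan$n_universe + 1))
  # a gene beating the seed in only one cohort is never counted
  one_cohort_only <- abs(rowSums(
    oracle_delta > matrix(seed_delta, nrow(oracle_delta), 2,
                          byrow = TRUE))) == 1
  expect_false(any(names(which(one_cohort_only)) %in% scan$extreme_genes))
})

test_that("a maximally rewired seed gives k = 0 in the scan", {
  cohorts <- list(make_cohort(n_control = 25, n_case = 25, f = 1,
                              n_genes = 60, n_set = 15, seed = 41),
                  make_cohort(n_control = 25, n_case = 25, f = 1,
                              n_genes = 60, n_set = 15, seed = 42))
  scan <- suppressWarnings(suppressMessages(
    genome_wide_delta_scan(cohorts, planted_set(15), "SEED")))
  expect_equal(scan$k, 0)
})

test_that("random-set specificity is deterministic and detects the planted set", {
  ds <- make_cohort(n_control = 30, n_case = 30, f = 1, seed = 51)
  r1 <- random_set_specificity(ds, "SEED", planted_set(73), n_sets = 200,
                               rng_seed = 5)
  r2 <- random_set_specificity(ds, "SEED", planted_set(73), n_sets = 200,
                               rng_seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value, 1 / 201)  # fully rewired set beats every draw
  # symmetric null: no rewiring anywhere leaves the set unremarkable
  null_ds <- make_cohort(f = 0, lc = -0.2, lk = -0.2, seed = 52)
  r0 <- random_set_specificity(null_ds, "SEED", planted_set(73),
                               n_sets = 200, rng_seed = 6)
  expect_gt(r0$p_value, 0.05)
  # inversion statistic variant runs and is bounded
  ri <- random_set_specificity(ds, "SEED", planted_set(73), n_sets = 100,
                               statistic = "inversion", rng_seed = 7)
  expect_lte(ri$p_value, 1)
})

test_that("per-gene change ranking orders planted amplitudes and flips sign", {
  mk <- function(seed, amp_gene_loading) {
    # one set gene (SETG001) rewires with doubled amplitude
    spec <- cohort_sim_spec(25, 25, loading_control = -0.3,
                            loading_case = 0.3, rewired_fraction = 1,
                            n_genes = 80, n_set_genes = 10, rng_seed = seed)
    ds <- simulate_cohort(spec)
    amp <- ds$values
    # double SETG001's coupling by squaring its (positive) values
    amp["SETG001", ] <- amp["SETG001", ]^2
    expression_dataset(amp, ds$meta)
  }
  cohorts <- lapply(list(61, 62), function(s) rank_dataset(mk(s)))
  tab <- per_gene_change_ranking(cohorts, "SEED", planted_set(10))
  expect_equal(nrow(tab), 10)
  expect_equal(tab$difference, sort(tab$difference, decreasing = TRUE))
  # reversing the seed's profile across subjects negates every correlation
  # and reverses the ordering exactly
  flipped <- lapply(cohorts, function(d) {
    v <- d$values
    v["SEED", ] <- max(v["SEED", ]) + 1 - v["SEED", ]
    expression_dataset(v, d$meta, ranked = TRUE)
  })
  tab_f <- per_gene_change_ranking(flipped, "SEED", planted_set(10))
  m <- match(tab$gene, tab_f$gene)
  expect_equal(tab_f$difference[m], -tab$difference)
})

test_that("meta-combination respects inclusion flags and closed forms", {
  res <- lapply(1:3, function(i) {
    ds <- make_cohort(n_control = 15, n_case = 15, f = 0.5,
                      n_genes = 120, n_set = 20, seed = 70 + i)
    differential_statistics(ds, "SEED", planted_set(20),
                            n_permutations = 199, rng_seed = i,
                            dataset_label = sprintf("c%d", i))
  })
  contrast <- differential_statistics(
    make_cohort(f = 0, lc = -0.2, lk = -0.2, n_control = 15, n_case = 15,
                n_genes = 120, n_set = 20, seed = 79),
    "SEED", planted_set(20), n_permutations = 199, rng_seed = 9,
    dataset_label = "blood", include_in_meta = FALSE)
  meta <- meta_combine(c(res, list(contrast)), which = "label_perm",
                       method = "fisher")
  expect_setequal(meta$datasets, c("c1", "c2", "c3"))  # contrast excluded
  ps <- vapply(res, function(r) r$label_perm$p_value, numeric(1))
  expect_equal(meta$combined$p_value, oracle_fisher_p(ps), tolerance = 1e-8)
  # k identical inputs match the closed chi-square form
  same <- combine_pvalues(rep(0.02, 4))
  expect_equal(same$p_value,
               pchisq(-8 * log(0.02), df = 8, lower.tail = FALSE))
  # all-1 inputs give a combined p of 1
  allone <- lapply(res, function(r) {
    r$label_perm$p_value <- 1; r$wilcoxon$p_value <- 1; r
  })
  expect_equal(meta_combine(allone, which = "wilcoxon",
                            method = "fisher")$combined$p_value, 1)
  expect_error(meta_combine(res[1], which = "label_perm"), "at least 2")
})

test_that("the summary table carries the right columns and averages", {
  res <- lapply(1:2, function(i) {
    ds <- make_cohort(n_control = 12, n_case = 12, f = 0.5, n_genes = 100,
                      n_set = 15, seed = 80 + i)
    differential_statistics(ds, "SEED", planted_set(15),
                            n_permutations = 149, rng_seed = i,
                            dataset_label = sprintf("c%d", i))
  })
  tbl <- differential_table(res)
  expect_equal(tbl$samples, c(24, 24))
  expect_equal(tbl$mean_control,
               vapply(res, function(r) r$mean_control, numeric(1)))
  summ <- summarize_differential_table(tbl)
  expect_equal(summ$mean_correlation_increase,
               mean(tbl$mean_case - tbl$mean_control))
  expect_equal(summ$mean_inversion_pct, mean(tbl$inversion_pct))
})
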