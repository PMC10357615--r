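# The generator is first-class code: its statistical structure is what the
# pipeline's tests rest on.

test_that("design covers the study layout with the extra hippocampus replicate", {
  d <- fad_design()
  expect_equal(nrow(dplyr::distinct(d, tissue, age, genotype)), 12)
  reps <- dplyr::count(d, tissue, age, genotype, animal_id)
  expect_true(all(reps$n >= 2))
  h5 <- dplyr::filter(reps, tissue == "hippocampus", age == 5)
  expect_true(all(h5$n == 3))
  expect_true(all(dplyr::filter(reps, !(tissue == "hippocampus" &
                                          age == 5))$n == 2))
  # technical replicates of one animal share its condition labels
  per_animal <- d |>
    dplyr::group_by(animal_id, tissue) |>
    dplyr::summarise(n_cond = dplyr::n_distinct(paste(age, genotype)),
                     .groups = "drop")
  expect_true(all(per_animal$n_cond == 1))
})

test_that("degenerate noise gives constant proteins and seed is mandatory", {
  params <- fad_params(n_proteins = 20, baseline_sd = 0.3, animal_sd = 0,
                       tech_sd = 0, batch_shift_sd = 0, batch_scale_sd = 0,
                       missing_midpoint = -Inf, dep_fraction = 0,
                       n_abeta_corr = c(), n_abeta_acorr = c(),
                       candidate = FALSE)
  sim <- simulate_lfq(fad_design(n_animals = 2), params, seed = 11)
  ranges <- apply(sim$lfq$values, 1, function(x) diff(range(x)))
  expect_true(all(ranges < 1e-12))
  expect_error(simulate_lfq(fad_design(), params, seed = NULL), "seed")
  expect_error(fad_params(animal_sd = -1), "sd")
})

test_that("flat MNAR limit masks about half of all values", {
  params <- fad_params(n_proteins = 300, missing_slope = 0,
                       missing_midpoint = 7, dep_fraction = 0,
                       candidate = FALSE)
  sim <- simulate_lfq(fad_design(), params, seed = 5)
  rate <- mean(is.na(sim$lfq$values))
  n <- length(sim$lfq$values)
  expect_lt(abs(rate - 0.5), 4 * sqrt(0.25 / n))
})

test_that("missingness is monotone non-increasing in true intensity", {
  params <- fad_params(n_proteins = 2000, animal_sd = 0, tech_sd = 0,
                       batch_shift_sd = 0, batch_scale_sd = 0,
                       dep_fraction = 0, candidate = FALSE,
                       missing_midpoint = 6.5, missing_slope = 2)
  sim <- simulate_lfq(fad_design(n_animals = 2), params, seed = 3)
  # with all noise off, a protein's true intensity is constant: recover it
  truth_int <- apply(sim$lfq$values, 1, median, na.rm = TRUE)
  miss <- rowMeans(is.na(sim$lfq$values))
  ok <- is.finite(truth_int)
  bins <- cut(truth_int[ok], quantile(truth_int[ok], seq(0, 1, 0.1)),
              include.lowest = TRUE)
  rate <- tapply(miss[ok], bins, mean)
  expect_true(all(diff(rate) <= 0.03))
  expect_lt(stats::cor(seq_along(rate), as.numeric(rate),
                       method = "spearman"), -0.9)
})

test_that("planted effects are recovered by direct group-mean differences", {
  # noiseless: exact recovery
  params0 <- fad_params(n_proteins = 60, animal_sd = 0, tech_sd = 0,
                        batch_shift_sd = 0, batch_scale_sd = 0,
                        missing_midpoint = -Inf)
  sim0 <- simulate_lfq(fad_design(), params0, seed = 21)
  lfc8 <- dplyr::filter(sim0$truth$planted_lfc,
                        tissue == "hippocampus", age == 8)
  cols_tg <- with(sim0$lfq$samples,
                  tissue == "hippocampus" & age == 8 & genotype == "TG")
  cols_wt <- with(sim0$lfq$samples,
                  tissue == "hippocampus" & age == 8 & genotype == "WT")
  diff0 <- rowMeans(sim0$lfq$values[lfc8$protein_id, cols_tg]) -
    rowMeans(sim0$lfq$values[lfc8$protein_id, cols_wt])
  expect_equal(unname(diff0), lfc8$lfc, tolerance = 1e-12)

  # noisy Monte-Carlo: within 3 standard errors at large n
  design <- fad_design(n_animals = 30)
  params <- fad_params(n_proteins = 60, missing_midpoint = -Inf,
                       batch_shift_sd = 0, batch_scale_sd = 0)
  sim <- simulate_lfq(design, params, seed = 22)
  lfc8 <- dplyr::filter(sim$truth$planted_lfc,
                        tissue == "hippocampus", age == 8)
  cols_tg <- with(sim$lfq$samples,
                  tissue == "hippocampus" & age == 8 & genotype == "TG")
  cols_wt <- with(sim$lfq$samples,
                  tissue == "hippocampus" & age == 8 & genotype == "WT")
  se <- sqrt(2 * (params$animal_sd^2 + params$tech_sd^2 / 2) / 30)
  diffs <- rowMeans(sim$lfq$values[lfc8$protein_id, cols_tg]) -
    rowMeans(sim$lfq$values[lfc8$protein_id, cols_wt])
  expect_true(mean(abs(diffs - lfc8$lfc) < 3 * se) > 0.95)
})

test_that("generation is byte-identical under a fixed seed", {
  pre <- fad_preset("smoke")
  a <- simulate_lfq(pre$design, pre$params, seed = 99)
  b <- simulate_lfq(pre$design, pre$params, seed = 99)
  expect_identical(a$lfq$values, b$lfq$values)
  expect_identical(a$truth$planted_lfc, b$truth$planted_lfc)
  c_ <- simulate_lfq(pre$design, pre$params, seed = 100)
  expect_false(identical(a$lfq$values, c_$lfq$values))
})

test_that("aggregate trajectories increase with age, steepest in hippocampus", {
  traj <- simulate_abeta_trajectories()
  inc <- traj |>
    dplyr::group_by(tissue, readout) |>
    dplyr::summarise(mono = all(diff(value) > 0),
                     span = diff(range(value)), .groups = "drop")
  expect_true(all(inc$mono))
  spans <- tidyr::pivot_wider(inc |> dplyr::select(-mono),
                              names_from = tissue, values_from = span)
  expect_true(all(spans$hippocampus > spans$cortex))
  expect_error(simulate_abeta_trajectories(ages = 2), "ages")
  expect_warning(
    flat <- simulate_abeta_trajectories(
      shapes = list(hippocampus = list(MFA = c(1, 1, 1)))),
    "constant"
  )
  expect_true(any(flat$zero_variance))
})

test_that("planted aggregate-tracking proteins correlate near-perfectly", {
  pre <- fad_preset("5xfad")
  sim <- simulate_lfq(pre$design, pre$params, seed = 12)
  traj <- sim$truth$trajectories
  tracked <- dplyr::filter(sim$truth$classes,
                           class %in% c("abeta_corr", "candidate"))
  lfcs <- sim$truth$planted_lfc |>
    dplyr::semi_join(tracked, by = c("protein_id", "tissue"))
  best_r <- lfcs |>
    dplyr::group_by(protein_id, tissue) |>
    dplyr::summarise(r = {
      ro <- traj[traj$tissue == tissue[1], ]
      max(vapply(split(ro$value, ro$readout),
                 function(v) stats::cor(lfc, v), numeric(1)))
    }, .groups = "drop")
  expect_true(all(best_r$r >= critical_r(3, 0.05)))
})

test_that("human table overlap and concordance fractions behave as planted", {
  pre <- fad_preset("smoke")
  sim <- simulate_lfq(pre$design, pre$params, seed = 31)
  expect_error(simulate_human_tables(sim$truth, seed = 1,
                                     overlap_fraction = 1.2), "fraction")

  none <- simulate_human_tables(sim$truth, seed = 32, overlap_fraction = 0)
  dep_syms <- toupper(mouse_symbols_for(sim))
  expect_equal(sum(none$tables$significant &
                     none$tables$gene_symbol %in% dep_syms), 0)

  # concordance fraction 0.5: agreements within the binomial 99% interval
  half <- simulate_human_tables(sim$truth, seed = 33,
                                overlap_fraction = 1,
                                concordance_fraction = 0.5)
  truth_sign <- sim$truth$planted_lfc |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(s = sign(lfc[which.max(abs(lfc))]), .groups = "drop")
  one <- dplyr::filter(half$tables, dataset_id == "D22", significant,
                       gene_symbol %in% dep_syms)
  # map human symbols back to protein ids to compare signs against truth
  ids <- sim$lfq$proteins$protein_id[
    match(one$gene_symbol, toupper(sim$lfq$proteins$gene_symbol))]
  agree <- sign(one$effect) ==
    truth_sign$s[match(ids, truth_sign$protein_id)]
  n <- length(agree)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(agree), ci[1])
  expect_lte(sum(agree), ci[2])

  # ortholog map contains all three component kinds
  comp <- half$ortholog_map
  expect_true(any(duplicated(comp$mouse_symbol[
    comp$source_direction == "m2h"])))
})

test_that("CSF generator matches its closed-form AUC and planted rank correlations", {
  expect_error(simulate_csf(seed = 1, n_case = 1), "subjects")
  big <- simulate_csf(seed = 8, n_case = 4000, n_control = 4000, d = 0.87)
  auc <- roc_auc(big$analyte[big$group == "AD"],
                 big$analyte[big$group == "control"])
  expect_lt(abs(auc - pnorm(0.87 / sqrt(2))), 0.02)

  same <- simulate_csf(seed = 9, n_case = 2000, n_control = 2000, d = 0)
  auc0 <- roc_auc(same$analyte[same$group == "AD"],
                  same$analyte[same$group == "control"])
  expect_lt(abs(auc0 - 0.5), 0.03)

  rhos <- vapply(1:5, function(s) {
    csf <- simulate_csf(seed = s)
    stats::cor(csf$analyte, csf$ratio42_40, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.4)), 0.15)
})

test_that("DEG table keeps transcript changes rare among tracked proteins", {
  pre <- fad_preset("5xfad")
  sim <- simulate_lfq(pre$design, pre$params, seed = 41)
  deg <- simulate_deg_table(sim$truth, seed = 41)
  expect_true(all(deg$adjusted_p >= 0 & deg$adjusted_p <= 1))
  expect_lt(mean(deg$significant), 0.05)
  expect_identical(deg, simulate_deg_table(sim$truth, seed = 41))
})
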