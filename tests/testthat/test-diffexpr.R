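# The moderated GLS machinery and its limits.

test_that("BH adjustment matches hand computation and handles edge inputs", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a single-protein toy gives logfc equal to the group-mean difference", {
  design <- toy_design(ages = 8, n_animals = 3, n_tech = 2)
  y <- c(7.0, 7.1, 6.9, 7.2, 7.05, 6.95,    # WT animals (2 reps each)
         7.5, 7.6, 7.4, 7.45, 7.55, 7.5)    # TG
  design <- dplyr::arrange(design, genotype, animal_id, tech_rep)
  vals <- matrix(c(rev(y * 0) + y), nrow = 1)
  x <- toy_lfq(vals, design)
  fit <- pairwise_fit(x, "hippocampus", 8, analysis_set = "P001")
  hand <- mean(y[design$genotype == "TG"]) -
    mean(y[design$genotype == "WT"])
  expect_equal(tidy(fit)$logfc, hand, tolerance = 1e-12)
  expect_equal(tidy(fit)$contrast_id, "DE.hippo.Age8")
})

test_that("zero prior df reproduces the ordinary t exactly", {
  set.seed(5)
  design <- toy_design(ages = 8, n_animals = 6, n_tech = 1)
  vals <- matrix(rnorm(200 * nrow(design), 7, 0.2), 200)
  x <- toy_lfq(vals, design)
  fit <- pairwise_fit(x, "hippocampus", 8, rho = 0, prior_df = 0)
  res <- tidy(fit)
  tg <- design$genotype == "TG"
  ord <- vapply(seq_len(200), function(g) {
    unname(t.test(vals[g, tg], vals[g, !tg], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_lt(max(abs(res$stat - ord[match(res$protein_id,
                                         sprintf("P%03d", 1:200))])),
            1e-12)
})

test_that("infinite prior df pools every protein to one variance", {
  set.seed(6)
  design <- toy_design(ages = 8, n_animals = 4, n_tech = 1)
  vals <- matrix(rnorm(100 * nrow(design), 7, 0.2), 100)
  fit <- pairwise_fit(toy_lfq(vals, design), "hippocampus", 8,
                      rho = 0, prior_df = Inf)
  res <- tidy(fit)
  implied_sd <- res$logfc / res$stat     # u * s_tilde, u shared
  expect_lt(diff(range(implied_sd)), 1e-12)
})

test_that("moderated variances stay between the prior and the raw variance", {
  set.seed(7)
  design <- toy_design(n_animals = 3, n_tech = 2)
  # heteroscedastic proteins so the prior df is finite
  sds <- runif(300, 0.05, 0.5)
  vals <- matrix(rnorm(300 * nrow(design), 7, sds), 300)
  fit <- fit_contrasts(toy_lfq(vals, design))
  g <- glance(fit)
  expect_gt(g$prior_df, 0)
  s2 <- fit$moderation$s2$s2
  d <- fit$moderation$s2$df_residual
  s2t <- (g$prior_df * g$prior_var + d * s2) / (g$prior_df + d)
  lo <- pmin(g$prior_var, s2)
  hi <- pmax(g$prior_var, s2)
  expect_true(all(s2t >= lo - 1e-12 & s2t <= hi + 1e-12))
})

test_that("GLS with zero correlation is ordinary least squares", {
  set.seed(8)
  design <- toy_design(n_animals = 2, n_tech = 2)
  vals <- matrix(rnorm(50 * nrow(design), 7, 0.2), 50)
  vals[matrix(runif(length(vals)) < 0.1, 50)] <- NA
  fit <- fit_contrasts(toy_lfq(vals, design), rho = 0, prior_df = 0)
  res <- tidy(fit)
  cond <- paste(design$tissue, design$age, design$genotype, sep = ".")
  one <- dplyr::filter(res, contrast_id == "A8TH")
  for (g in sample(one$protein_id, 5)) {
    gi <- match(g, sprintf("P%03d", 1:50))
    ols <- mean(vals[gi, cond == "hippocampus.8.TG"], na.rm = TRUE) -
      mean(vals[gi, cond == "hippocampus.8.WT"], na.rm = TRUE)
    expect_equal(one$logfc[one$protein_id == g], ols, tolerance = 1e-12)
  }
})

test_that("consensus correlation recovers its generating value", {
  design <- fad_design(n_animals = 5)
  # identical technical replicates: rho -> 1
  p1 <- fad_params(n_proteins = 300, tech_sd = 0, animal_sd = 0.1,
                   batch_shift_sd = 0, batch_scale_sd = 0,
                   missing_midpoint = -Inf, dep_fraction = 0,
                   candidate = FALSE)
  s1 <- simulate_lfq(design, p1, seed = 51)
  expect_gt(estimate_consensus_correlation(s1$lfq), 0.98)

  # independent replicates: rho near 0
  p2 <- fad_params(n_proteins = 2000, tech_sd = 0.1, animal_sd = 0,
                   batch_shift_sd = 0, batch_scale_sd = 0,
                   missing_midpoint = -Inf, dep_fraction = 0,
                   candidate = FALSE)
  s2 <- simulate_lfq(design, p2, seed = 52)
  expect_lt(abs(estimate_consensus_correlation(s2$lfq)), 0.05)

  # planted compound symmetry rho = 0.5 (equal animal and tech sd)
  p3 <- fad_params(n_proteins = 2000, tech_sd = 0.1, animal_sd = 0.1,
                   batch_shift_sd = 0, batch_scale_sd = 0,
                   missing_midpoint = -Inf, dep_fraction = 0,
                   candidate = FALSE)
  s3 <- simulate_lfq(design, p3, seed = 53)
  rho3 <- estimate_consensus_correlation(s3$lfq)
  expect_gt(rho3, 0.4)
  expect_lt(rho3, 0.6)

  # no replicated animals: zero with a warning
  d1 <- toy_design(n_animals = 3, n_tech = 1)
  v <- matrix(rnorm(10 * nrow(d1), 7), 10)
  expect_warning(r0 <- estimate_consensus_correlation(toy_lfq(v, d1)),
                 "technical replicates")
  expect_equal(r0, 0)
})

test_that("moderated statistics agree with the limma reference on complete data", {
  set.seed(10)
  design <- toy_design(ages = 8, n_animals = 6, n_tech = 1)
  vals <- matrix(rnorm(400 * nrow(design), 7, 0.25), 400)
  rownames(vals) <- sprintf("P%03d", 1:400)
  fit <- pairwise_fit(toy_lfq(vals, design), "hippocampus", 8, rho = 0)
  res <- tidy(fit)

  grp <- factor(design$genotype, levels = c("WT", "TG"))
  mm <- stats::model.matrix(~grp)
  lf <- limma::eBayes(limma::lmFit(vals, mm))
  expect_equal(res$logfc,
               unname(lf$coefficients[res$protein_id, "grpTG"]),
               tolerance = 1e-10)
  expect_equal(fit$moderation$prior_df, lf$df.prior, tolerance = 0.05)
  expect_gt(cor(res$stat, lf$t[res$protein_id, "grpTG"]), 0.9999)
  expect_equal(res$stat, unname(lf$t[res$protein_id, "grpTG"]),
               tolerance = 0.01)
})

test_that("interaction contrasts equal differences of transgene effects", {
  set.seed(11)
  design <- fad_design(n_animals = 3)
  params <- fad_params(n_proteins = 80, missing_midpoint = -Inf,
                       batch_shift_sd = 0, batch_scale_sd = 0)
  sim <- simulate_lfq(design, params, seed = 61)
  fit <- fit_contrasts(sim$lfq, rho = 0, prior_df = 0)
  res <- tidy(fit)
  wide <- res |>
    dplyr::select(protein_id, contrast_id, logfc) |>
    tidyr::pivot_wider(names_from = contrast_id, values_from = logfc)
  expect_equal(wide$A82TH, wide$A8TH - wide$A2TH, tolerance = 1e-10)
  expect_equal(wide$A5THC, wide$A5TH - wide$A5TC, tolerance = 1e-10)
  # difference contrasts have zero-sum coefficients
  L <- fad_contrasts(design)
  diffs <- grep("T.{2,}|A[0-9]{2}", colnames(L), value = TRUE)
  expect_true(all(abs(colSums(L[, setdiff(colnames(L), c(
    "A2TC", "A5TC", "A8TC", "A2TH", "A5TH", "A8TH"))])) < 1e-12))
})

test_that("proteins missing a whole condition are reported absent for its contrasts", {
  design <- toy_design(n_animals = 2, n_tech = 2)
  vals <- matrix(rnorm(5 * nrow(design), 7, 0.1), 5)
  cond <- paste(design$age, design$genotype)
  vals[1, cond == "8 TG"] <- NA
  fit <- fit_contrasts(toy_lfq(vals, design), rho = 0)
  res <- tidy(fit)
  p1 <- dplyr::filter(res, protein_id == "P001")
  expect_false("A8TH" %in% p1$contrast_id)
  expect_true("A2TH" %in% p1$contrast_id)
  # fdr is monotone in p within each contrast
  mono <- res |>
    dplyr::group_by(contrast_id) |>
    dplyr::arrange(p_value, .by_group = TRUE) |>
    dplyr::summarise(ok = !is.unsorted(fdr), .groups = "drop")
  expect_true(all(mono$ok))
})
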