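# Correlation toolkit and trajectory classifier.

test_that("Pearson r and its t-test p match hand computation", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(r = 1, p = 0, n = 3L))
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  ex <- pearson_with_p(c(1, 2, 4), c(1, 2, 3))
  expect_equal(ex$r, 0.981980506, tolerance = 1e-8)
  # t = 3*sqrt(3) at df = 1; p = 2*pt(-3*sqrt(3), 1)
  expect_equal(ex$p, 2 * pt(-3 * sqrt(3), 1), tolerance = 1e-12)
  expect_equal(ex$p, 0.12104, tolerance = 1e-4)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("pearson_with_p agrees with the covariance-formula oracle", {
  set.seed(314)
  for (i in 1:2000) {
    x <- rnorm(3)
    y <- rnorm(3)
    if (sd(x) == 0 || sd(y) == 0) next
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    got <- pearson_with_p(x, y)
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
  }
  # p cross-checked against cor.test on a subsample
  set.seed(315)
  for (i in 1:50) {
    x <- rnorm(8)
    y <- rnorm(8)
    ct <- stats::cor.test(x, y)
    got <- pearson_with_p(x, y)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("the critical r comes from inverting the t quantile", {
  expect_equal(critical_r(3, 0.05),
               qt(0.975, 1) / sqrt(qt(0.975, 1)^2 + 1), tolerance = 1e-12)
  expect_equal(critical_r(3, 0.05), 0.996917, tolerance = 1e-6)
  expect_equal(critical_r(12, 0.05), 0.576, tolerance = 1e-3)
  expect_lt(critical_r(3, 0.9999), 0.01)
  expect_error(critical_r(2, 0.05), "n >= 3")
  expect_error(critical_r(3, 1.5), "alpha")
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman_with_p(1:5, 1:5)$rho, 1)
  expect_equal(spearman_with_p(1:5, -(1:5)^3)$rho, -1)  # monotone transform
  expect_equal(spearman_with_p(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_equal(spearman_with_p(1:6, exp(1:6))$rho, 1)
})

test_that("classification recovers planted trajectory classes exactly", {
  traj <- simulate_abeta_trajectories()
  ages <- c(2, 5, 8)
  readouts <- split(traj$value[traj$tissue == "hippocampus"],
                    traj$readout[traj$tissue == "hippocampus"])
  set.seed(88)
  n_corr <- 50
  n_acorr <- 30
  n_null <- 120
  mk <- function(i, y) tibble::tibble(
    protein_id = sprintf("D%03d", i), tissue = "hippocampus",
    age = ages, logfc = y
  )
  rows <- list()
  for (i in seq_len(n_corr)) {
    v <- readouts[[sample(length(readouts), 1)]]
    rows[[i]] <- mk(i, runif(1, -0.1, 0.1) + runif(1, 0.2, 0.5) *
                      (v - min(v)) / diff(range(v)))
  }
  for (i in seq_len(n_acorr)) {
    v <- readouts[[sample(length(readouts), 1)]]
    rows[[n_corr + i]] <- mk(n_corr + i,
                             -(runif(1, 0.2, 0.5) *
                                 (v - min(v)) / diff(range(v))))
  }
  for (i in seq_len(n_null)) {
    y <- sample_uncorrelated_shape(traj, "hippocampus", rmax = 0.99)
    rows[[n_corr + n_acorr + i]] <- mk(n_corr + n_acorr + i, y)
  }
  dep_lfcs <- dplyr::bind_rows(rows)
  cls <- classify_abeta(dep_lfcs, traj)
  planted_corr <- sprintf("D%03d", seq_len(n_corr))
  planted_acorr <- sprintf("D%03d", n_corr + seq_len(n_acorr))
  expect_setequal(cls$protein_id[cls$class == "corr"], planted_corr)
  expect_setequal(cls$protein_id[cls$class == "acorr"], planted_acorr)
  # exclusivity and universe containment
  expect_equal(sum(cls$class == "corr" & cls$class == "acorr"), 0)
  expect_true(all(cls$protein_id %in% dep_lfcs$protein_id))

  # monotone in alpha: stricter level selects a subset
  cls_strict <- classify_abeta(dep_lfcs, traj, alpha = 0.01)
  for (k in c("corr", "acorr")) {
    expect_true(all(cls_strict$protein_id[cls_strict$class == k] %in%
                      cls$protein_id[cls$class == k]))
  }

  # invariance under positive affine rescaling of a readout
  traj2 <- traj
  hit <- traj2$tissue == "hippocampus" & traj2$readout == "MFA"
  traj2$value[hit] <- 3 + 10 * traj2$value[hit]
  cls2 <- classify_abeta(dep_lfcs, traj2)
  expect_identical(cls$class, cls2$class)
})

test_that("proportional and degenerate trajectories behave at the boundaries", {
  traj <- simulate_abeta_trajectories()
  v <- traj$value[traj$tissue == "hippocampus" & traj$readout == "MFA"]
  prop <- tibble::tibble(protein_id = "X1", tissue = "hippocampus",
                         age = c(2, 5, 8), logfc = 0.1 * v)
  cls <- classify_abeta(prop, traj)
  expect_equal(cls$class, "corr")
  expect_equal(cls$p, 0)
  neg <- dplyr::mutate(prop, logfc = -logfc)
  expect_equal(classify_abeta(neg, traj)$class, "acorr")

  # missing age point: skipped and reported
  incomplete <- prop[1:2, ]
  cls3 <- classify_abeta(incomplete, traj)
  expect_equal(nrow(cls3), 0)
  expect_equal(nrow(attr(cls3, "skipped")), 1)
})

test_that("Spearman matrices respect shared-protein rules and signs", {
  t1 <- tibble::tibble(protein_id = sprintf("P%02d", 1:20),
                       logfc = rnorm(20))
  t2 <- dplyr::mutate(t1, logfc = logfc^3)          # monotone transform
  t3 <- dplyr::mutate(t1, logfc = -logfc)
  m <- lfc_spearman_matrix(list(a = t1, b = t2, c = t3))
  expect_equal(m$rho[m$table_a == "a" & m$table_b == "b"], 1)
  expect_equal(m$rho[m$table_a == "a" & m$table_b == "c"], -1)
  tiny <- tibble::tibble(protein_id = c("Q1", "Q2"), logfc = c(1, 2))
  m2 <- lfc_spearman_matrix(list(a = t1, d = tiny))
  expect_true(is.na(m2$rho))
  expect_equal(m2$n_shared, 0)
})

test_that("plaque load follows the volume-fraction formula with exclusion", {
  expect_equal(plaque_load(c(100, 200), 10000), 3)
  expect_equal(plaque_load(c(40), 10000), 0)
  expect_equal(plaque_load(numeric(0), 10000), 0)
  expect_equal(plaque_load(c(50), 10000), 0.5)     # boundary included
  expect_error(plaque_load(c(100), 0), "region_volume")
  expect_error(plaque_load(c(-5), 100), "negative")
})
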