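# Correlation toolkit and the aggregate-trajectory classifier: a
# differentially expressed protein is "aggregate-correlated" when its
# 3-point age trajectory of log fold-changes has a significant positive
# Pearson correlation with at least one aggregate readout trajectory of
# the same tissue (anticorrelated for significant negative r).

#' Pearson correlation with two-tailed t-test p-value
#'
#' Standard Pearson r; significance from `t = r * sqrt((n-2) / (1-r^2))`
#' with `n - 2` degrees of freedom, two-tailed. `r = +/-1` yields `p = 0`.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return tibble with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) abort("need equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: Pearson correlation undefined")
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Critical Pearson r for a two-tailed test
#'
#' The |r| above which the two-tailed p falls below `alpha` at `n - 2`
#' degrees of freedom, by inverting the t quantile:
#' `r = t / sqrt(t^2 + n - 2)`. With only three points per trajectory
#' (df = 1) this is ~0.9969 at alpha = 0.05 - the price of the 3-point
#' design.
#'
#' @param n number of paired points (>= 3).
#' @param alpha two-tailed level in (0, 1).
#' @return critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) abort("need n >= 3")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  tq <- qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + (n - 2))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p from the same t transform as
#' [pearson_with_p()] applied to the rank correlation.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @return tibble with `rho`, `p`, `n`.
#' @export
spearman_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) abort("need equal-length vectors, n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("zero rank variance: Spearman correlation undefined")
  }
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Classify DEP trajectories against aggregate readouts
#'
#' For every (protein, tissue) with a complete age trajectory of log
#' fold-changes, computes the Pearson correlation against each aggregate
#' readout trajectory of that tissue. Class `corr` when any readout gives
#' r > 0 with p < alpha, `acorr` for r < 0 with p < alpha, else `none`.
#' When both occur across readouts the smaller p wins (tie: |r| closer to
#' 1) and the conflict is recorded. Proteins with a missing age point are
#' skipped and listed in the `skipped` attribute.
#'
#' @param dep_lfcs tibble: `protein_id`, `tissue`, `age`, `logfc` - one row
#'   per age; typically pairwise-model log10 fold-changes of the DEPs.
#' @param trajectories tibble from [simulate_abeta_trajectories()] or
#'   [read_trajectories()].
#' @param alpha significance level per readout correlation.
#' @return tibble: `protein_id`, `tissue`, `best_readout`, `r`, `p`,
#'   `class` (`corr` / `acorr` / `none`), `conflict`; attributes `skipped`
#'   and `conflicts`.
#' @export
classify_abeta <- function(dep_lfcs, trajectories, alpha = 0.05) {
  ages_needed <- sort(unique(trajectories$age))
  keyed <- dep_lfcs |>
    group_by(.data$protein_id, .data$tissue) |>
    arrange(.data$age, .by_group = TRUE)
  complete <- keyed |>
    summarise(ok = length(.data$age) == length(ages_needed) &&
                all(sort(.data$age) == ages_needed) &&
                !anyNA(.data$logfc), .groups = "drop")
  skipped <- complete |> filter(!.data$ok)
  groups <- keyed |>
    ungroup() |>
    semi_join(filter(complete, .data$ok),
              by = c("protein_id", "tissue"))

  traj_split <- trajectories |>
    group_by(.data$tissue, .data$readout) |>
    arrange(.data$age, .by_group = TRUE) |>
    summarise(values = list(.data$value),
              constant = sd(.data$value) == 0, .groups = "drop")

  out <- groups |>
    group_by(.data$protein_id, .data$tissue) |>
    summarise(lfc = list(.data$logfc), .groups = "drop") |>
    left_join(traj_split, by = "tissue",
              relationship = "many-to-many") |>
    filter(!.data$constant, !purrr::map_lgl(.data$lfc, ~ sd(.x) == 0)) |>
    mutate(res = purrr::map2(.data$lfc, .data$values,
                             ~ pearson_with_p(.x, .y))) |>
    tidyr::unnest("res")

  classify_one <- function(d) {
    sig <- d[d$p < alpha, , drop = FALSE]
    if (!nrow(sig)) {
      best <- d[which.min(d$p), ]
      return(tibble(best_readout = best$readout, r = best$r, p = best$p,
                    class = "none", conflict = FALSE))
    }
    conflict <- any(sig$r > 0) && any(sig$r < 0)
    best <- sig[order(sig$p, abs(1 - abs(sig$r))), ][1, ]
    tibble(best_readout = best$readout, r = best$r, p = best$p,
           class = if (best$r > 0) "corr" else "acorr",
           conflict = conflict)
  }
  empty_res <- tibble(protein_id = character(), tissue = character(),
                      best_readout = character(), r = numeric(),
                      p = numeric(), class = character(),
                      conflict = logical())
  res <- if (!nrow(out)) {
    empty_res
  } else {
    out |>
      group_by(.data$protein_id, .data$tissue) |>
      group_modify(~ classify_one(.x)) |>
      ungroup()
  }
  attr(res, "skipped") <- skipped
  attr(res, "conflicts") <- filter(res, .data$conflict)
  res
}

#' Split a classification into the four family tables
#'
#' @param classification result of [classify_abeta()].
#' @return named list of tibbles `c_corr`, `c_acorr`, `h_corr`, `h_acorr`
#'   (cortex / hippocampus x correlated / anticorrelated).
#' @export
abeta_families <- function(classification) {
  fam <- function(t, cl) {
    filter(classification, .data$tissue == t, .data$class == cl)
  }
  list(
    c_corr = fam("cortex", "corr"),
    c_acorr = fam("cortex", "acorr"),
    h_corr = fam("hippocampus", "corr"),
    h_acorr = fam("hippocampus", "acorr")
  )
}

#' Spearman correlation matrix between differential result tables
#'
#' For each requested pair of contrast tables, Spearman correlation of the
#' effect sizes over the proteins present in both, with a t-approximation
#' p-value; p-values BH-adjusted over all pairs of the matrix. Signs are
#' preserved (anticorrelations stay negative). Pairs sharing fewer than 3
#' proteins are marked not computable (`NA`).
#'
#' @param diff_tables named list of DiffResult tibbles (one per contrast).
#' @param pairs optional 2-column matrix/tibble of table names; defaults to
#'   all unordered pairs.
#' @param value column to correlate (default `"logfc"`).
#' @return tibble: `table_a`, `table_b`, `rho`, `p`, `fdr`, `n_shared`.
#' @export
lfc_spearman_matrix <- function(diff_tables, pairs = NULL,
                                value = "logfc") {
  nms <- names(diff_tables)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nms, 2))
  }
  pairs <- as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE),
                     .name_repair = ~ c("table_a", "table_b"))
  res <- purrr::pmap_dfr(pairs, function(table_a, table_b) {
    a <- diff_tables[[table_a]]
    b <- diff_tables[[table_b]]
    shared <- intersect(a$protein_id, b$protein_id)
    if (length(shared) < 3L) {
      return(tibble(table_a = table_a, table_b = table_b, rho = NA_real_,
                    p = NA_real_, n_shared = length(shared)))
    }
    s <- spearman_with_p(a[[value]][match(shared, a$protein_id)],
                         b[[value]][match(shared, b$protein_id)])
    tibble(table_a = table_a, table_b = table_b, rho = s$rho, p = s$p,
           n_shared = length(shared))
  })
  res$fdr <- NA_real_
  comp <- !is.na(res$p)
  res$fdr[comp] <- benjamini_hochberg(res$p[comp])
  res
}

#' Plaque load from plaque volumes
#'
#' `load (%) = 100 * sum(volumes >= min_volume) / region_volume`; plaques
#' smaller than `min_volume` (default 50 um^3) are excluded.
#'
#' @param plaque_volumes numeric vector of plaque volumes (um^3).
#' @param region_volume total region volume (um^3), > 0.
#' @param min_volume exclusion threshold (um^3).
#' @return percentage of region volume occupied by plaques.
#' @export
plaque_load <- function(plaque_volumes, region_volume, min_volume = 50) {
  if (region_volume <= 0) abort("region_volume must be > 0")
  if (any(plaque_volumes < 0)) abort("negative plaque volume")
  kept <- plaque_volumes[plaque_volumes >= min_volume]
  100 * sum(kept) / region_volume
}
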