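# CSF biomarker evaluation: ROC by the linear trapezoid rule (exactly the
# Mann-Whitney U / (n1*n2) with midrank tie handling), group comparison,
# and Spearman association with established biomarkers.

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps all observed thresholds (cases assumed higher); ties contribute
#' half, so the trapezoidal AUC equals the Mann-Whitney U statistic divided
#' by `n1 * n2`, and the result is invariant under strictly monotone score
#' transforms.
#'
#' @param cases,controls numeric score vectors (>= 1 each).
#' @return list of class `roc_curve`: `points` tibble (`threshold`, `tpr`,
#'   `fpr`) and `auc`.
#' @export
roc_curve <- function(cases, controls) {
  if (!length(cases) || !length(controls)) abort("empty group")
  thr <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  # the lowest observed threshold always gives (fpr, tpr) = (1, 1)
  points <- tibble(threshold = c(Inf, thr), tpr = c(0, tpr),
                   fpr = c(0, fpr))
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(cases, controls) roc_curve(cases, controls)$auc

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) tibble(auc = x$auc)

#' Two-group comparison of an analyte
#'
#' Mean and SD per group plus a two-tailed unpaired t-test (classic
#' equal-variance by default; `welch = TRUE` for the unequal-variance
#' form).
#'
#' @param csf CSF tibble (`group`, `analyte`, ...).
#' @param groups length-2 character: case label then control label.
#' @param analyte column to compare.
#' @param welch use the Welch correction.
#' @return tibble: one row per group with `n`, `mean`, `sd`, plus `t`,
#'   `p_value` (repeated), and a `degenerate_variance` flag.
#' @export
group_compare <- function(csf, groups = c("AD", "control"),
                          analyte = "analyte", welch = FALSE) {
  x <- csf[[analyte]][csf$group == groups[1]]
  y <- csf[[analyte]][csf$group == groups[2]]
  if (length(x) < 2L || length(y) < 2L) abort("need >= 2 per group")
  degen <- sd(x) == 0 && sd(y) == 0
  if (degen && isTRUE(all.equal(mean(x), mean(y)))) {
    warn("degenerate variance: identical constant groups, p set to 1")
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- t.test(x, y, var.equal = !welch)
  }
  tibble(
    group = groups, n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
    t = unname(tt$statistic), p_value = tt$p.value,
    degenerate_variance = degen
  )
}

#' Spearman association of an analyte with biomarker columns
#'
#' Pairwise-complete Spearman correlation (t-approximation p, two-tailed)
#' of the analyte against each biomarker column; unadjusted by default,
#' matching the single-table presentation convention (`adjust = TRUE` for
#' BH).
#'
#' @param csf CSF tibble.
#' @param analyte analyte column name.
#' @param biomarkers character vector of biomarker column names.
#' @param adjust apply BH across the biomarkers.
#' @return tibble: `biomarker`, `rho`, `p`, `n` (and `fdr` if adjusted).
#' @export
biomarker_spearman <- function(csf, analyte = "analyte",
                               biomarkers = c("abeta42", "abeta40",
                                              "ratio42_40", "t_tau",
                                              "p_tau"),
                               adjust = FALSE) {
  res <- purrr::map_dfr(biomarkers, function(b) {
    ok <- complete.cases(csf[[analyte]], csf[[b]])
    if (sum(ok) < 3L) abort(paste0("fewer than 3 complete pairs for ", b))
    s <- spearman_with_p(csf[[analyte]][ok], csf[[b]][ok])
    tibble(biomarker = b, rho = s$rho, p = s$p, n = s$n)
  })
  if (adjust) res$fdr <- benjamini_hochberg(res$p)
  res
}
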