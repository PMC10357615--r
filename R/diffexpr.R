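# Moderated differential abundance on log10 intensities: per-protein
# generalized least squares with a consensus within-animal correlation
# (block compound symmetry over technical replicates), residual variances
# shrunk by closed-form empirical-Bayes moderation with moment-matched
# prior degrees of freedom, two-tailed moderated t, and Benjamini-Hochberg
# FDR computed separately within each contrast.

#' Consensus within-animal correlation
#'
#' Technical replicates of one animal share its biology, so their residuals
#' are correlated. Per protein, the correlation is estimated over all
#' within-animal replicate pairs of residuals (after removing condition
#' means), Fisher z-transformed, robust-averaged with a trimmed mean over
#' proteins, and transformed back.
#'
#' @param lfq an [lfq_experiment()].
#' @param trim trimming fraction of the mean over proteins.
#' @return scalar estimate in (-1, 1); 0 with a warning when no animal has
#'   two or more technical replicates.
#' @export
estimate_consensus_correlation <- function(lfq, trim = 0.1) {
  Y <- lfq$values
  p <- nrow(Y)
  cond <- sample_conditions(lfq)
  akey <- paste(lfq$samples$animal_id, lfq$samples$tissue)
  if (!any(table(akey) >= 2L)) {
    warn("no animal with >= 2 technical replicates; consensus rho set to 0")
    return(0)
  }
  # pooled one-way (animal within condition) variance decomposition per
  # protein: E[MSB] = sigma_w^2 + m0 sigma_b^2, E[MSW] = sigma_w^2, so the
  # intra-animal correlation is (MSB - MSW) / (MSB + (m0 - 1) MSW).
  ssw <- dfw <- ssb <- dfb <- ntot <- m2tot <- rep(0, p)
  for (cols in split(seq_len(ncol(Y)), cond)) {
    blocks <- split(cols, akey[cols])
    blocks <- blocks[lengths(blocks) >= 2L]
    if (length(blocks) < 2L) next
    means <- vapply(blocks, function(j) {
      rowMeans(Y[, j, drop = FALSE], na.rm = TRUE)
    }, numeric(p))
    counts <- vapply(blocks, function(j) {
      rowSums(!is.na(Y[, j, drop = FALSE]))
    }, numeric(p))
    if (p == 1L) {
      means <- matrix(means, nrow = 1)
      counts <- matrix(counts, nrow = 1)
    }
    for (j in seq_along(blocks)) {
      d <- Y[, blocks[[j]], drop = FALSE] - means[, j]
      ssw <- ssw + rowSums(d^2, na.rm = TRUE)
      dfw <- dfw + pmax(counts[, j] - 1, 0)
    }
    ok <- counts >= 2L
    n_animals <- rowSums(ok)
    ncond <- rowSums(counts * ok)
    gm <- rowSums(ifelse(ok, means * counts, 0)) / ncond
    term <- ifelse(ok, counts * (means - gm)^2, 0)
    ssb <- ssb + rowSums(term)
    dfb <- dfb + pmax(n_animals - 1, 0)
    ntot <- ntot + ncond
    m2tot <- m2tot + rowSums(ifelse(ok, counts^2, 0)) / pmax(ncond, 1)
  }
  usable <- dfw > 0 & dfb > 0 & (ssw > 0 | ssb > 0)
  if (!any(usable)) {
    warn("within-animal correlation not estimable; consensus rho set to 0")
    return(0)
  }
  msw <- ssw / dfw
  msb <- ssb / dfb
  m0 <- (ntot - m2tot) / dfb
  icc <- (msb - msw) / (msb + (m0 - 1) * msw)
  icc <- pmin(pmax(icc[usable], -0.9999), 0.9999)
  tanh(mean(atanh(icc), trim = trim, na.rm = TRUE))
}

# Block-compound-symmetry whitening matrix V^{-1/2} for observed samples.
cs_whitener <- function(block, rho) {
  n <- length(block)
  W <- matrix(0, n, n)
  bb <- 1 / sqrt(1 - rho)
  for (idx in split(seq_len(n), block)) {
    m <- length(idx)
    if (m == 1L) {
      W[idx, idx] <- 1
    } else {
      a <- 1 / sqrt(1 - rho + m * rho)
      Wb <- matrix((a - bb) / m, m, m)
      diag(Wb) <- bb + (a - bb) / m
      W[idx, idx] <- Wb
    }
  }
  W
}

# Moment-matched empirical-Bayes variance shrinkage on log variances.
# Returns prior df d0 (possibly Inf) and prior variance s02.
estimate_moderation_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) {
    return(list(prior_df = 0, prior_var = NA_real_))
  }
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  c0 <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(c0) && c0 > 0) {
    d0 <- 2 * trigamma_inverse(c0)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s02)
}

#' Contrast matrix for the full two-tissue time-course model
#'
#' Builds the three contrast families over the condition coefficients:
#' transgene effects at each (tissue, age) (`A8TH` = age 8, tissue
#' hippocampus), transgene-effect differences between ages within a tissue
#' (`A82TC` = age 8 vs 2, cortex), and transgene-effect differences between
#' tissues at one age (`A5THC` = age 5, hippocampus vs cortex). Difference
#' contrasts have zero-sum coefficients.
#'
#' @param samples sample metadata tibble (as in [lfq_experiment()]).
#' @return numeric matrix, rows = condition ids, columns = contrast ids.
#' @export
fad_contrasts <- function(samples) {
  tissues <- sort(unique(samples$tissue))
  ages <- sort(unique(samples$age))
  conds <- sort(unique(condition_id(samples$tissue, samples$age,
                                    samples$genotype)))
  tl <- function(t) toupper(substr(t, 1, 1))
  L <- list()
  tg_vec <- function(t, a) {
    v <- setNames(numeric(length(conds)), conds)
    v[condition_id(t, a, "TG")] <- 1
    v[condition_id(t, a, "WT")] <- -1
    v
  }
  for (t in tissues) {
    for (a in ages) L[[paste0("A", a, "T", tl(t))]] <- tg_vec(t, a)
    if (length(ages) > 1) {
      for (i in seq_along(ages)[-1]) {
        for (j in seq_len(i - 1)) {
          id <- paste0("A", ages[i], ages[j], "T", tl(t))
          L[[id]] <- tg_vec(t, ages[i]) - tg_vec(t, ages[j])
        }
      }
    }
  }
  if (length(tissues) == 2) {
    for (a in ages) {
      id <- paste0("A", a, "T", tl(tissues[2]), tl(tissues[1]))
      L[[id]] <- tg_vec(tissues[2], a) - tg_vec(tissues[1], a)
    }
  }
  do.call(cbind, L)
}

#' Fit moderated contrasts on an LFQ experiment
#'
#' Per protein: generalized least squares over the condition-mean design
#' with block compound symmetry (consensus within-animal correlation
#' `rho`); residual variances shrunk towards a moment-matched prior;
#' moderated t with `prior_df + df_residual` degrees of freedom; two-tailed
#' p; BH adjustment within each contrast independently. A (protein,
#' contrast) pair whose contrast touches a condition with no observed value
#' for that protein is reported absent (no row), so downstream counts equal
#' set cardinalities.
#'
#' @param lfq an [lfq_experiment()].
#' @param contrasts contrast matrix (rows = condition ids, columns =
#'   contrast ids); defaults to [fad_contrasts()].
#' @param rho consensus within-animal correlation; `NULL` to estimate via
#'   [estimate_consensus_correlation()].
#' @param prior_df override the estimated prior degrees of freedom
#'   (0 disables shrinkage, `Inf` pools fully); `NULL` to estimate.
#' @param fdr_threshold significance threshold on the adjusted p-value.
#' @param log_scale `"log10"` (native) or `"log2"` (effects multiplied by
#'   `log2(10)`).
#' @return object of class `lfq_fit`: `results` tibble (`protein_id`,
#'   `contrast_id`, `logfc`, `stat`, `p_value`, `fdr`, `significant`,
#'   `df_residual`, `df_total`) and `moderation` state (`prior_df`,
#'   `prior_var`, `rho`, per-protein `s2`). Use [tidy()] / [glance()].
#' @export
fit_contrasts <- function(lfq, contrasts = NULL, rho = NULL,
                          prior_df = NULL, fdr_threshold = 0.05,
                          log_scale = c("log10", "log2")) {
  log_scale <- match.arg(log_scale)
  if (is.null(contrasts)) contrasts <- fad_contrasts(lfq$samples)
  if (is.null(rho)) rho <- estimate_consensus_correlation(lfq)
  rho <- min(max(rho, -0.45), 0.9999)

  Y <- lfq$values
  p <- nrow(Y)
  cond <- factor(sample_conditions(lfq), levels = rownames(contrasts))
  if (anyNA(cond)) abort("contrast matrix does not cover all conditions")
  X <- stats::model.matrix(~ 0 + cond)
  colnames(X) <- levels(cond)
  block <- paste(lfq$samples$animal_id, lfq$samples$tissue)
  m <- ncol(contrasts)

  est <- u2 <- matrix(NA_real_, p, m,
                      dimnames = list(rownames(Y), colnames(contrasts)))
  s2 <- df <- rep(NA_real_, p)

  for (rows in split(seq_len(p), pattern_key(Y))) {
    o <- which(!is.na(Y[rows[1], ]))
    if (length(o) < 2L) next
    Xo <- X[o, , drop = FALSE]
    keep <- colSums(Xo) > 0
    k <- sum(keep)
    if (length(o) <= k) next   # zero residual df: excluded and flagged NA
    W <- cs_whitener(block[o], rho)
    Xw <- W %*% Xo[, keep, drop = FALSE]
    pinv <- chol2inv(chol(crossprod(Xw)))
    Yw <- Y[rows, o, drop = FALSE] %*% W   # W symmetric
    B <- Yw %*% (Xw %*% pinv)
    Res <- Yw - B %*% t(Xw)
    s2[rows] <- rowSums(Res^2) / (length(o) - k)
    df[rows] <- length(o) - k
    for (j in seq_len(m)) {
      w <- contrasts[, j]
      if (any(w[!keep] != 0)) next   # contrast not estimable: absent
      wk <- w[keep]
      est[rows, j] <- B %*% wk
      u2[rows, j] <- drop(t(wk) %*% pinv %*% wk)
    }
  }

  prior <- if (is.null(prior_df)) {
    estimate_moderation_prior(s2, df)
  } else {
    base <- estimate_moderation_prior(s2, df)
    list(prior_df = prior_df,
         prior_var = if (is.finite(prior_df) && prior_df == 0) {
           NA_real_
         } else {
           base$prior_var
         })
  }
  d0 <- prior$prior_df
  s02 <- prior$prior_var
  s2_tilde <- if (is.infinite(d0)) {
    rep(s02, p)
  } else if (d0 == 0 || is.na(s02)) {
    s2
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }

  scale_factor <- if (log_scale == "log2") log2(10) else 1
  results <- purrr::map_dfr(seq_len(m), function(j) {
    present <- which(!is.na(est[, j]) & is.finite(s2_tilde) & df > 0)
    if (!length(present)) return(NULL)
    se <- sqrt(u2[present, j] * s2_tilde[present])
    stat <- est[present, j] / se
    df_tot <- df[present] + d0
    pval <- 2 * pt(-abs(stat), df_tot)
    fdr <- benjamini_hochberg(pval)
    tibble(
      protein_id = rownames(Y)[present],
      contrast_id = colnames(contrasts)[j],
      logfc = unname(est[present, j]) * scale_factor,
      stat = unname(stat),
      p_value = unname(pval),
      fdr = unname(fdr),
      significant = unname(fdr < fdr_threshold),
      df_residual = unname(df[present]),
      df_total = unname(df_tot)
    )
  })

  structure(
    list(results = results,
         moderation = list(prior_df = d0, prior_var = s02, rho = rho,
                           s2 = tibble(protein_id = rownames(Y),
                                       s2 = s2, df_residual = df)),
         contrasts = contrasts,
         log_scale = log_scale,
         fdr_threshold = fdr_threshold),
    class = "lfq_fit"
  )
}

#' @export
print.lfq_fit <- function(x, ...) {
  cat("<lfq_fit> ", dplyr::n_distinct(x$results$protein_id), " proteins, ",
      dplyr::n_distinct(x$results$contrast_id), " contrast(s)\n", sep = "")
  cat("  prior df: ", format(x$moderation$prior_df, digits = 4),
      "; prior var: ", format(x$moderation$prior_var, digits = 4),
      "; rho: ", format(x$moderation$rho, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy lfq_fit
#' @export
tidy.lfq_fit <- function(x, ...) x$results

#' @method glance lfq_fit
#' @export
glance.lfq_fit <- function(x, ...) {
  tibble(
    prior_df = x$moderation$prior_df,
    prior_var = x$moderation$prior_var,
    rho = x$moderation$rho,
    n_proteins = dplyr::n_distinct(x$results$protein_id),
    n_contrasts = dplyr::n_distinct(x$results$contrast_id),
    n_significant = sum(x$results$significant)
  )
}

#' Pairwise (single tissue, single age) transgene fit
#'
#' The same statistical machinery restricted to one (tissue, age): proteins
#' reliable in both genotypes, genotype-mean design, contrast TG - WT.
#' Result family named `DE.<tissue>.Age<age>` (tissue abbreviated to
#' `hippo` for hippocampus).
#'
#' @inheritParams fit_contrasts
#' @param tissue,age condition selectors.
#' @param analysis_set optional protein ids; defaults to
#'   [pairwise_analysis_set()].
#' @return an `lfq_fit`.
#' @export
pairwise_fit <- function(lfq, tissue, age, analysis_set = NULL, rho = NULL,
                         prior_df = NULL, fdr_threshold = 0.05,
                         log_scale = c("log10", "log2")) {
  keep <- lfq$samples$tissue == tissue & lfq$samples$age == age
  if (!any(keep)) abort(sprintf("no samples at (%s, %s months)", tissue, age))
  if (is.null(analysis_set)) {
    analysis_set <- pairwise_analysis_set(lfq, tissue, age)
  }
  sub <- lfq[match(analysis_set, lfq$proteins$protein_id), which(keep)]
  short <- if (tissue == "hippocampus") "hippo" else tissue
  cid <- sprintf("DE.%s.Age%g", short, age)
  conds <- sort(unique(sample_conditions(sub)))
  L <- matrix(0, length(conds), 1, dimnames = list(conds, cid))
  L[grepl("\\.TG$", conds), 1] <- 1
  L[grepl("\\.WT$", conds), 1] <- -1
  fit_contrasts(sub, contrasts = L, rho = rho, prior_df = prior_df,
                fdr_threshold = fdr_threshold, log_scale = log_scale)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment, monotone in p rank and
#' capped at 1, computed separately for each contrast by the fitting
#' functions.
#'
#' @param p numeric vector of p-values in `[0, 1]`; empty in, empty out.
#' @return adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
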