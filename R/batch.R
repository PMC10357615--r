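# Parametric empirical-Bayes batch adjustment of log10 LFQ intensities.
# Implements the classic location/scale model (per-protein standardization
# by a covariate fit, per-batch location and scale estimates shrunk to
# batch-level normal / inverse-gamma priors, moment-matched), with full
# support for missing values: NA entries stay NA and are excluded from
# every estimate, honoring the no-imputation contract.

pattern_key <- function(M) {
  apply(is.na(M), 1L, function(r) paste0(as.integer(r), collapse = ""))
}

# Per-protein OLS coefficients for a common design with row-wise missing
# data: proteins sharing a missingness pattern are solved together.
fit_by_pattern <- function(Y, X) {
  p <- nrow(Y)
  k <- ncol(X)
  B <- matrix(NA_real_, p, k, dimnames = list(rownames(Y), colnames(X)))
  for (rows in split(seq_len(p), pattern_key(Y))) {
    o <- which(!is.na(Y[rows[1], ]))
    if (!length(o)) next
    Xo <- X[o, , drop = FALSE]
    qr_o <- qr(Xo)
    cf <- qr.coef(qr_o, t(Y[rows, o, drop = FALSE]))
    B[rows, ] <- t(cf)
  }
  B
}

#' Empirical-Bayes batch adjustment with missing values
#'
#' Adjusts a log10 intensity matrix for additive and multiplicative batch
#' effects while protecting the condition (tissue/age/genotype) effects
#' through covariates. Per-protein per-batch location and scale estimates
#' are shrunk towards batch-level priors (normal for locations,
#' inverse-gamma for scales, both moment-matched) and removed on the
#' standardized scale. A single batch returns the input unchanged. Batches
#' with fewer than two observed values for a protein fall back to the
#' prior means (recorded in the model's `fallback` table).
#'
#' @param lfq an [lfq_experiment()]; adjust each tissue separately.
#' @param covariates factor (length = samples) whose effects must be
#'   preserved; defaults to the condition factor. `NULL` for none.
#' @return list with `lfq` (adjusted) and `model` (class `batch_model`:
#'   shrunk per-batch location/scale estimates, priors, fallbacks).
#' @export
adjust_batch <- function(lfq, covariates = NULL) {
  batch <- factor(lfq$samples$batch)
  if (nlevels(batch) < 2L) {
    model <- structure(list(batches = levels(batch), identity = TRUE),
                       class = "batch_model")
    return(list(lfq = lfq, model = model))
  }
  Y <- lfq$values
  p <- nrow(Y)
  n <- ncol(Y)
  if (is.null(covariates)) covariates <- factor(sample_conditions(lfq))
  covariates <- droplevels(factor(covariates))

  batch_mm <- stats::model.matrix(~ 0 + batch)
  X <- if (nlevels(covariates) > 1L) {
    cov_mm <- stats::model.matrix(~ covariates)[, -1, drop = FALSE]
    # refuse designs where batch is confounded with the covariates
    # (joint design rank deficient)
    joint <- cbind(batch_mm, cov_mm)
    if (qr(joint)$rank < ncol(joint)) {
      abort("batch is confounded with a covariate level; refusing to adjust")
    }
    joint
  } else {
    batch_mm
  }

  B <- fit_by_pattern(Y, X)
  B0 <- B
  B0[is.na(B0)] <- 0
  nb <- nlevels(batch)
  n_per_batch <- as.numeric(table(batch))
  alpha <- as.numeric(B0[, seq_len(nb), drop = FALSE] %*%
                        (n_per_batch / n))
  cov_part <- if (ncol(X) > nb) {
    B0[, -seq_len(nb), drop = FALSE] %*% t(X[, -seq_len(nb), drop = FALSE])
  } else {
    matrix(0, p, n)
  }
  stand_mean <- alpha + cov_part          # p x n
  fitted <- B0 %*% t(X)
  resid <- Y - fitted
  n_obs <- rowSums(!is.na(Y))
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / n_obs
  var_pooled[var_pooled <= 0 | !is.finite(var_pooled)] <- NA_real_
  sigma <- sqrt(var_pooled)

  Z <- (Y - stand_mean) / sigma

  gamma_star <- delta_star <- matrix(NA_real_, p, nb,
                                     dimnames = list(rownames(Y),
                                                     levels(batch)))
  priors <- list()
  fallback <- list()
  for (i in seq_len(nb)) {
    cols <- which(batch == levels(batch)[i])
    Zi <- Z[, cols, drop = FALSE]
    n_ig <- rowSums(!is.na(Zi))
    g_hat <- rowMeans(Zi, na.rm = TRUE)
    d_hat <- apply(Zi, 1, var, na.rm = TRUE)
    usable <- n_ig >= 2L & is.finite(g_hat) & is.finite(d_hat) & d_hat > 0
    if (sum(usable) < 2L) {
      # too few proteins to form a prior: keep raw estimates
      gamma_star[, i] <- g_hat
      delta_star[, i] <- ifelse(is.finite(d_hat) & d_hat > 0, d_hat, 1)
      warn("fewer than 2 usable proteins in a batch; no shrinkage applied")
      next
    }
    g_bar <- mean(g_hat[usable])
    t2 <- var(g_hat[usable])
    m <- mean(d_hat[usable])
    s2 <- var(d_hat[usable])
    a_pr <- (2 * s2 + m^2) / s2
    b_pr <- (m * s2 + m^3) / s2
    # joint EB iteration (proteins vectorized)
    g_new <- g_hat
    d_new <- d_hat
    g_new[!usable] <- g_bar
    d_new[!usable] <- b_pr / (a_pr - 1)
    sum_fun <- function(g) rowSums((Zi - g)^2, na.rm = TRUE)
    for (it in 1:100) {
      g_old <- g_new
      d_old <- d_new
      g_new <- ifelse(usable,
                      (n_ig * t2 * g_hat + d_new * g_bar) /
                        (n_ig * t2 + d_new),
                      g_bar)
      d_new <- ifelse(usable,
                      (b_pr + 0.5 * sum_fun(g_new)) /
                        (n_ig / 2 + a_pr - 1),
                      b_pr / (a_pr - 1))
      if (max(abs(g_new - g_old), abs(d_new - d_old), na.rm = TRUE) < 1e-8) {
        break
      }
    }
    gamma_star[, i] <- g_new
    delta_star[, i] <- d_new
    priors[[levels(batch)[i]]] <- tibble(
      batch = levels(batch)[i], gamma_bar = g_bar, tau2 = t2,
      a_prior = a_pr, b_prior = b_pr
    )
    fallback[[i]] <- tibble(batch = levels(batch)[i],
                            protein_id = rownames(Y)[!usable])
  }

  bidx <- as.integer(batch)
  adj <- (Z - gamma_star[, bidx, drop = FALSE]) /
    sqrt(delta_star[, bidx, drop = FALSE])
  Y_adj <- adj * sigma + stand_mean
  Y_adj[is.na(Y)] <- NA_real_

  model <- structure(
    list(batches = levels(batch), identity = FALSE,
         gamma_star = gamma_star, delta_star = delta_star,
         priors = bind_rows(priors), fallback = bind_rows(fallback),
         var_pooled = var_pooled),
    class = "batch_model"
  )
  list(lfq = lfq_experiment(Y_adj, lfq$proteins, lfq$samples),
       model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<batch_model> single batch: identity adjustment\n")
  } else {
    cat("<batch_model> ", length(x$batches), " batches; ",
        nrow(x$fallback), " protein-batch fallbacks to prior\n", sep = "")
  }
  invisible(x)
}

#' @method glance batch_model
#' @export
glance.batch_model <- function(x, ...) {
  tibble(n_batches = length(x$batches), identity = isTRUE(x$identity),
         n_fallback = if (is.null(x$fallback)) 0L else nrow(x$fallback))
}
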