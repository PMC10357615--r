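# End-to-end orchestration: synthetic inputs (or user tables) -> reliability
# filtering -> batch adjustment -> pairwise and full moderated fits ->
# aggregate-trajectory classification -> cross-species concordance ->
# candidate funnel -> CSF biomarker evaluation, with one config, a
# deterministic manifest and per-stage counts.

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage draws a named substream
#'   from it.
#' @param preset generator preset (see [fad_preset()]).
#' @param fdr_threshold FDR significance threshold.
#' @param alpha trajectory-correlation significance level.
#' @param top_k funnel effect-rank cutoff.
#' @param funnel_terms annotation terms accepted by the funnel's last stage.
#' @param overlap_fraction,concordance_fraction human-table generator
#'   fractions.
#' @param out_dir optional directory; when given, every artifact is written
#'   there together with `manifest.json`.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, preset = "5xfad", fdr_threshold = 0.05,
                            alpha = 0.05, top_k = 25L,
                            funnel_terms = c("lysosome", "endo-lysosomal"),
                            overlap_fraction = 0.5,
                            concordance_fraction = 0.8,
                            out_dir = NULL) {
  assert_seed(seed)
  structure(
    list(seed = as.integer(seed), preset = preset,
         fdr_threshold = fdr_threshold, alpha = alpha,
         top_k = as.integer(top_k), funnel_terms = funnel_terms,
         overlap_fraction = overlap_fraction,
         concordance_fraction = concordance_fraction, out_dir = out_dir),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order on the preset's synthetic
#' inputs. Re-running with the same config and seed reproduces every
#' result exactly (the manifest records a hash over all stage outputs, so
#' two runs can be compared by hash equality).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_run` with all stage results and
#'   `manifest` (config hash, per-stage counts, results hash).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  pre <- fad_preset(config$preset)

  sim <- simulate_lfq(pre$design, pre$params, seed = seed)
  traj <- sim$truth$trajectories
  human <- simulate_human_tables(
    sim$truth, seed = seed,
    overlap_fraction = config$overlap_fraction,
    concordance_fraction = config$concordance_fraction
  )
  deg <- simulate_deg_table(sim$truth, seed = seed)
  csf <- simulate_csf(seed = seed)

  tissues <- unique(pre$design$tissue)
  ages <- sort(unique(pre$design$age))

  # per-tissue reliability filter + batch adjustment
  tissue_data <- purrr::map(setNames(tissues, tissues), function(t) {
    flt <- filter_tissue(sim$lfq, t)
    adj <- adjust_batch(flt$lfq)
    list(lfq = adj$lfq, filter_report = flt$report,
         batch_model = adj$model)
  })

  # pairwise fits per (tissue, age)
  pairwise <- purrr::map(tissue_data, function(td) {
    purrr::map(setNames(ages, paste0("age", ages)), function(a) {
      pairwise_fit(td$lfq, unique(td$lfq$samples$tissue), a,
                   fdr_threshold = config$fdr_threshold)
    })
  })
  pairwise_results <- purrr::map(pairwise, function(fits) {
    bind_rows(purrr::map(fits, tidy))
  })

  # full model on the cross-tissue reconciled set
  fms <- full_model_set(tissue_data[[1]]$lfq, tissue_data[[2]]$lfq)
  full_fit <- if (nrow(fms$pairs) >= 2) {
    a <- tissue_data[[1]]$lfq
    b <- tissue_data[[2]]$lfq
    vals <- cbind(a$values[fms$pairs$id_a, , drop = FALSE],
                  b$values[fms$pairs$id_b, , drop = FALSE])
    rownames(vals) <- fms$pairs$id_a
    combined <- lfq_experiment(
      vals,
      a$proteins[match(fms$pairs$id_a, a$proteins$protein_id), ],
      bind_rows(a$samples, b$samples)
    )
    fit_contrasts(combined, fdr_threshold = config$fdr_threshold)
  }

  # full-vs-pairwise transgene-statistic consistency
  consistency <- if (!is.null(full_fit)) {
    purrr::map_dfr(tissues, function(t) {
      tl <- toupper(substr(t, 1, 1))
      purrr::map_dfr(ages, function(a) {
        fid <- paste0("A", a, "T", tl)
        f <- filter(full_fit$results, .data$contrast_id == fid)
        short <- if (t == "hippocampus") "hippo" else t
        p <- filter(pairwise_results[[t]],
                    .data$contrast_id == sprintf("DE.%s.Age%g", short, a))
        shared <- intersect(f$protein_id, p$protein_id)
        tibble(tissue = t, age = a, n_shared = length(shared),
               t_correlation = if (length(shared) >= 3) {
                 cor(f$stat[match(shared, f$protein_id)],
                     p$stat[match(shared, p$protein_id)])
               } else NA_real_)
      })
    })
  }

  # aggregate-trajectory classification of the pairwise DEPs
  dep_lfcs <- purrr::imap_dfr(pairwise_results, function(res, t) {
    deps <- unique(res$protein_id[res$significant])
    res |>
      filter(.data$protein_id %in% deps) |>
      mutate(tissue = t,
             age = as.numeric(sub(".*Age", "", .data$contrast_id))) |>
      select("protein_id", "tissue", "age", "logfc")
  })
  classification <- classify_abeta(dep_lfcs, traj, alpha = config$alpha)

  # cross-species
  resolution <- resolve_orthologs(human$ortholog_map)
  gene_map <- sim$lfq$proteins
  mouse_datasets <- list(
    H5 = list(tissue = "hippocampus", age = 5),
    H8 = list(tissue = "hippocampus", age = 8),
    C8 = list(tissue = "cortex", age = 8)
  )
  mouse_diff <- purrr::imap_dfr(mouse_datasets, function(d, id) {
    short <- if (d$tissue == "hippocampus") "hippo" else d$tissue
    pairwise_results[[d$tissue]] |>
      filter(.data$contrast_id == sprintf("DE.%s.Age%g", short, d$age)) |>
      mutate(dataset_id = id,
             gene_symbol = gene_map$gene_symbol[
               match(.data$protein_id, gene_map$protein_id)]) |>
      select("dataset_id", "gene_symbol", "logfc", "significant")
  })
  cset <- concordance(mouse_diff, human$tables, resolution)
  signatures <- if (nrow(cset)) make_signatures(cset)
  xcorr <- cross_correlation(mouse_diff, human$tables, resolution,
                             mode = "all")
  mouse_sets <- purrr::imap(mouse_datasets, function(d, id) {
    unique(mouse_diff$gene_symbol[mouse_diff$significant &
                                    mouse_diff$dataset_id == id])
  })
  human_sets <- split(
    human$tables$gene_symbol[human$tables$significant],
    human$tables$dataset_id[human$tables$significant]
  )
  overlaps <- overlap_report(mouse_sets, human_sets, resolution)

  # candidate funnel (hippocampus)
  hippo <- tissue_data$hippocampus
  funnel <- run_funnel(
    present_set = hippo$lfq$proteins$protein_id,
    dep_table = pairwise_results$hippocampus,
    human = human$tables,
    resolution = resolution,
    cset = cset,
    classification = filter(classification,
                            .data$tissue == "hippocampus"),
    annotations = sim$truth$annotations,
    gene_map = gene_map,
    terms = config$funnel_terms,
    k = config$top_k
  )

  # transcript-protein intersection
  class_sym <- classification |>
    mutate(gene_symbol = gene_map$gene_symbol[
      match(.data$protein_id, gene_map$protein_id)])
  deg_dep <- intersect_deg_dep(deg, class_sym)

  # wild-type expression split (hippocampus, oldest age)
  wt_cols <- hippo$lfq$samples$genotype == "WT" &
    hippo$lfq$samples$age == max(ages)
  wt_expr <- tibble(
    protein_id = hippo$lfq$proteins$protein_id,
    wt_mean = rowMeans(hippo$lfq$values[, wt_cols, drop = FALSE],
                       na.rm = TRUE)
  ) |> filter(is.finite(.data$wt_mean))
  short_h <- "hippo"
  h8 <- filter(pairwise_results$hippocampus,
               .data$contrast_id == sprintf("DE.%s.Age%g", short_h,
                                            max(ages)))
  wt_split <- wt_median_split(
    wt_expr,
    h8 |> select("protein_id", "significant")
  )

  # CSF biomarker evaluation
  roc <- roc_curve(csf$analyte[csf$group == "AD"],
                   csf$analyte[csf$group == "control"])
  groups <- group_compare(csf)
  assoc <- biomarker_spearman(csf)

  results <- list(
    sim = sim, human = human, deg = deg, csf = csf,
    tissue_data = tissue_data, pairwise = pairwise,
    pairwise_results = pairwise_results, full_model = fms,
    full_fit = full_fit, consistency = consistency,
    classification = classification, resolution = resolution,
    concordance = cset, signatures = signatures,
    cross_correlation = xcorr, overlaps = overlaps, funnel = funnel,
    deg_dep = deg_dep, wt_split = wt_split,
    roc = roc, group_compare = groups, biomarker_assoc = assoc
  )

  counts <- list(
    n_proteins = nrow(sim$lfq$values),
    n_samples = ncol(sim$lfq$values),
    n_present = purrr::map_int(tissue_data,
                               ~ nrow(.x$lfq$values)),
    n_dep_pairwise = purrr::map_int(pairwise_results,
                                    ~ dplyr::n_distinct(
                                      .x$protein_id[.x$significant])),
    n_full_model = nrow(fms$pairs),
    n_classified = sum(classification$class != "none"),
    n_concordant = nrow(cset),
    funnel = setNames(as.list(funnel$stages$n), funnel$stages$stage),
    csf_auc = roc$auc
  )
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config),
    counts = counts,
    results_hash = rlang::hash(list(
      purrr::map(pairwise_results, ~ .x),
      if (!is.null(full_fit)) full_fit$results,
      classification, cset, funnel$stages, roc$auc
    ))
  )

  run <- structure(c(results, list(manifest = manifest)),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_outputs(run, config)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> config ", x$manifest$config_hash, "\n", sep = "")
  cat("  proteins: ", x$manifest$counts$n_proteins,
      "; pairwise DEPs: ",
      paste(names(x$manifest$counts$n_dep_pairwise),
            x$manifest$counts$n_dep_pairwise, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  concordant: ", x$manifest$counts$n_concordant,
      "; funnel final: ",
      x$manifest$counts$funnel[[length(x$manifest$counts$funnel)]],
      "; CSF AUC: ", sprintf("%.3f", x$manifest$counts$csf_auc),
      "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(run, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_protein_groups(run$sim$lfq, p("protein_groups.tsv"))
  write_sample_meta(run$sim$lfq$samples, p("sample_meta.csv"))
  write_trajectories(run$sim$truth$trajectories, p("abeta_trajectories.csv"))
  write_ortholog_map(run$human$ortholog_map, p("ortholog_map.tsv"))
  write_human_tables(run$human$tables, config$out_dir)
  write_deg_table(run$deg, p("deg_table.csv"))
  write_csf_table(run$csf, p("csf_table.csv"))
  for (t in names(run$pairwise_results)) {
    write_diff_table(run$pairwise_results[[t]],
                     p(paste0("diff_pairwise_", t, ".csv")))
  }
  if (!is.null(run$full_fit)) {
    write_diff_table(run$full_fit$results, p("diff_full_model.csv"))
  }
  write_pf_csv(run$classification, p("abeta_classification.csv"))
  write_pf_csv(run$concordance, p("concordance.csv"))
  write_funnel_report(run$funnel, p("funnel_report.json"))
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
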