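#' Study design table for the two-tissue amyloid time-course
#'
#' Builds the sample layout of the emulated study: every biological replicate
#' (animal) of each (age, genotype) cell contributes both tissues, and every
#' (tissue, animal) pair is measured in technical replicates. The default
#' matches the design this package emulates: 2 tissues x ages {2, 5, 8}
#' months x {WT, TG} x 5 animals x 2 technical replicates, with a third
#' technical replicate for the 5-month hippocampus samples.
#'
#' Batches default to one per (tissue, acquisition half): within each tissue
#' the animal roster is split in two halves, emulating data acquired in two
#' MS blocks.
#'
#' @param tissues character vector of tissue labels.
#' @param ages ordered numeric vector of ages in months.
#' @param genotypes character vector; must contain `"WT"` and `"TG"`.
#' @param n_animals biological replicates per (age, genotype) cell.
#' @param n_tech_reps technical replicates per (tissue, animal).
#' @param extra_tech_rep list with `tissue` and `age`; that condition gets
#'   one extra technical replicate (`NULL` to disable).
#' @return tibble with one row per sample: `sample_id`, `tissue`, `age`,
#'   `genotype`, `animal_id`, `tech_rep`, `batch`.
#' @export
fad_design <- function(tissues = c("cortex", "hippocampus"),
                       ages = c(2, 5, 8),
                       genotypes = c("WT", "TG"),
                       n_animals = 5L,
                       n_tech_reps = 2L,
                       extra_tech_rep = list(tissue = "hippocampus", age = 5)) {
  if (n_animals < 2L) abort("every condition needs >= 2 biological replicates")
  if (n_tech_reps < 1L) abort("n_tech_reps must be positive")
  if (length(ages) < 1L) abort("at least one age is required")

  animals <- tidyr::expand_grid(
    age = ages, genotype = genotypes, rep = seq_len(n_animals)
  ) |>
    mutate(animal_id = sprintf("%s%g_%02d", .data$genotype, .data$age,
                               .data$rep))

  design <- tidyr::expand_grid(tissue = tissues, animals) |>
    rowwise() |>
    mutate(n_tech = n_tech_reps +
             as.integer(!is.null(extra_tech_rep) &&
                          .data$tissue == extra_tech_rep$tissue &&
                          .data$age == extra_tech_rep$age)) |>
    ungroup() |>
    tidyr::uncount(.data$n_tech, .id = "tech_rep") |>
    mutate(
      batch = paste0(.data$tissue, "_b",
                     1L + as.integer(.data$rep > ceiling(n_animals / 2))),
      sample_id = sprintf("%s_%s_t%d", .data$animal_id, .data$tissue,
                          .data$tech_rep)
    ) |>
    select("sample_id", "tissue", "age", "genotype", "animal_id",
           "tech_rep", "batch")
  design
}

#' Generator parameters for synthetic LFQ data
#'
#' Defaults define the emulated study conditions on the log10 LFQ intensity
#' scale. Missingness is missing-not-at-random (MNAR): an observation is
#' masked with probability `plogis(missing_slope * (missing_midpoint - y))`,
#' so low intensities vanish more often, which is the standard LFQ
#' non-detection model and what the no-imputation reliability filter guards
#' against.
#'
#' @param n_proteins number of protein groups.
#' @param baseline_mean,baseline_sd per-protein baseline log10 intensity.
#' @param animal_sd biological (per animal) noise sd.
#' @param tech_sd technical replicate noise sd.
#' @param missing_midpoint,missing_slope logistic MNAR parameters
#'   (midpoint on the log10 scale; slope per log10 unit; slope 0 gives a
#'   flat 50% missing rate, midpoint `-Inf` disables missingness).
#' @param batch_shift_sd sd of per-batch additive shifts (and of per-protein
#'   deviations around them); `batch_shifts` may fix the per-batch means.
#' @param batch_scale_sd sd of per-batch log multiplicative noise scales.
#' @param batch_shifts optional named numeric of fixed per-batch shifts.
#' @param dep_fraction fraction of proteins planted as tissue DEPs.
#' @param n_abeta_corr,n_abeta_acorr planted aggregate-correlated /
#'   anticorrelated proteins per tissue (named numeric: cortex, hippocampus).
#' @param lfc_range magnitude range of planted log10 fold-changes at the
#'   oldest age.
#' @param candidate plant a hippocampus-specific, monotone-increasing,
#'   lysosome-annotated candidate protein (logical).
#' @return a list of validated parameters, class `fad_params`.
#' @export
fad_params <- function(n_proteins = 1500L,
                       baseline_mean = 7,
                       baseline_sd = 0.8,
                       animal_sd = 0.08,
                       tech_sd = 0.05,
                       missing_midpoint = 5.5,
                       missing_slope = 2,
                       batch_shift_sd = 0.2,
                       batch_scale_sd = 0.05,
                       batch_shifts = NULL,
                       dep_fraction = 0.15,
                       n_abeta_corr = c(cortex = 20, hippocampus = 40),
                       n_abeta_acorr = c(cortex = 12, hippocampus = 25),
                       lfc_range = c(0.15, 0.6),
                       candidate = TRUE) {
  p <- list(
    n_proteins = as.integer(n_proteins), baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, animal_sd = animal_sd, tech_sd = tech_sd,
    missing_midpoint = missing_midpoint, missing_slope = missing_slope,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    batch_shifts = batch_shifts, dep_fraction = dep_fraction,
    n_abeta_corr = n_abeta_corr, n_abeta_acorr = n_abeta_acorr,
    lfc_range = lfc_range, candidate = isTRUE(candidate)
  )
  sds <- c(p$baseline_sd, p$animal_sd, p$tech_sd, p$batch_shift_sd,
           p$batch_scale_sd)
  if (any(sds < 0)) abort("all sd parameters must be >= 0")
  if (p$n_proteins < 1L) abort("n_proteins must be positive")
  if (p$dep_fraction < 0 || p$dep_fraction > 1) {
    abort("dep_fraction must lie in [0, 1]")
  }
  structure(p, class = "fad_params")
}

# Planted log10 fold-change trajectories. Aggregate-tracking proteins are
# affine in one aggregate readout trajectory (so their true trajectory
# correlation is exactly +/-1); generic DEPs get a random monotone-ish shape
# whose magnitude grows with age, the dominant pattern in amyloid models.
plant_lfcs <- function(params, ages, tissues, trajectories) {
  n <- params$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  lfc <- list()
  classes <- list()
  n_dep <- round(params$dep_fraction * n)
  pool <- seq_len(n)

  cand_id <- NULL
  if (params$candidate) {
    cand_id <- ids[1L]
    pool <- setdiff(pool, 1L)
    traj <- trajectories$value[trajectories$tissue == "hippocampus" &
                                 trajectories$readout == "MFA"]
    scaled <- (traj - min(traj)) / diff(range(traj))
    lfc[["cand"]] <- tibble(
      protein_id = cand_id, tissue = "hippocampus", age = ages,
      lfc = 0.3 + 0.4 * scaled
    )
    classes[["cand"]] <- tibble(protein_id = cand_id,
                                tissue = "hippocampus", class = "candidate")
  }

  for (t in tissues) {
    dep_idx <- sample(pool, min(n_dep, length(pool)))
    n_corr <- unname(params$n_abeta_corr[t] %||% 0)
    n_acorr <- unname(params$n_abeta_acorr[t] %||% 0)
    n_corr <- min(n_corr, length(dep_idx))
    n_acorr <- min(n_acorr, max(0L, length(dep_idx) - n_corr))
    corr_idx <- dep_idx[seq_len(n_corr)]
    acorr_idx <- dep_idx[n_corr + seq_len(n_acorr)]
    plain_idx <- setdiff(dep_idx, c(corr_idx, acorr_idx))
    readouts <- unique(trajectories$readout)

    affine <- function(idx, sign) {
      if (!length(idx)) return(NULL)
      purrr::map_dfr(idx, function(i) {
        ro <- sample(readouts, 1L)
        traj <- trajectories$value[trajectories$tissue == t &
                                     trajectories$readout == ro]
        scaled <- (traj - min(traj)) / diff(range(traj))
        span <- runif(1, params$lfc_range[1], params$lfc_range[2])
        offset <- runif(1, -0.1, 0.1)
        tibble(protein_id = ids[i], tissue = t, age = ages,
               lfc = sign * (offset + span * scaled))
      })
    }
    lfc[[paste0(t, "_corr")]] <- affine(corr_idx, +1)
    lfc[[paste0(t, "_acorr")]] <- affine(acorr_idx, -1)
    if (length(plain_idx)) {
      lfc[[paste0(t, "_plain")]] <- purrr::map_dfr(plain_idx, function(i) {
        mag <- runif(1, params$lfc_range[1], params$lfc_range[2])
        s <- sample(c(-1, 1), 1)
        u1 <- runif(1, 0, 0.4)
        u2 <- runif(1, u1, 0.8)
        tibble(protein_id = ids[i], tissue = t, age = ages,
               lfc = s * mag * c(u1, u2, 1)[seq_along(ages)])
      })
    }
    classes[[paste0(t, "_c")]] <- bind_rows(
      tibble(protein_id = ids[corr_idx], tissue = t, class = "abeta_corr"),
      tibble(protein_id = ids[acorr_idx], tissue = t, class = "abeta_acorr"),
      tibble(protein_id = ids[plain_idx], tissue = t, class = "dep")
    )
  }
  list(
    ids = ids,
    lfc = bind_rows(lfc),
    classes = bind_rows(classes),
    candidate_id = cand_id
  )
}

#' Simulate an LFQ intensity experiment with ground truth
#'
#' Draws a proteins x samples log10 intensity matrix following the study
#' design: per-protein baseline + planted condition effect (genotype
#' log10 fold-change at that tissue/age) + per-batch additive shift and
#' multiplicative noise scale + animal noise + technical noise, then masks
#' values as missing under the logistic MNAR model. The returned ground
#' truth records every planted quantity so recovery can be tested.
#'
#' @param design design tibble from [fad_design()].
#' @param params parameters from [fad_params()].
#' @param seed integer seed; required (reproducibility contract).
#' @param trajectories aggregate trajectories used to shape planted
#'   aggregate-tracking proteins; defaults to [simulate_abeta_trajectories()].
#' @return list with `lfq` (an [lfq_experiment()]) and `truth` (planted
#'   log fold-changes, classes, candidate id, annotations, batch effects).
#' @export
simulate_lfq <- function(design, params = fad_params(), seed,
                         trajectories = NULL) {
  assert_seed(seed)
  design <- as_tibble(design)
  ages <- sort(unique(design$age))
  tissues <- unique(design$tissue)
  reps <- count(design, .data$tissue, .data$age, .data$genotype,
                wt = dplyr::n_distinct(.data$animal_id))
  if (any(reps$n < 2)) abort("every condition needs >= 2 biological replicates")
  if (is.null(trajectories)) {
    trajectories <- simulate_abeta_trajectories(ages = ages, tissues = tissues)
  }

  n <- params$n_proteins
  ns <- nrow(design)

  planted <- with_substream(seed, "plant",
                            plant_lfcs(params, ages, tissues, trajectories))

  # per-batch effects
  batches <- unique(design$batch)
  truth_batch <- with_substream(seed, "batch", {
    shift <- if (!is.null(params$batch_shifts)) {
      params$batch_shifts[batches]
    } else {
      rnorm(length(batches), 0, params$batch_shift_sd)
    }
    tibble(batch = batches, shift = unname(shift),
           log_scale = rnorm(length(batches), 0, params$batch_scale_sd))
  })

  values <- with_substream(seed, "intensities", {
    baseline <- rnorm(n, params$baseline_mean, params$baseline_sd)
    mu <- matrix(baseline, nrow = n, ncol = ns)

    # planted genotype effects
    tg <- design$genotype == "TG"
    if (nrow(planted$lfc) && any(tg)) {
      key_col <- paste(design$tissue, design$age)[tg]
      key_lfc <- paste(planted$lfc$tissue, planted$lfc$age)
      for (k in unique(key_lfc)) {
        rows <- planted$lfc[key_lfc == k, ]
        cols <- which(tg)[key_col == k]
        if (length(cols)) {
          ridx <- match(rows$protein_id, planted$ids)
          mu[ridx, cols] <- mu[ridx, cols] + rows$lfc
        }
      }
    }

    # batch shift: batch-level mean plus per-protein deviation
    bidx <- match(design$batch, truth_batch$batch)
    shift_dev <- matrix(rnorm(n * length(batches), 0,
                              params$batch_shift_sd / 2),
                        nrow = n)
    mu <- mu + rep(truth_batch$shift[bidx], each = n) + shift_dev[, bidx]

    # noise: animal (shared across tech reps) and technical, scaled per batch
    akey <- paste(design$animal_id, design$tissue)
    animals <- unique(akey)
    animal_eff <- matrix(rnorm(n * length(animals), 0, params$animal_sd),
                         nrow = n)
    noise <- animal_eff[, match(akey, animals), drop = FALSE] +
      matrix(rnorm(n * ns, 0, params$tech_sd), nrow = n)
    scale <- exp(truth_batch$log_scale[bidx] +
                   rnorm(length(bidx), 0, params$batch_scale_sd / 2))
    mu + noise * rep(scale, each = n)
  })

  # MNAR masking
  values <- with_substream(seed, "missing", {
    if (is.finite(params$missing_midpoint)) {
      pmis <- plogis(params$missing_slope *
                       (params$missing_midpoint - values))
      values[matrix(runif(length(values)), nrow = n) < pmis] <- NA_real_
    }
    values
  })

  proteins <- tibble(
    protein_id = planted$ids,
    gene_symbol = mouse_case(sprintf("gene%04d", seq_len(n)))
  )

  annotations <- with_substream(seed, "annotations", {
    ann <- list()
    if (!is.null(planted$candidate_id)) {
      cand_sym <- proteins$gene_symbol[proteins$protein_id ==
                                         planted$candidate_id]
      # a second lysosome-annotated planted protein (Lamp1-like) plus
      # decoy annotations on null proteins
      hc <- planted$classes |>
        filter(.data$tissue == "hippocampus", .data$class == "abeta_corr")
      lamp_like <- if (nrow(hc)) {
        proteins$gene_symbol[proteins$protein_id == hc$protein_id[1]]
      }
      ann$lyso <- tibble(
        gene_symbol = c(cand_sym, lamp_like, cand_sym),
        term = c("lysosome", "lysosome", "endo-lysosomal")
      )
    }
    null_ids <- setdiff(proteins$gene_symbol,
                        proteins$gene_symbol[
                          match(unique(planted$classes$protein_id),
                                proteins$protein_id)])
    extra <- sample(null_ids, min(30L, length(null_ids)))
    ann$extra <- tibble(
      gene_symbol = extra,
      term = sample(c("synapse", "mitochondrion", "lysosome"),
                    length(extra), replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    )
    distinct(bind_rows(ann))
  })

  lfq <- lfq_experiment(values, proteins, design)
  truth <- list(
    planted_lfc = planted$lfc,
    classes = planted$classes,
    candidate_id = planted$candidate_id,
    annotations = annotations,
    batch = truth_batch,
    params = params,
    trajectories = trajectories,
    seed = as.integer(seed)
  )
  list(lfq = lfq, truth = truth)
}

#' Synthetic amyloid-aggregate trajectories
#'
#' Three-point (per age) mean trajectories of the four aggregate readouts:
#' membrane filter assay (MFA) signal, plaque load (%), and plaque counts by
#' 6E10 and Thioflavin-S staining. Hippocampus trajectories are strictly
#' increasing and steeper than cortex, mirroring the faster aggregate
#' deposition there. Values are deterministic per-tissue means (each
#' standing for the mean of `n_per_point` biological replicates).
#'
#' @param ages ordered ages (months); at least two required.
#' @param tissues tissues to emit.
#' @param shapes optional named list overriding trajectory values, as
#'   `shapes[[tissue]][[readout]]` numeric vectors of `length(ages)`.
#' @param n_per_point replicates behind each mean (recorded, not simulated).
#' @return tibble: `tissue`, `readout`, `age`, `value`, `n_per_point`,
#'   `zero_variance` flag (TRUE when a requested trajectory is constant and
#'   therefore unusable for correlation).
#' @export
simulate_abeta_trajectories <- function(ages = c(2, 5, 8),
                                        tissues = c("cortex", "hippocampus"),
                                        shapes = NULL,
                                        n_per_point = 5L) {
  if (length(ages) < 2L) abort("need >= 2 ages for a trajectory")
  defaults <- list(
    hippocampus = list(
      MFA = c(1, 3, 9),
      plaque_load = c(0.2, 1.5, 6),
      plaque_count_6E10 = c(5, 60, 260),
      plaque_count_ThioS = c(2, 35, 150)
    ),
    cortex = list(
      MFA = c(0.5, 1.2, 2.2),
      plaque_load = c(0.05, 0.4, 1.1),
      plaque_count_6E10 = c(2, 15, 45),
      plaque_count_ThioS = c(1, 8, 24)
    )
  )
  out <- purrr::map_dfr(tissues, function(t) {
    base <- defaults[[t]] %||% defaults$cortex
    if (!is.null(shapes) && !is.null(shapes[[t]])) {
      base <- modifyList(base, shapes[[t]])
    }
    purrr::map_dfr(names(base), function(ro) {
      v <- base[[ro]]
      # interpolate default 3-point shapes onto the requested age grid
      if (length(v) != length(ages)) {
        v <- stats::approx(seq(0, 1, length.out = length(v)),
                           v, seq(0, 1, length.out = length(ages)))$y
      }
      tibble(tissue = t, readout = ro, age = ages, value = v,
             n_per_point = n_per_point)
    })
  })
  out <- out |>
    group_by(.data$tissue, .data$readout) |>
    mutate(zero_variance = sd(.data$value) == 0) |>
    ungroup()
  if (any(out$zero_variance)) {
    warn("constant trajectory requested: correlation against it is undefined")
  }
  out
}

#' Synthetic human differential-abundance tables and ortholog map
#'
#' Emulates published human Alzheimer brain proteome tables (three datasets,
#' labelled D22, J20, J22) with controllable overlap with the planted mouse
#' DEPs and controllable sign concordance, plus a mouse-human symbol map
#' containing one-to-one, one-to-many and many-to-many components in stated
#' proportions. The planted candidate protein is forced significant and
#' upregulated in all human datasets.
#'
#' @param truth ground truth from [simulate_lfq()].
#' @param seed integer seed (required).
#' @param overlap_fraction probability that a planted mouse DEP is
#'   significant in each human dataset.
#' @param concordance_fraction probability that such an overlapping protein
#'   keeps the mouse effect sign.
#' @param n_background extra human-only genes per dataset.
#' @param frac_one_to_many,frac_many_to_many fractions of mapped genes drawn
#'   into ambiguous (1-to-many / many-to-many) ortholog components.
#' @param datasets dataset ids to emit.
#' @return list with `tables` (tibble: `dataset_id`, `gene_symbol`,
#'   `effect`, `significant`) and `ortholog_map` (tibble: `mouse_symbol`,
#'   `human_symbol`, `source_direction`).
#' @export
simulate_human_tables <- function(truth, seed,
                                  overlap_fraction = 0.5,
                                  concordance_fraction = 0.8,
                                  n_background = 600L,
                                  frac_one_to_many = 0.05,
                                  frac_many_to_many = 0.03,
                                  datasets = c("D22", "J20", "J22")) {
  assert_seed(seed)
  if (overlap_fraction < 0 || overlap_fraction > 1 ||
      concordance_fraction < 0 || concordance_fraction > 1) {
    abort("overlap and concordance fractions must lie in [0, 1]")
  }
  n <- truth$params$n_proteins
  mouse_syms <- mouse_case(sprintf("gene%04d", seq_len(n)))
  cand_sym <- if (!is.null(truth$candidate_id)) {
    mouse_case(sub("^P", "gene", truth$candidate_id))
  }

  with_substream(seed, "human", {
    human_syms <- toupper(mouse_syms)

    # ortholog map: both translation directions for clean pairs; planted
    # ambiguous components
    n_o2m <- round(frac_one_to_many * n)
    n_m2m <- round(frac_many_to_many * n / 2) * 2
    amb <- sample(setdiff(seq_len(n), match(cand_sym, mouse_syms)),
                  n_o2m + n_m2m)
    o2m <- head(amb, n_o2m)
    m2m <- utils::tail(amb, n_m2m)
    clean <- setdiff(seq_len(n), amb)

    map <- bind_rows(
      tibble(mouse_symbol = mouse_syms[clean],
             human_symbol = human_syms[clean], source_direction = "m2h"),
      tibble(mouse_symbol = mouse_syms[clean],
             human_symbol = human_syms[clean], source_direction = "h2m"),
      # one mouse gene mapping to two human symbols
      tibble(mouse_symbol = rep(mouse_syms[o2m], each = 2),
             human_symbol = as.vector(rbind(human_syms[o2m],
                                            paste0(human_syms[o2m], "B"))),
             source_direction = "m2h"),
      # fully connected 2x2 mouse-human clusters
      if (n_m2m > 0) {
        pairs <- matrix(m2m, ncol = 2)
        purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
          ms <- mouse_syms[pairs[i, ]]
          hs <- human_syms[pairs[i, ]]
          tidyr::expand_grid(mouse_symbol = ms, human_symbol = hs) |>
            mutate(source_direction = "m2h")
        })
      }
    ) |> distinct()

    dep_ids <- unique(truth$classes$protein_id)
    dep_syms <- mouse_syms[match(dep_ids, sprintf("P%04d", seq_len(n)))]
    dep_sign <- truth$planted_lfc |>
      group_by(.data$protein_id) |>
      summarise(sign = sign(.data$lfc[which.max(abs(.data$lfc))]),
                .groups = "drop")
    dep_sign <- setNames(dep_sign$sign, mouse_syms[
      match(dep_sign$protein_id, sprintf("P%04d", seq_len(n)))])

    tables <- purrr::map_dfr(datasets, function(ds) {
      take <- runif(length(dep_syms)) < overlap_fraction
      if (!is.null(cand_sym) && overlap_fraction > 0) {
        take[dep_syms == cand_sym] <- TRUE
      }
      sel <- dep_syms[take]
      agree <- runif(length(sel)) < concordance_fraction
      if (!is.null(cand_sym)) agree[sel == cand_sym] <- TRUE
      s <- unname(dep_sign[sel]) * ifelse(agree, 1, -1)
      overlap_tbl <- tibble(
        dataset_id = ds,
        gene_symbol = toupper(sel),
        effect = s * abs(rnorm(length(sel), 0.5, 0.2)),
        significant = TRUE
      )
      bg <- tibble(
        dataset_id = ds,
        gene_symbol = c(
          sample(setdiff(human_syms, toupper(sel)),
                 min(n_background, n - length(sel))),
          sprintf("HSONLY%03d_%s", seq_len(50), ds)
        ),
        effect = rnorm(min(n_background, n - length(sel)) + 50, 0, 0.3),
        significant = FALSE
      )
      bind_rows(overlap_tbl, bg)
    })
    list(tables = tables, ortholog_map = map)
  })
}

#' Synthetic differential-transcript (DEG) table
#'
#' Emulates an ingested transcriptome differential-expression table over
#' the same gene universe. Only a small fraction of the planted
#' aggregate-tracking proteins change at the transcript level (mirroring
#' the predominance of post-transcriptional regulation), and background
#' genes are significant at a low rate.
#'
#' @param truth ground truth from [simulate_lfq()].
#' @param seed integer seed (required).
#' @param frac_sig_tracked probability that an aggregate-tracking protein's
#'   transcript is significant.
#' @param frac_sig_background significance rate among other genes.
#' @return tibble: `gene_symbol`, `log2fc`, `adjusted_p`, `significant`.
#' @export
simulate_deg_table <- function(truth, seed, frac_sig_tracked = 0.03,
                               frac_sig_background = 0.01) {
  assert_seed(seed)
  n <- truth$params$n_proteins
  syms <- mouse_case(sprintf("gene%04d", seq_len(n)))
  tracked_ids <- truth$classes |>
    filter(.data$class %in% c("abeta_corr", "abeta_acorr", "candidate")) |>
    pull("protein_id") |>
    unique()
  tracked <- syms[match(tracked_ids, sprintf("P%04d", seq_len(n)))]
  with_substream(seed, "deg", {
    sig <- ifelse(syms %in% tracked,
                  runif(n) < frac_sig_tracked,
                  runif(n) < frac_sig_background)
    tibble(
      gene_symbol = syms,
      log2fc = rnorm(n, 0, 0.4) + ifelse(sig, sample(c(-1, 1), n,
                                                     replace = TRUE), 0),
      adjusted_p = ifelse(sig, runif(n, 0, 0.049), runif(n, 0.05, 1)),
      significant = sig
    )
  })
}

#' Synthetic cerebrospinal-fluid analyte table
#'
#' Two-group (AD vs control) log-normal analyte concentrations plus
#' auxiliary biomarker columns with planted Spearman rank correlations to
#' the analyte, generated through a Gaussian copula on the pooled analyte
#' normal scores. Defaults give a standardized group difference whose
#' theoretical ROC AUC is `pnorm(d / sqrt(2))`.
#'
#' @param seed integer seed (required).
#' @param n_case,n_control subjects per group (>= 2 each).
#' @param group_labels labels for cases and controls.
#' @param meanlog_control,d log-scale control mean and standardized case
#'   shift (case meanlog = control + `d * sdlog`).
#' @param sdlog log-scale sd (common).
#' @param marker_spearman named numeric of planted Spearman correlations
#'   between the analyte and each auxiliary biomarker column.
#' @return tibble: `subject_id`, `group`, `analyte`, one column per marker.
#' @export
simulate_csf <- function(seed,
                         n_case = 41L, n_control = 41L,
                         group_labels = c("AD", "control"),
                         meanlog_control = log(500),
                         d = 0.87, sdlog = 0.5,
                         marker_spearman = c(abeta42 = -0.25, abeta40 = 0,
                                             ratio42_40 = -0.4,
                                             t_tau = 0.25, p_tau = 0.4)) {
  assert_seed(seed)
  if (n_case < 2L || n_control < 2L) abort("need >= 2 subjects per group")
  if (any(abs(marker_spearman) >= 1)) {
    abort("planted Spearman correlations must lie in (-1, 1)")
  }
  with_substream(seed, "csf", {
    ntot <- n_case + n_control
    grp <- rep(group_labels, c(n_case, n_control))
    mu <- ifelse(grp == group_labels[1], meanlog_control + d * sdlog,
                 meanlog_control)
    loga <- rnorm(ntot, mu, sdlog)
    z <- as.numeric(scale(loga))
    markers <- purrr::imap_dfc(as.list(marker_spearman), function(s, nm) {
      rho <- 2 * sin(pi * s / 6)   # Spearman -> latent Pearson
      zj <- rho * z + sqrt(1 - rho^2) * rnorm(ntot)
      tibble("{nm}" := exp(log(300) + 0.4 * zj))
    })
    bind_cols(
      tibble(subject_id = sprintf("S%03d", seq_len(ntot)), group = grp,
             analyte = exp(loga)),
      markers
    )
  })
}

#' Ready-made generator presets
#'
#' * `"5xfad"`: the default emulated study conditions (full design, 1500
#'   proteins, realistic noise and missingness).
#' * `"smoke"`: 200 proteins, same design; for quick end-to-end runs.
#' * `"funnel-demo"`: 600 proteins with low biological/technical noise and a
#'   uniquely lysosome-annotated strong candidate; the engineered
#'   construction on which the selection funnel provably converges to the
#'   planted candidate.
#'
#' @param name preset name.
#' @return list with `design` and `params`.
#' @export
fad_preset <- function(name = c("5xfad", "smoke", "funnel-demo")) {
  name <- match.arg(name)
  switch(
    name,
    "5xfad" = list(design = fad_design(), params = fad_params()),
    "smoke" = list(design = fad_design(),
                   params = fad_params(n_proteins = 200L,
                                       n_abeta_corr = c(cortex = 6,
                                                        hippocampus = 10),
                                       n_abeta_acorr = c(cortex = 4,
                                                         hippocampus = 6))),
    "funnel-demo" = list(
      design = fad_design(),
      params = fad_params(n_proteins = 600L, animal_sd = 0.02,
                          tech_sd = 0.02, batch_shift_sd = 0.1,
                          batch_scale_sd = 0.02, missing_midpoint = 5,
                          n_abeta_corr = c(cortex = 10, hippocampus = 20),
                          n_abeta_acorr = c(cortex = 6, hippocampus = 12))
    )
  )
}
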