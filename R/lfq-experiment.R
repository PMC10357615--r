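#' LFQ intensity experiment container
#'
#' Bundles a proteins x samples matrix of log10 label-free quantification
#' (LFQ) intensities with per-protein and per-sample annotation. Missing
#' intensities are `NA` (never zero, never imputed). Sample metadata carries
#' the study design: tissue, age (months), genotype, animal, technical
#' replicate and batch.
#'
#' @param values numeric matrix, proteins in rows, samples in columns;
#'   `NA` marks a missing (non-detected) intensity. Row names are protein
#'   ids, column names sample ids.
#' @param proteins tibble with one row per protein: `protein_id` (unique;
#'   semicolon-joined accessions allowed) and `gene_symbol`.
#' @param samples tibble with one row per sample: `sample_id`, `tissue`,
#'   `age`, `genotype`, `animal_id`, `tech_rep`, `batch`.
#' @return an object of class `lfq_experiment`.
#' @export
lfq_experiment <- function(values, proteins, samples) {
  values <- as.matrix(values)
  proteins <- as_tibble(proteins)
  samples <- as_tibble(samples)
  stopifnot(
    nrow(values) == nrow(proteins),
    ncol(values) == nrow(samples),
    all(c("protein_id") %in% names(proteins)),
    all(c("sample_id", "tissue", "age", "genotype", "animal_id",
          "tech_rep", "batch") %in% names(samples))
  )
  if (anyDuplicated(proteins$protein_id)) {
    abort("protein ids must be unique")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample ids must be unique")
  }
  if (any(is.infinite(values))) {
    abort("intensities must be finite or NA")
  }
  if (!"gene_symbol" %in% names(proteins)) proteins$gene_symbol <- NA_character_
  rownames(values) <- proteins$protein_id
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, proteins = proteins, samples = samples),
    class = "lfq_experiment"
  )
}

#' @export
print.lfq_experiment <- function(x, ...) {
  cat("<lfq_experiment> ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  tissues: ", paste(unique(x$samples$tissue), collapse = ", "), "\n",
      sep = "")
  cat("  ages (months): ", paste(sort(unique(x$samples$age)), collapse = ", "),
      "; genotypes: ", paste(unique(x$samples$genotype), collapse = ", "),
      "\n", sep = "")
  cat("  missing: ",
      sprintf("%.1f%%", 100 * mean(is.na(x$values))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.lfq_experiment <- function(x) dim(x$values)

#' Subset an LFQ experiment by proteins and/or samples
#'
#' @param x an [lfq_experiment()].
#' @param i protein index (logical, integer or protein-id character vector).
#' @param j sample index (logical, integer or sample-id character vector).
#' @param ... unused.
#' @export
`[.lfq_experiment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$proteins$protein_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  lfq_experiment(
    x$values[i, j, drop = FALSE],
    x$proteins[i, , drop = FALSE],
    x$samples[j, , drop = FALSE]
  )
}

#' Tidy an LFQ experiment into long format
#'
#' One row per (protein, sample) observation, joined with sample metadata.
#' Missing intensities appear as `NA` in `log10_intensity`.
#'
#' @param x an [lfq_experiment()].
#' @param ... unused.
#' @method tidy lfq_experiment
#' @export
tidy.lfq_experiment <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id",
                        values_to = "log10_intensity")
  long |>
    left_join(x$samples, by = "sample_id") |>
    left_join(x$proteins[c("protein_id", "gene_symbol")], by = "protein_id")
}

#' @method as_tibble lfq_experiment
#' @export
as_tibble.lfq_experiment <- function(x, ...) tidy.lfq_experiment(x, ...)

#' @method glance lfq_experiment
#' @export
glance.lfq_experiment <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$values),
    n_samples = ncol(x$values),
    n_conditions = nrow(distinct(x$samples, .data$tissue, .data$age,
                                 .data$genotype)),
    missing_fraction = mean(is.na(x$values))
  )
}

# Condition id per sample, in sample order.
sample_conditions <- function(x) {
  condition_id(x$samples$tissue, x$samples$age, x$samples$genotype)
}

#' Collapse technical replicates by within-animal means
#'
#' Cheaper alternative to modelling the within-animal correlation explicitly:
#' average the technical replicates of each animal (per protein, ignoring
#' missing values) and return one column per animal. This changes the
#' effective error model and is provided as a documented deviation from the
#' consensus-correlation route.
#'
#' @param x an [lfq_experiment()].
#' @return an [lfq_experiment()] with one sample per animal (`tech_rep = 1`).
#' @export
collapse_tech_reps <- function(x) {
  key <- paste(x$samples$animal_id, x$samples$tissue, sep = "@")
  groups <- split(seq_len(ncol(x$values)), key)
  vals <- vapply(groups, function(j) {
    rowMeans(x$values[, j, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x$values)))
  vals[is.nan(vals)] <- NA_real_
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- x$samples[first, , drop = FALSE]
  meta$tech_rep <- 1L
  meta$sample_id <- paste0(meta$animal_id, "_", meta$tissue, "_m")
  lfq_experiment(vals, x$proteins, meta)
}
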