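# Readers and writers for every tabular artifact. Derived tables are CSV
# with a one-line "# proteofunnel <version>" comment header; the protein
# group table stays in its MaxQuant-style TSV dialect (no comment line).

pf_header <- function() {
  sprintf("# proteofunnel %s",
          as.character(utils::packageVersion("proteofunnel")))
}

write_pf_csv <- function(x, path) {
  writeLines(pf_header(), path)
  readr::write_csv(mutate(x, across(where(is.numeric),
                                    ~ as.numeric(format(.x, digits = 15)))),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_pf_csv <- function(path, col_types = NULL) {
  readr::read_csv(path, comment = "#", col_types = col_types %||%
                    readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}

#' Read a MaxQuant-style protein-group table
#'
#' Expects a TSV with a `Protein IDs` column and one or more
#' `LFQ intensity <sample>` columns. Rows flagged `Reverse` (decoys),
#' `Potential contaminant` or `Only identified by site` are dropped and
#' counted. Zero LFQ intensities denote non-detection and become missing
#' (`NA`), never `-Inf` and never an imputed value.
#'
#' @param path TSV file path.
#' @param sample_meta optional sample metadata tibble (see
#'   [read_sample_meta()]); must cover exactly the LFQ sample columns.
#' @param linear_to_log if `TRUE` (default) intensities are log10-transformed.
#' @return an [lfq_experiment()]; the attribute `drop_log` records how many
#'   rows each flag filter removed.
#' @export
read_protein_groups <- function(path, sample_meta = NULL,
                                linear_to_log = TRUE) {
  tbl <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  if (!"Protein IDs" %in% names(tbl)) {
    abort("schema error: mandatory column `Protein IDs` is missing")
  }
  lfq_cols <- grep("^LFQ intensity ", names(tbl), value = TRUE)
  if (!length(lfq_cols)) {
    abort("schema error: no `LFQ intensity <sample>` column found")
  }
  sample_ids <- sub("^LFQ intensity ", "", lfq_cols)
  if (anyDuplicated(sample_ids)) abort("duplicate sample names in header")

  drop_log <- c()
  for (flag in c("Reverse", "Potential contaminant",
                 "Only identified by site")) {
    if (flag %in% names(tbl)) {
      hit <- !is.na(tbl[[flag]]) & tbl[[flag]] == "+"
      drop_log[flag] <- sum(hit)
      tbl <- tbl[!hit, , drop = FALSE]
    }
  }

  vals <- as.matrix(tbl[lfq_cols])
  if (any(vals < 0, na.rm = TRUE)) {
    abort("negative raw LFQ intensity encountered")
  }
  vals[vals == 0] <- NA_real_
  if (linear_to_log) vals <- log10(vals)
  colnames(vals) <- sample_ids

  if (is.null(sample_meta)) {
    sample_meta <- tibble(
      sample_id = sample_ids, tissue = NA_character_, age = NA_real_,
      genotype = NA_character_, animal_id = NA_character_,
      tech_rep = NA_integer_, batch = NA_character_
    )
  } else {
    if (!setequal(sample_meta$sample_id, sample_ids)) {
      abort("sample metadata does not match the LFQ sample columns")
    }
    sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), ]
  }

  proteins <- tibble(
    protein_id = tbl[["Protein IDs"]],
    gene_symbol = if ("Gene names" %in% names(tbl)) {
      tbl[["Gene names"]]
    } else NA_character_
  )
  out <- lfq_experiment(vals, proteins, sample_meta)
  attr(out, "drop_log") <- drop_log
  out
}

#' Write a protein-group table in the MaxQuant-style dialect
#'
#' Inverse of [read_protein_groups()]: emits `Protein IDs`, `Gene names` and
#' one `LFQ intensity <sample>` column per sample. Missing values are
#' written as 0 on the linear scale (the dialect's non-detection code).
#'
#' @param lfq an [lfq_experiment()] with log10 intensities.
#' @param path output TSV path.
#' @export
write_protein_groups <- function(lfq, path) {
  vals <- 10^lfq$values
  vals[is.na(vals)] <- 0
  out <- bind_cols(
    tibble(`Protein IDs` = lfq$proteins$protein_id,
           `Gene names` = lfq$proteins$gene_symbol),
    as_tibble(vals, .name_repair = ~ paste0("LFQ intensity ",
                                            lfq$samples$sample_id))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' @param path CSV with columns `sample_id`, `tissue`, `age`, `genotype`,
#'   `animal_id`, `tech_rep`, `batch`.
#' @param tissues,ages,genotypes allowed label vocabularies; any label
#'   outside them is rejected with a message listing the allowed values.
#' @return tibble of sample metadata.
#' @export
read_sample_meta <- function(path, tissues = c("cortex", "hippocampus"),
                             ages = c(2, 5, 8),
                             genotypes = c("WT", "TG")) {
  meta <- read_pf_csv(path)
  need <- c("sample_id", "tissue", "age", "genotype", "animal_id",
            "tech_rep", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("schema error: missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  check_vocab <- function(x, allowed, what) {
    bad <- setdiff(unique(x), allowed)
    if (length(bad)) {
      abort(sprintf("unknown %s label(s) %s; allowed: %s", what,
                    paste(bad, collapse = ", "),
                    paste(allowed, collapse = ", ")))
    }
  }
  check_vocab(meta$tissue, tissues, "tissue")
  check_vocab(meta$age, ages, "age")
  check_vocab(meta$genotype, genotypes, "genotype")
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids")
  meta
}

#' @rdname read_sample_meta
#' @param meta sample metadata tibble.
#' @export
write_sample_meta <- function(meta, path) write_pf_csv(meta, path)

#' Write / read a differential-abundance result table
#'
#' Round-trip identity holds to at least 12 significant digits.
#'
#' @param results DiffResult tibble (see [fit_contrasts()]).
#' @param path CSV path.
#' @export
write_diff_table <- function(results, path) write_pf_csv(results, path)

#' @rdname write_diff_table
#' @export
read_diff_table <- function(path) {
  tbl <- read_pf_csv(path)
  if (any(tbl$p_value < 0 | tbl$p_value > 1, na.rm = TRUE) ||
      any(tbl$fdr < 0 | tbl$fdr > 1, na.rm = TRUE)) {
    abort("p_value / fdr outside [0, 1]")
  }
  tbl
}

#' Read human differential-abundance tables
#'
#' @param paths named character vector of CSV paths; names are dataset ids
#'   from `datasets`.
#' @param datasets closed vocabulary of dataset ids.
#' @return tibble: `dataset_id`, `gene_symbol`, `effect`, `significant`.
#' @export
read_human_tables <- function(paths,
                              datasets = c("D22", "J20", "J22", "J22_Asym")) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be named by dataset id")
  }
  bad <- setdiff(names(paths), datasets)
  if (length(bad)) {
    abort(sprintf("unknown dataset id(s) %s; allowed: %s",
                  paste(bad, collapse = ", "),
                  paste(datasets, collapse = ", ")))
  }
  purrr::imap_dfr(paths, function(p, ds) {
    tbl <- read_pf_csv(p)
    need <- c("gene_symbol", "effect", "significant")
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      abort(paste0("schema error in ", ds, ": missing ",
                   paste(miss, collapse = ", ")))
    }
    if (any(is.na(tbl$gene_symbol) | !nzchar(tbl$gene_symbol))) {
      abort(paste0("empty gene symbol in ", ds))
    }
    tibble(dataset_id = ds, gene_symbol = toupper(tbl$gene_symbol),
           effect = tbl$effect, significant = as.logical(tbl$significant))
  })
}

#' @rdname read_human_tables
#' @param tables human tables tibble; written one file per dataset id into
#'   `dir`, returning the named path vector.
#' @param dir output directory.
#' @export
write_human_tables <- function(tables, dir) {
  ids <- unique(tables$dataset_id)
  paths <- setNames(file.path(dir, paste0("human_", ids, ".csv")), ids)
  for (ds in ids) {
    write_pf_csv(filter(tables, .data$dataset_id == ds) |>
                   select(-"dataset_id"), paths[[ds]])
  }
  paths
}

#' Read / write a mouse-human ortholog map
#'
#' TSV with columns `mouse_symbol`, `human_symbol`, `source_direction`
#' (`m2h` or `h2m`). Duplicated triples are rejected with their row number.
#'
#' @param path TSV path.
#' @export
read_ortholog_map <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  need <- c("mouse_symbol", "human_symbol", "source_direction")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("schema error: missing ", paste(miss, collapse = ", ")))
  }
  bad_dir <- setdiff(unique(tbl$source_direction), c("m2h", "h2m"))
  if (length(bad_dir)) {
    abort("source_direction must be `m2h` or `h2m`")
  }
  dup <- which(duplicated(tbl))
  if (length(dup)) {
    abort(sprintf("duplicated ortholog triple at row %d", dup[1]))
  }
  tbl
}

#' @rdname read_ortholog_map
#' @param map ortholog map tibble.
#' @export
write_ortholog_map <- function(map, path) {
  writeLines(pf_header(), path)
  readr::write_tsv(map, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a differential-transcript (DEG) table
#'
#' @param path CSV with `gene_symbol`, `log2fc`, `adjusted_p`,
#'   `significant`.
#' @export
read_deg_table <- function(path) {
  tbl <- read_pf_csv(path)
  need <- c("gene_symbol", "log2fc", "adjusted_p", "significant")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("schema error: missing ", paste(miss, collapse = ", ")))
  }
  if (any(tbl$adjusted_p < 0 | tbl$adjusted_p > 1, na.rm = TRUE)) {
    abort("adjusted_p outside [0, 1]")
  }
  tbl
}

#' @rdname read_deg_table
#' @param deg DEG tibble.
#' @export
write_deg_table <- function(deg, path) write_pf_csv(deg, path)

#' Read / write amyloid-aggregate trajectory tables
#' @param path CSV path.
#' @export
read_trajectories <- function(path) {
  tbl <- read_pf_csv(path)
  need <- c("tissue", "readout", "age", "value")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("schema error: missing ", paste(miss, collapse = ", ")))
  }
  tbl
}

#' @rdname read_trajectories
#' @param traj trajectory tibble.
#' @export
write_trajectories <- function(traj, path) write_pf_csv(traj, path)

#' Read / write a CSF analyte table
#' @param path CSV path.
#' @param groups allowed group labels.
#' @export
read_csf_table <- function(path, groups = c("AD", "control", "HD",
                                            "control_HD")) {
  tbl <- read_pf_csv(path)
  need <- c("subject_id", "group", "analyte")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("schema error: missing ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$group), groups)
  if (length(bad)) {
    abort(sprintf("unknown group label(s) %s; allowed: %s",
                  paste(bad, collapse = ", "),
                  paste(groups, collapse = ", ")))
  }
  if (any(tbl$analyte < 0, na.rm = TRUE)) abort("negative concentration")
  tbl
}

#' @rdname read_csf_table
#' @param csf CSF tibble.
#' @export
write_csf_table <- function(csf, path) write_pf_csv(csf, path)
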