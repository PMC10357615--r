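# Reliability filtering: the no-imputation strategy. A protein is reliably
# measured in a condition when strictly fewer than half of that condition's
# samples (technical replicates count as samples) are missing; "half or
# more missing" marks it unreliable there.

#' Per-condition reliability flags
#'
#' For every (protein, condition) pair, counts missing values among the
#' condition's samples and flags the pair reliable when
#' `n_missing < n_samples / 2` (exact comparison, so 15-sample conditions
#' behave deterministically: 7 missing is reliable, 8 is not).
#'
#' @param lfq an [lfq_experiment()].
#' @return tibble: `protein_id`, `tissue`, `age`, `genotype`, `n_samples`,
#'   `n_missing`, `reliable`.
#' @export
reliability_flags <- function(lfq) {
  cond <- sample_conditions(lfq)
  groups <- split(seq_len(ncol(lfq$values)), cond)
  if (any(lengths(groups) == 0)) abort("empty condition")
  per_cond <- purrr::imap_dfr(groups, function(j, cid) {
    n_missing <- unname(rowSums(is.na(lfq$values[, j, drop = FALSE])))
    meta <- lfq$samples[j[1], ]
    tibble(
      protein_id = lfq$proteins$protein_id,
      tissue = meta$tissue, age = meta$age, genotype = meta$genotype,
      n_samples = length(j), n_missing = n_missing,
      reliable = n_missing < length(j) / 2
    )
  })
  per_cond
}

new_filter_report <- function(stage, proteins_in, proteins_out, flags) {
  structure(
    list(summary = tibble(stage = stage, proteins_in = proteins_in,
                          proteins_out = proteins_out),
         flags = flags),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) x$summary

#' Tissue-level reliability filter
#'
#' Restricts the experiment to one tissue and drops proteins that are
#' unreliable there. Under the default reading (`"all-conditions"`) a
#' protein is excluded only when it is unreliable in *every* condition of
#' the tissue; the stricter alternative reading (`"any-condition"`) excludes
#' a protein that is unreliable in any one condition.
#'
#' @param lfq an [lfq_experiment()].
#' @param tissue tissue label to keep.
#' @param reading which reading of the exclusion rule to apply.
#' @param flags optional precomputed [reliability_flags()].
#' @return list with `lfq` (filtered, tissue-only) and `report`
#'   (a `filter_report` retaining the per-condition flags for audit).
#' @export
filter_tissue <- function(lfq, tissue,
                          reading = c("all-conditions", "any-condition"),
                          flags = NULL) {
  reading <- match.arg(reading)
  keep_samples <- lfq$samples$tissue == tissue
  if (!any(keep_samples)) abort(paste0("no samples for tissue ", tissue))
  sub <- lfq[, which(keep_samples)]
  flags <- flags %||% reliability_flags(sub)
  flags <- filter(flags, .data$tissue == !!tissue)
  per_protein <- flags |>
    group_by(.data$protein_id) |>
    summarise(keep = if (reading == "all-conditions") {
      any(.data$reliable)
    } else {
      all(.data$reliable)
    }, .groups = "drop")
  keep_ids <- per_protein$protein_id[per_protein$keep]
  out <- sub[match(keep_ids, sub$proteins$protein_id), ]
  report <- new_filter_report(
    paste0("filter_tissue:", tissue, ":", reading),
    nrow(sub$values), length(keep_ids), flags
  )
  list(lfq = out, report = report)
}

#' Analysis set for a pairwise (one tissue, one age) comparison
#'
#' Proteins reliably measured in both genotypes at the given tissue and age.
#'
#' @param lfq an [lfq_experiment()].
#' @param tissue,age condition selectors.
#' @param flags optional precomputed [reliability_flags()].
#' @return character vector of protein ids.
#' @export
pairwise_analysis_set <- function(lfq, tissue, age, flags = NULL) {
  flags <- flags %||% reliability_flags(lfq)
  sub <- filter(flags, .data$tissue == !!tissue, .data$age == !!age)
  if (length(unique(sub$genotype)) < 2L) {
    abort(sprintf("both genotypes required at (%s, %s months)", tissue, age))
  }
  sub |>
    group_by(.data$protein_id) |>
    summarise(ok = all(.data$reliable) & dplyr::n() >= 2L,
              .groups = "drop") |>
    filter(.data$ok) |>
    pull("protein_id")
}

# Match protein groups of two tissue datasets through shared accessions.
# Protein-group ids are semicolon-joined accession lists; two groups are
# linked when they share at least one accession. Connected components that
# are not one-to-one are ambiguous.
reconcile_protein_groups <- function(ids_a, ids_b,
                                     keep_one_to_many = FALSE) {
  empty <- list(pairs = tibble(id_a = character(), id_b = character()),
                dropped = tibble(id_a = character(), id_b = character(),
                                 reason = character()))
  if (!length(ids_a) || !length(ids_b)) return(empty)
  split_acc <- function(ids) {
    setNames(strsplit(ids, ";", fixed = TRUE), ids)
  }
  acc_a <- split_acc(ids_a)
  acc_b <- split_acc(ids_b)
  lookup_b <- tibble(
    id_b = rep(ids_b, lengths(acc_b)),
    acc = unlist(acc_b, use.names = FALSE)
  )
  edges <- tibble(
    id_a = rep(ids_a, lengths(acc_a)),
    acc = unlist(acc_a, use.names = FALSE)
  ) |>
    inner_join(lookup_b, by = "acc", relationship = "many-to-many") |>
    distinct(.data$id_a, .data$id_b)
  if (!nrow(edges)) {
    return(list(pairs = tibble(id_a = character(), id_b = character()),
                dropped = tibble(id_a = character(), id_b = character(),
                                 reason = character())))
  }
  g <- igraph::graph_from_data_frame(
    tibble(from = paste0("a|", edges$id_a), to = paste0("b|", edges$id_b)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  edges$component <- comp[paste0("a|", edges$id_a)]
  sizes <- edges |>
    group_by(.data$component) |>
    summarise(n_a = dplyr::n_distinct(.data$id_a),
              n_b = dplyr::n_distinct(.data$id_b), .groups = "drop")
  edges <- left_join(edges, sizes, by = "component")
  ok <- edges$n_a == 1L & edges$n_b == 1L
  if (keep_one_to_many) {
    ok <- ok | (edges$n_a == 1L) != (edges$n_b == 1L)
  }
  list(
    pairs = edges[ok, c("id_a", "id_b")],
    dropped = edges[!ok, ] |>
      mutate(reason = ifelse(.data$n_a > 1 & .data$n_b > 1,
                             "many-to-many", "one-to-many")) |>
      select("id_a", "id_b", "reason")
  )
}

#' Full-model analysis set across tissues
#'
#' Per tissue, keeps proteins reliable in all conditions (both genotypes at
#' every age); then intersects the two tissue sets after reconciling
#' protein-group identifiers through shared accessions. Ambiguous
#' many-to-many identifier components are always discarded; one-to-many
#' components are discarded by default.
#'
#' @param lfq_a,lfq_b single-tissue experiments (e.g. cortex and
#'   hippocampus after [filter_tissue()]).
#' @param keep_one_to_many retain one-to-many identifier components.
#' @return list: `pairs` (tibble `id_a`, `id_b` of matched protein groups in
#'   the final set), `set_a`, `set_b` (per-tissue all-condition-reliable
#'   sets before intersection), `dropped` (ambiguous components with
#'   reasons) and `report`.
#' @export
full_model_set <- function(lfq_a, lfq_b, keep_one_to_many = FALSE) {
  all_reliable <- function(lfq) {
    reliability_flags(lfq) |>
      group_by(.data$protein_id) |>
      summarise(ok = all(.data$reliable), .groups = "drop") |>
      filter(.data$ok) |>
      pull("protein_id")
  }
  set_a <- all_reliable(lfq_a)
  set_b <- all_reliable(lfq_b)
  rec <- reconcile_protein_groups(set_a, set_b, keep_one_to_many)
  report <- new_filter_report(
    "full_model_set",
    length(union(lfq_a$proteins$protein_id, lfq_b$proteins$protein_id)),
    nrow(rec$pairs),
    NULL
  )
  report$summary <- bind_rows(
    report$summary,
    tibble(stage = c("all_conditions_a", "all_conditions_b",
                     "dropped_ambiguous"),
           proteins_in = c(nrow(lfq_a$values), nrow(lfq_b$values),
                           nrow(rec$pairs) + nrow(distinct(rec$dropped))),
           proteins_out = c(length(set_a), length(set_b), nrow(rec$pairs)))
  )
  list(pairs = rec$pairs, set_a = set_a, set_b = set_b,
       dropped = rec$dropped, report = report)
}
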