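# The biomarker candidate-selection funnel: an ordered sequence of
# conjunctive filters over the hippocampus proteome, each stage recording
# its surviving set so the selection is fully auditable.

#' Per-age top-k effect-size ranking
#'
#' Per age, ranks a tissue's differential results by |moderated statistic|
#' (default) or |log fold-change| descending and returns the top-k set,
#' plus the proteins ranked top-k at every age. Ties at rank k break by
#' the other criterion, then lexicographically.
#'
#' @param dep_table DiffResult tibble covering the tissue's per-age
#'   contrasts (`contrast_id` must encode the age as `Age<k>` or `A<k>`).
#' @param k rank cutoff.
#' @param rank_by `"stat"` (moderated statistic magnitude) or `"logfc"`.
#' @return list: `per_age` (named list of top-k id vectors) and
#'   `intersection`.
#' @export
top_k_effect_rank <- function(dep_table, k = 25L,
                              rank_by = c("stat", "logfc")) {
  rank_by <- match.arg(rank_by)
  ages <- unique(dep_table$contrast_id)
  per_age <- purrr::map(setNames(ages, ages), function(a) {
    sub <- filter(dep_table, .data$contrast_id == a)
    ord <- if (rank_by == "stat") {
      order(-abs(sub$stat), -abs(sub$logfc), sub$protein_id)
    } else {
      order(-abs(sub$logfc), -abs(sub$stat), sub$protein_id)
    }
    head(sub$protein_id[ord], k)
  })
  list(per_age = per_age, intersection = purrr::reduce(per_age, intersect))
}

#' Run the candidate-selection funnel
#'
#' Six conjunctive stages over the hippocampus data:
#' S1 proteins reliably present; S2 significant DEPs (FDR < threshold at
#' any age); S3 resolved ortholog significant in >= 1 human dataset; S4
#' concordant direction (in the concordance set); S5 aggregate-correlated
#' or anticorrelated AND top-k effect rank at all ages; S6 annotation term
#' filter. An empty stage output simply propagates (not an error).
#'
#' @param present_set character: the reliability-filtered universe (S1).
#' @param dep_table DiffResult tibble with the tissue's per-age contrasts.
#' @param human tibble of human tables (`dataset_id`, `gene_symbol`,
#'   `effect`, `significant`).
#' @param resolution an [resolve_orthologs()] result.
#' @param cset concordance tibble from [concordance()].
#' @param classification tibble from [classify_abeta()] (same tissue).
#' @param annotations tibble `gene_symbol`, `term`.
#' @param gene_map tibble `protein_id`, `gene_symbol` translating ids.
#' @param terms annotation terms accepted at S6.
#' @param k top-k cutoff for S5.
#' @param rank_by ranking criterion for S5 (see [top_k_effect_rank()]).
#' @return object of class `funnel_report`: `stages` tibble (`stage`,
#'   `description`, `n`) and `sets` (list of surviving protein-id sets).
#' @export
run_funnel <- function(present_set, dep_table, human, resolution, cset,
                       classification, annotations, gene_map,
                       terms = c("lysosome", "endo-lysosomal"),
                       k = 25L, rank_by = c("stat", "logfc")) {
  rank_by <- match.arg(rank_by)
  sym <- function(ids) gene_map$gene_symbol[match(ids, gene_map$protein_id)]

  s1 <- unique(present_set)

  deps <- dep_table |> filter(.data$significant) |> pull("protein_id")
  s2 <- intersect(s1, unique(deps))

  human_sig <- human |> filter(.data$significant) |> pull("gene_symbol")
  hsym <- translate_mouse(sym(s2), resolution)
  s3 <- s2[!is.na(hsym) & hsym %in% human_sig]

  s4 <- s3[sym(s3) %in% cset$mouse_symbol]

  corr_ids <- classification |>
    filter(.data$class %in% c("corr", "acorr")) |>
    pull("protein_id")
  topk <- top_k_effect_rank(dep_table, k = k, rank_by = rank_by)
  s5 <- intersect(intersect(s4, corr_ids), topk$intersection)

  ann_sym <- annotations |>
    filter(.data$term %in% terms) |>
    pull("gene_symbol")
  s6 <- s5[sym(s5) %in% ann_sym]

  sets <- list(
    S1_present = s1, S2_significant = s2, S3_human_overlap = s3,
    S4_concordant = s4, S5_abeta_top_rank = s5, S6_annotation = s6
  )
  desc <- c(
    "reliably measured (present) proteins",
    "significant DEPs (any age, FDR < threshold)",
    "ortholog significant in >= 1 human dataset",
    "concordant direction in mouse and human",
    sprintf("aggregate-(anti)correlated and top-%d effect rank at all ages",
            k),
    sprintf("annotated with: %s", paste(terms, collapse = ", "))
  )
  structure(
    list(stages = tibble(stage = names(sets), description = desc,
                         n = unname(lengths(sets))),
         sets = sets,
         params = list(terms = terms, k = k, rank_by = rank_by)),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stages)
  invisible(x)
}

#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) x$stages

#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  tibble(n_stages = nrow(x$stages),
         n_start = x$stages$n[1],
         n_final = x$stages$n[nrow(x$stages)])
}

#' Serialize / deserialize a funnel report as JSON
#'
#' @param report a `funnel_report`.
#' @param path JSON file path.
#' @export
write_funnel_report <- function(report, path) {
  jsonlite::write_json(
    list(stages = report$stages, sets = report$sets,
         params = report$params),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_funnel_report
#' @export
read_funnel_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- purrr::map(x$sets, as.character)
  structure(
    list(stages = as_tibble(x$stages) |>
           mutate(n = as.integer(.data$n)),
         sets = sets,
         params = x$params),
    class = "funnel_report"
  )
}
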