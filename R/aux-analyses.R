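# Small self-contained side analyses: transcript-protein intersection,
# cell-type marker derivation and enrichment, and the wild-type
# expression-level split.

#' Intersect significant transcripts with aggregate-classified proteins
#'
#' Returns the genes significant at the transcript level that are also
#' aggregate-correlated or anticorrelated at the protein level, and that
#' set's fraction of the classified-protein universe.
#'
#' @param deg DEG tibble (`gene_symbol`, `significant`).
#' @param classification tibble from [classify_abeta()] with a
#'   `gene_symbol` column attached (same species, no ortholog step).
#' @return list: `genes` (character), `fraction` (of the corr/acorr
#'   universe; `NA` with a warning when that universe is empty),
#'   `n_universe`.
#' @export
intersect_deg_dep <- function(deg, classification) {
  prot_universe <- classification |>
    filter(.data$class %in% c("corr", "acorr")) |>
    pull("gene_symbol") |>
    unique()
  deg_sig <- unique(deg$gene_symbol[deg$significant])
  genes <- intersect(deg_sig, prot_universe)
  fraction <- if (!length(prot_universe)) {
    warn("empty classified-protein universe: fraction undefined")
    NA_real_
  } else {
    length(genes) / length(prot_universe)
  }
  list(genes = sort(genes), fraction = fraction,
       n_universe = length(prot_universe))
}

#' Derive cell-type marker genes from mean expression profiles
#'
#' Gene g is a marker for cell type c when its expression there is at
#' least `fold` times the mean of the other cell types. A gene meeting the
#' criterion for two cell types (possible only with zeros) is assigned to
#' none and recorded. Scale-invariant by construction.
#'
#' @param expression tibble: `gene_symbol` plus one numeric column per
#'   cell type (non-negative means).
#' @param fold fold-change threshold.
#' @return tibble `gene_symbol`, `cell_type`; attribute `ambiguous` lists
#'   genes matching several types.
#' @export
derive_markers <- function(expression, fold = 10) {
  types <- setdiff(names(expression), "gene_symbol")
  if (length(types) < 2L) abort("need >= 2 cell types")
  M <- as.matrix(expression[types])
  if (any(M < 0, na.rm = TRUE)) abort("expressions must be non-negative")
  hits <- matrix(vapply(seq_along(types), function(i) {
    others <- rowMeans(M[, -i, drop = FALSE])
    M[, i] >= fold * others
  }, logical(nrow(M))), nrow = nrow(M))
  n_hits <- rowSums(hits)
  ambiguous <- expression$gene_symbol[n_hits > 1L]
  ok <- n_hits == 1L
  out <- tibble(
    gene_symbol = expression$gene_symbol[ok],
    cell_type = types[apply(hits[ok, , drop = FALSE], 1, which)]
  )
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Cell-type marker enrichment among DEPs
#'
#' Per cell type: the overlap count between the DEP set and that type's
#' markers, with a one-sided hypergeometric enrichment p, BH-adjusted
#' across cell types.
#'
#' @param dep_set character gene symbols (must be a subset of `universe`).
#' @param markers tibble from [derive_markers()].
#' @param universe character: all analyzed gene symbols.
#' @return tibble: `cell_type`, `n_markers`, `n_overlap`, `p`, `fdr`.
#' @export
marker_enrichment <- function(dep_set, markers, universe) {
  if (!all(dep_set %in% universe)) {
    abort("dep_set must be a subset of the universe")
  }
  types <- sort(unique(markers$cell_type))
  markers <- filter(markers, .data$gene_symbol %in% universe)
  res <- purrr::map_dfr(types, function(ct) {
    mk <- markers$gene_symbol[markers$cell_type == ct]
    q <- length(intersect(dep_set, mk))
    p <- phyper(q - 1, length(mk), length(universe) - length(mk),
                length(dep_set), lower.tail = FALSE)
    tibble(cell_type = ct, n_markers = length(mk), n_overlap = q, p = p)
  })
  if (!nrow(res)) {
    return(tibble(cell_type = character(), n_markers = integer(),
                  n_overlap = integer(), p = numeric(), fdr = numeric()))
  }
  res$fdr <- benjamini_hochberg(res$p)
  res
}

#' Wild-type expression split vs differential-expression status
#'
#' Ranks proteins by wild-type mean expression, omits a central band
#' (default: the middle third, giving low / medium / high groups with
#' medium dropped), and tests whether DEP status associates with the
#' low/high split: 2x2 table, odds ratio (Haldane 0.5 correction when a
#' cell is empty) and two-sided Fisher p.
#'
#' @param wt_expression tibble: `protein_id`, `wt_mean` (per-protein
#'   wild-type mean log10 intensity).
#' @param dep_flags tibble: `protein_id`, `significant`.
#' @param omit_fraction width of the omitted central band in (0, 1); 0
#'   gives a pure median split.
#' @return list: `table` (2x2 matrix), `odds_ratio`, `p`, `degenerate`
#'   flag (all or no DEPs).
#' @export
wt_median_split <- function(wt_expression, dep_flags, omit_fraction = 1 / 3) {
  joined <- inner_join(wt_expression, dep_flags, by = "protein_id")
  if (nrow(joined) < 4L) abort("need >= 4 proteins")
  if (omit_fraction < 0 || omit_fraction >= 1) {
    abort("omit_fraction must lie in [0, 1)")
  }
  r <- rank(joined$wt_mean, ties.method = "first") / nrow(joined)
  lo <- (1 - omit_fraction) / 2
  hi <- 1 - lo
  grp <- case_when(r <= lo ~ "low", r > hi ~ "high", TRUE ~ NA_character_)
  keep <- !is.na(grp)
  tab <- table(
    expression = factor(grp[keep], levels = c("low", "high")),
    dep = factor(joined$significant[keep], levels = c(FALSE, TRUE),
                 labels = c("not_dep", "dep"))
  )
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) warn("degenerate split: odds ratio not identifiable")
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  odds_ratio <- (t2["high", "dep"] * t2["low", "not_dep"]) /
    (t2["high", "not_dep"] * t2["low", "dep"])
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(odds_ratio), p = p,
       degenerate = degenerate)
}
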