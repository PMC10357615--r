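# Mapping mouse results onto human Alzheimer proteome tables: ortholog
# resolution, overlap accounting, concordance, signatures and cross-study
# Spearman matrices. Only signs and ranks cross the species boundary;
# human effect sizes keep their native scales.

#' Resolve an ortholog map to one-to-one pairs
#'
#' Combines both translation directions into one bipartite symbol graph and
#' keeps only connected components that are exactly one mouse and one human
#' symbol. Many-to-many components are always dropped; one-to-many
#' components are dropped by default (`policy = "keep"` retains the pair
#' whose human symbol is the upper-cased mouse symbol, when present).
#'
#' @param map tibble from [read_ortholog_map()] (`mouse_symbol`,
#'   `human_symbol`, `source_direction`).
#' @param policy how to treat one-to-many components: `"drop"` or
#'   `"keep"` (best-named match).
#' @return list of class `ortholog_resolution`: `pairs` (tibble
#'   `mouse_symbol`, `human_symbol`), `dropped` (with `reason`).
#' @export
resolve_orthologs <- function(map, policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  edges <- distinct(map, .data$mouse_symbol, .data$human_symbol)
  if (!nrow(edges)) {
    warn("empty ortholog map: empty resolution")
    return(structure(list(pairs = tibble(mouse_symbol = character(),
                                         human_symbol = character()),
                          dropped = tibble(mouse_symbol = character(),
                                           human_symbol = character(),
                                           reason = character())),
                     class = "ortholog_resolution"))
  }
  g <- igraph::graph_from_data_frame(
    tibble(from = paste0("m|", edges$mouse_symbol),
           to = paste0("h|", edges$human_symbol)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  edges$component <- unname(comp[paste0("m|", edges$mouse_symbol)])
  sizes <- edges |>
    group_by(.data$component) |>
    summarise(n_mouse = dplyr::n_distinct(.data$mouse_symbol),
              n_human = dplyr::n_distinct(.data$human_symbol),
              .groups = "drop")
  edges <- left_join(edges, sizes, by = "component")
  one_one <- edges$n_mouse == 1L & edges$n_human == 1L
  keep <- one_one
  if (policy == "keep") {
    named <- edges$n_mouse == 1L & edges$n_human > 1L &
      toupper(edges$mouse_symbol) == edges$human_symbol
    keep <- keep | named
  }
  dropped <- edges[!keep, ] |>
    mutate(reason = case_when(
      .data$n_mouse > 1L & .data$n_human > 1L ~ "many-to-many",
      TRUE ~ "one-to-many"
    )) |>
    select("mouse_symbol", "human_symbol", "reason")
  structure(
    list(pairs = edges[keep, c("mouse_symbol", "human_symbol")] |>
           distinct() |>
           arrange(.data$mouse_symbol),
         dropped = dropped),
    class = "ortholog_resolution"
  )
}

#' @export
print.ortholog_resolution <- function(x, ...) {
  cat("<ortholog_resolution> ", nrow(x$pairs), " resolved pairs; ",
      nrow(x$dropped), " ambiguous edges dropped\n", sep = "")
  invisible(x)
}

#' @method tidy ortholog_resolution
#' @export
tidy.ortholog_resolution <- function(x, ...) x$pairs

translate_mouse <- function(symbols, resolution) {
  res <- resolution$pairs
  res$human_symbol[match(symbols, res$mouse_symbol)]
}

#' Overlap counts between mouse and human significant sets
#'
#' Mouse symbols are translated through the resolution first; per dataset
#' pair the intersection and set differences are counted, plus the
#' union-wide "significant in >= 1 mouse and >= 1 human set" count.
#'
#' @param mouse_sets named list of mouse gene-symbol sets.
#' @param human_sets named list of human gene-symbol sets.
#' @param resolution an [resolve_orthologs()] result.
#' @return list: `pairwise` tibble (`mouse_set`, `human_set`,
#'   `n_intersect`, `n_mouse_only`, `n_human_only`) and `n_union_overlap`.
#' @export
overlap_report <- function(mouse_sets, human_sets, resolution) {
  mouse_tr <- purrr::map(mouse_sets, function(s) {
    unique(na.omit(translate_mouse(s, resolution)))
  })
  pairwise <- purrr::imap_dfr(mouse_tr, function(ms, mn) {
    purrr::imap_dfr(human_sets, function(hs, hn) {
      tibble(mouse_set = mn, human_set = hn,
             n_intersect = length(intersect(ms, hs)),
             n_mouse_only = length(setdiff(ms, hs)),
             n_human_only = length(setdiff(hs, ms)))
    })
  })
  m_union <- unique(unlist(mouse_tr))
  h_union <- unique(unlist(human_sets))
  list(pairwise = pairwise,
       n_union_overlap = length(intersect(m_union, h_union)))
}

#' Concordant mouse-human protein set
#'
#' An ortholog-resolved protein enters the set when it is significant with
#' the same effect sign in at least one mouse dataset and at least one
#' human dataset (default rule `"any"`); `rule = "all"` demands sign
#' agreement in every dataset where the protein is significant. A protein
#' with significant pairs of both signs gets a conflict flag and takes the
#' direction of the largest-|effect| mouse dataset.
#'
#' @param mouse_diff tibble of mouse differential results with
#'   `gene_symbol`, `dataset_id`, `logfc`, `significant` (e.g. the H5, H8,
#'   C8 families bound together).
#' @param human tibble of human tables (`dataset_id`, `gene_symbol`,
#'   `effect`, `significant`).
#' @param resolution an [resolve_orthologs()] result.
#' @param rule `"any"` (>= 1 agreeing pair) or `"all"` (all significant
#'   datasets agree).
#' @return tibble of class rows: `mouse_symbol`, `human_symbol`,
#'   `direction` (`up` / `down`), `conflict`, `ranking` (max |mouse logfc|
#'   over significant mouse datasets), `mouse_datasets`, `human_datasets`.
#' @export
concordance <- function(mouse_diff, human, resolution,
                        rule = c("any", "all")) {
  rule <- match.arg(rule)
  m_sig <- mouse_diff |>
    filter(.data$significant) |>
    mutate(human_symbol = translate_mouse(.data$gene_symbol, resolution)) |>
    filter(!is.na(.data$human_symbol))
  h_sig <- filter(human, .data$significant)
  joined <- inner_join(
    m_sig |>
      select(mouse_symbol = "gene_symbol", "human_symbol",
             mouse_dataset = "dataset_id", "logfc"),
    h_sig |>
      select(human_symbol = "gene_symbol", human_dataset = "dataset_id",
             "effect"),
    by = "human_symbol", relationship = "many-to-many"
  ) |>
    mutate(agree = sign(.data$logfc) == sign(.data$effect))
  if (!nrow(joined)) {
    return(tibble(mouse_symbol = character(), human_symbol = character(),
                  direction = character(), conflict = logical(),
                  ranking = numeric(), mouse_datasets = character(),
                  human_datasets = character()))
  }
  per_protein <- joined |>
    group_by(.data$mouse_symbol, .data$human_symbol) |>
    summarise(
      any_agree = any(.data$agree),
      all_agree = all(.data$agree),
      conflict = any(.data$agree) && any(!.data$agree),
      direction = {
        top <- which.max(abs(.data$logfc))
        if (sign(.data$logfc[top]) > 0) "up" else "down"
      },
      ranking = max(abs(.data$logfc)),
      mouse_datasets = paste(sort(unique(
        .data$mouse_dataset[.data$agree])), collapse = ";"),
      human_datasets = paste(sort(unique(
        .data$human_dataset[.data$agree])), collapse = ";"),
      .groups = "drop"
    )
  kept <- if (rule == "any") {
    filter(per_protein, .data$any_agree)
  } else {
    filter(per_protein, .data$all_agree)
  }
  kept |>
    select("mouse_symbol", "human_symbol", "direction", "conflict",
           "ranking", "mouse_datasets", "human_datasets") |>
    arrange(.data$mouse_symbol)
}

#' Top-k up/down signatures from a concordance set
#'
#' `sig_plus` = the k concordantly upregulated proteins with the largest
#' ranking value (max |mouse log fold-change| over significant mouse
#' datasets), `sig_minus` = the same among downregulated ones. Ties at the
#' k-th rank break by lexicographic symbol order, so the output is
#' independent of input row order. A direction with fewer than k entries
#' returns all of them.
#'
#' @param cset tibble from [concordance()].
#' @param k signature size per direction.
#' @return list with tibbles `sig_plus` and `sig_minus`.
#' @export
make_signatures <- function(cset, k = 15L) {
  if (!nrow(cset)) abort("empty concordance set")
  pick <- function(dir) {
    cset |>
      filter(.data$direction == dir) |>
      arrange(desc(.data$ranking), .data$mouse_symbol) |>
      head(k)
  }
  list(sig_plus = pick("up"), sig_minus = pick("down"))
}

#' Cross-species Spearman matrix of effect sizes
#'
#' Per (mouse dataset, human dataset) pair, Spearman correlation of effect
#' sizes over the ortholog-resolved proteins shared by both tables; mode
#' `"sig"` restricts to proteins significant in both. P-values are
#' BH-adjusted over the whole matrix.
#'
#' @inheritParams concordance
#' @param mode `"all"` shared proteins or `"sig"` both-significant only.
#' @return tibble: `mouse_dataset`, `human_dataset`, `rho`, `p`, `fdr`,
#'   `n_shared` (`NA` when < 3 shared).
#' @export
cross_correlation <- function(mouse_diff, human, resolution,
                              mode = c("all", "sig")) {
  mode <- match.arg(mode)
  m <- mouse_diff |>
    mutate(human_symbol = translate_mouse(.data$gene_symbol, resolution)) |>
    filter(!is.na(.data$human_symbol))
  res <- purrr::map_dfr(unique(m$dataset_id), function(md) {
    purrr::map_dfr(unique(human$dataset_id), function(hd) {
      a <- filter(m, .data$dataset_id == md)
      b <- filter(human, .data$dataset_id == hd)
      if (mode == "sig") {
        a <- filter(a, .data$significant)
        b <- filter(b, .data$significant)
      }
      shared <- intersect(a$human_symbol, b$gene_symbol)
      if (length(shared) < 3L) {
        return(tibble(mouse_dataset = md, human_dataset = hd,
                      rho = NA_real_, p = NA_real_,
                      n_shared = length(shared)))
      }
      s <- spearman_with_p(a$logfc[match(shared, a$human_symbol)],
                           b$effect[match(shared, b$gene_symbol)])
      tibble(mouse_dataset = md, human_dataset = hd, rho = s$rho,
             p = s$p, n_shared = length(shared))
    })
  })
  res$fdr <- NA_real_
  comp <- !is.na(res$p)
  res$fdr[comp] <- benjamini_hochberg(res$p[comp])
  res
}
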