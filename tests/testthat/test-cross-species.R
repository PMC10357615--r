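# Ortholog resolution, overlap, concordance, signatures.

test_that("ortholog resolution keeps one-to-one components only", {
  map <- tibble::tibble(
    mouse_symbol = c("Arl8b", "Arl8b", "M1", "M1", "M2", "M2", "Solo"),
    human_symbol = c("ARL8B", "ARL8B", "H1", "H2", "H1", "H2", "SOLOX"),
    source_direction = c("m2h", "h2m", rep("m2h", 5))
  )
  res <- resolve_orthologs(map)
  expect_equal(res$pairs,
               tibble::tibble(mouse_symbol = c("Arl8b", "Solo"),
                              human_symbol = c("ARL8B", "SOLOX")))
  mm <- dplyr::filter(res$dropped, reason == "many-to-many")
  expect_setequal(mm$mouse_symbol, c("M1", "M2"))
  expect_equal(nrow(mm), 4)   # all four edges of the 2x2 component

  # direction-order invariance: unions in either order resolve identically
  rev_map <- map[rev(seq_len(nrow(map))), ]
  expect_equal(resolve_orthologs(rev_map)$pairs, res$pairs)

  # idempotence: an already one-to-one resolution resolves to itself
  again <- resolve_orthologs(
    dplyr::mutate(res$pairs, source_direction = "m2h"))
  expect_equal(again$pairs, res$pairs)

  expect_warning(empty <- resolve_orthologs(map[0, ]), "empty")
  expect_equal(nrow(empty$pairs), 0)
})

test_that("one-to-many policy keeps the best-named match only when asked", {
  map <- tibble::tibble(
    mouse_symbol = c("Gab1", "Gab1"),
    human_symbol = c("GAB1", "GAB1L"),
    source_direction = "m2h"
  )
  expect_equal(nrow(resolve_orthologs(map)$pairs), 0)
  kept <- resolve_orthologs(map, policy = "keep")$pairs
  expect_equal(kept$human_symbol, "GAB1")
})

test_that("overlap counts match set arithmetic and the planted overlap rate", {
  res <- resolve_orthologs(tibble::tibble(
    mouse_symbol = c("Aa", "Bb", "Cc"),
    human_symbol = c("AA", "BB", "CC"), source_direction = "m2h"))
  rep1 <- overlap_report(list(m = c("Aa", "Bb")),
                         list(h = c("ZZ", "YY")), res)
  expect_equal(rep1$pairwise$n_intersect, 0)
  rep2 <- overlap_report(list(m = c("Aa", "Bb")),
                         list(h = c("AA", "BB")), res)
  expect_equal(rep2$pairwise$n_intersect, 2)
  expect_equal(rep2$n_union_overlap, 2)

  # generator-planted overlap fraction: within the binomial 99% interval
  pre <- fad_preset("5xfad")
  sim <- simulate_lfq(pre$design, pre$params, seed = 71)
  hum <- simulate_human_tables(sim$truth, seed = 72,
                               overlap_fraction = 0.25,
                               concordance_fraction = 1)
  resol <- resolve_orthologs(hum$ortholog_map)
  dep_syms <- mouse_symbols_for(sim)
  d22 <- dplyr::filter(hum$tables, dataset_id == "D22", significant)
  hits <- sum(!is.na(proteofunnel:::translate_mouse(dep_syms, resol)) &
                proteofunnel:::translate_mouse(dep_syms, resol) %in%
                  d22$gene_symbol)
  n_resolved <- sum(!is.na(proteofunnel:::translate_mouse(dep_syms, resol)))
  ci <- qbinom(c(0.005, 0.995), n_resolved, 0.25)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("concordance requires significant same-sign pairs", {
  res <- resolve_orthologs(tibble::tibble(
    mouse_symbol = c("Up1", "Down1", "Dis1"),
    human_symbol = c("UP1", "DOWN1", "DIS1"), source_direction = "m2h"))
  mouse <- tibble::tibble(
    dataset_id = "H8",
    gene_symbol = c("Up1", "Down1", "Dis1"),
    logfc = c(0.5, -0.4, 0.3),
    significant = TRUE
  )
  human <- tibble::tibble(
    dataset_id = "D22",
    gene_symbol = c("UP1", "DOWN1", "DIS1"),
    effect = c(1.2, -0.8, -0.6),
    significant = TRUE
  )
  cs <- concordance(mouse, human, res)
  expect_setequal(cs$mouse_symbol, c("Up1", "Down1"))
  expect_equal(cs$direction[cs$mouse_symbol == "Up1"], "up")
  expect_equal(cs$direction[cs$mouse_symbol == "Down1"], "down")

  # non-significant human rows do not count
  human0 <- dplyr::mutate(human, significant = FALSE)
  expect_equal(nrow(concordance(mouse, human0, res)), 0)
})

test_that("forced full concordance makes the set equal the overlap", {
  pre <- fad_preset("smoke")
  sim <- simulate_lfq(pre$design, pre$params, seed = 73)
  hum <- simulate_human_tables(sim$truth, seed = 74,
                               overlap_fraction = 1,
                               concordance_fraction = 1)
  resol <- resolve_orthologs(hum$ortholog_map)
  truth_sign <- sim$truth$planted_lfc |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(lfc = lfc[which.max(abs(lfc))], .groups = "drop")
  mouse <- tibble::tibble(
    dataset_id = "H8",
    gene_symbol = sim$lfq$proteins$gene_symbol[
      match(truth_sign$protein_id, sim$lfq$proteins$protein_id)],
    logfc = truth_sign$lfc,
    significant = TRUE
  )
  cs <- concordance(mouse, hum$tables, resol)
  translated <- proteofunnel:::translate_mouse(mouse$gene_symbol, resol)
  human_sig <- unique(hum$tables$gene_symbol[hum$tables$significant])
  expect_equal(nrow(cs), sum(translated %in% human_sig, na.rm = TRUE))
  expect_false(any(cs$conflict))
  # invariants: set within resolved pairs; signature sizes bounded
  expect_true(all(cs$mouse_symbol %in% resol$pairs$mouse_symbol))
  sig <- make_signatures(cs)
  expect_lte(nrow(sig$sig_plus) + nrow(sig$sig_minus), nrow(cs))
})

test_that("signatures pick top-ranked entries deterministically", {
  cs <- tibble::tibble(
    mouse_symbol = c("Bb", "Aa", "Cc", "Dd", "Ee"),
    human_symbol = toupper(mouse_symbol),
    direction = c("up", "up", "up", "down", "down"),
    conflict = FALSE,
    ranking = c(0.5, 0.4, 0.3, 0.2, 0.2)
  )
  sig <- make_signatures(cs, k = 2)
  expect_equal(sig$sig_plus$mouse_symbol, c("Bb", "Aa"))
  expect_equal(nrow(sig$sig_minus), 2)
  sig15 <- make_signatures(cs, k = 15)
  expect_equal(nrow(sig15$sig_plus), 3)   # fewer than k: return all

  # tie at rank k: lexicographically smaller symbol wins; row order
  # never matters
  tie <- tibble::tibble(
    mouse_symbol = c("Zz", "Mm", "Aa"), human_symbol = toupper(mouse_symbol),
    direction = "up", conflict = FALSE, ranking = c(0.9, 0.5, 0.5)
  )
  expect_equal(make_signatures(tie, k = 2)$sig_plus$mouse_symbol,
               c("Zz", "Aa"))
  for (i in 1:5) {
    perm <- tie[sample(3), ]
    expect_equal(make_signatures(perm, k = 2)$sig_plus$mouse_symbol,
                 c("Zz", "Aa"))
  }
  expect_error(make_signatures(cs[0, ]), "empty")
})

test_that("cross-species Spearman hits the exact and null benchmarks", {
  n <- 1000
  msym <- sprintf("Gene%04d", 1:n)
  res <- resolve_orthologs(tibble::tibble(
    mouse_symbol = msym, human_symbol = toupper(msym),
    source_direction = "m2h"))
  set.seed(100)
  eff <- rnorm(n)
  mouse <- tibble::tibble(dataset_id = "H8", gene_symbol = msym,
                          logfc = eff, significant = TRUE)
  monotone <- tibble::tibble(dataset_id = "D22",
                             gene_symbol = toupper(msym),
                             effect = exp(eff), significant = TRUE)
  flipped <- dplyr::mutate(monotone, dataset_id = "J20", effect = -effect)
  indep <- tibble::tibble(dataset_id = "J22", gene_symbol = toupper(msym),
                          effect = rnorm(n), significant = TRUE)
  xc <- cross_correlation(mouse, dplyr::bind_rows(monotone, flipped,
                                                  indep), res)
  expect_equal(xc$rho[xc$human_dataset == "D22"], 1)
  expect_equal(xc$rho[xc$human_dataset == "J20"], -1)
  expect_lt(abs(xc$rho[xc$human_dataset == "J22"]), 0.1)
  expect_equal(xc$n_shared, rep(n, 3))
})
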