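# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Minimal experiment: one tissue unless stated, conditions defined by a
# design tibble; values filled from `fill` (recycled) unless a matrix is
# given.
toy_lfq <- function(values, design) {
  n <- nrow(values)
  proteins <- tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(n)),
    gene_symbol = sprintf("Gene%03d", seq_len(n))
  )
  proteofunnel::lfq_experiment(values, proteins, design)
}

# A design with `n_animals` per (age, genotype) cell and `n_tech`
# technical replicates, single tissue.
toy_design <- function(tissue = "hippocampus", ages = c(2, 5, 8),
                       genotypes = c("WT", "TG"), n_animals = 2,
                       n_tech = 2, batches = 1) {
  d <- tidyr::expand_grid(
    tissue = tissue, age = ages, genotype = genotypes,
    rep = seq_len(n_animals), tech_rep = seq_len(n_tech)
  )
  d$animal_id <- sprintf("%s%g_%d", d$genotype, d$age, d$rep)
  d$batch <- paste0(tissue, "_b", 1 + (d$rep %% batches))
  d$sample_id <- sprintf("%s_%s_t%d", d$animal_id, d$tissue, d$tech_rep)
  d[, c("sample_id", "tissue", "age", "genotype", "animal_id",
        "tech_rep", "batch")]
}

# Brute-force reliability oracle: literal enumeration of the rule into a
# protein x condition logical matrix.
brute_reliable_matrix <- function(values, design) {
  cond <- paste(design$tissue, design$age, design$genotype, sep = ".")
  cids <- unique(cond)
  out <- matrix(NA, nrow(values), length(cids),
                dimnames = list(NULL, cids))
  for (cid in cids) {
    j <- which(cond == cid)
    for (g in seq_len(nrow(values))) {
      out[g, cid] <- sum(is.na(values[g, j])) < length(j) / 2
    }
  }
  out
}

# Long-format wrapper kept for unit tests.
brute_reliable <- function(values, design) {
  m <- brute_reliable_matrix(values, design)
  tibble::tibble(
    protein = rep(seq_len(nrow(m)), ncol(m)),
    condition = rep(colnames(m), each = nrow(m)),
    reliable = as.vector(m)
  )
}

# Independent step-up BH reference (rank formula + cumulative minimum).
bh_reference <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Mann-Whitney U / (n1 n2) with midranks: the AUC oracle.
u_auc <- function(cases, controls) {
  r <- rank(c(cases, controls))
  n1 <- length(cases)
  n2 <- length(controls)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Gene symbols of every planted (non-null) protein in a simulation.
mouse_symbols_for <- function(sim) {
  ids <- unique(sim$truth$classes$protein_id)
  sim$lfq$proteins$gene_symbol[
    match(ids, sim$lfq$proteins$protein_id)]
}

# Random monotone-ish 3-point trajectory whose best |r| against every
# readout stays below `rmax` (rejection sampling).
sample_uncorrelated_shape <- function(trajectories, tissue, rmax = 0.99) {
  readouts <- split(trajectories$value[trajectories$tissue == tissue],
                    trajectories$readout[trajectories$tissue == tissue])
  repeat {
    y <- stats::rnorm(3)
    if (stats::sd(y) == 0) next
    rs <- vapply(readouts, function(v) abs(stats::cor(y, v)), numeric(1))
    if (max(rs) < rmax) return(y)
  }
}
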