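# Shared fixtures and independent oracles used across the suite.

# Published odds scores (2 dp) for the sixteen superfamily rows, one column
# per genus in the order Tco, Tci, Cs, Aa, Ha, Nt, Os, At.  Three cells of
# the IPR036909 row are printed inconsistently in the source table (their
# printed values cannot arise from the row's own counts and mean, while the
# other five cells can); those cells carry the arithmetically consistent
# values here and are tested separately.
published_odds_scores <- function() {
  tibble::tribble(
    ~signature_id, ~Tco,  ~Tci,  ~Cs,   ~Aa,   ~Ha,   ~Nt,   ~Os,   ~At,
    "IPR036041",    1.96,  1.29, -1.81, -1.00, -3.07, -3.07, -0.94, -3.07,
    "IPR005848",    2.36, -0.14, -1.87, -1.46, -1.87, -0.87, -2.14, -1.87,
    "IPR036226",    1.86,  0.48, -0.22, -0.82, -1.12, -0.67, -1.86, -2.44,
    "IPR033966",    1.60, -0.25,  0.05, -0.15, -1.37, -0.95, -0.25, -1.15,
    "IPR032466",    1.48,  0.69, -1.13, -0.89, -0.32, -0.05, -1.61, -0.98,
    "IPR036849",    1.38,  0.91, -0.62, -0.55, -0.78, -0.29, -1.41, -1.29,
    "IPR036396",    0.90,  0.19,  0.16,  0.07, -0.20, -0.12, -1.05, -0.85,
    "IPR035983",    1.22,  0.84,  0.10, -0.52, -0.90, -0.21, -1.84, -1.25,
    "IPR039512",   -1.18, -0.48, -0.09, -0.09, -0.01,  1.28, -0.72, -0.09,
    "IPR035992",    0.81,  1.41, -0.34, -0.05, -1.22, -0.80, -1.10, -1.48,
    "IPR036861",   -0.13, -1.13, -0.39, -0.25,  0.53,  0.29,  0.09,  0.37,
    "IPR036097",   -0.11,  1.41, -0.62, -0.37, -0.28,  0.35, -1.74, -0.74,
    "IPR024792",    0.48,  1.24, -0.14, -0.58, -0.34, -0.14, -1.04, -1.04,
    "IPR012347",    0.72,  1.29, -0.03, -0.71, -0.57, -0.86, -1.23, -0.57,
    "IPR036909",    0.40,  1.16, -0.50, -0.84, -0.22,  0.16, -0.72, -0.72,
    "IPR037069",    0.45,  1.05, -0.60, -0.30, -0.22,  0.22, -0.98, -0.84
  )
}

# Cells whose printed values disagree with their row's own arithmetic.
inconsistent_printed_cells <- function() {
  tibble::tibble(
    signature_id = "IPR036909",
    genus = c("Nt", "Os", "At"),
    printed = c(-0.16, -0.82, -0.82),
    consistent = c(0.16, -0.72, -0.72)
  )
}

# Direct per-cell evaluation of the odds formula, independent of odds_score()
# internals (plain loops over a wide matrix).
oracle_odds <- function(wide_counts, ps) {
  genera <- setdiff(names(wide_counts),
                    c("category", "signature_id", "signature_name"))
  out <- list()
  for (i in seq_len(nrow(wide_counts))) {
    n <- as.numeric(unlist(wide_counts[i, genera]))
    nbar <- sum(n) / length(n)
    for (j in seq_along(genera)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        genus = genera[j],
        signature_id = wide_counts$signature_id[i],
        score = log2((n[j] + ps) / (nbar + ps))
      )
    }
  }
  dplyr::bind_rows(out)
}

# Random domain-hit table for oracle comparisons.
random_hits <- function(n_genes, n_hits, clades = c("sire", "del", "athila",
                                                    "tork", "oryco"),
                        seed = 1L) {
  withr::with_seed(seed, {
    starts <- sample.int(500, n_hits, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("g%03d", sample.int(n_genes, n_hits, replace = TRUE)),
      clade = sample(clades, n_hits, replace = TRUE),
      evalue = 10^stats::runif(n_hits, -40, 1),
      ali_start = starts,
      ali_end = starts + sample.int(300, n_hits, replace = TRUE)
    )
  })
}

# Exhaustive best-hit selection: for each gene, scan all hits.
oracle_best_hit <- function(hits) {
  genes <- sort(unique(hits$gene_id))
  clade <- character(length(genes))
  for (i in seq_along(genes)) {
    h <- hits[hits$gene_id == genes[i], , drop = FALSE]
    h$span <- h$ali_end - h$ali_start + 1L
    h <- h[order(h$evalue, -h$span, h$clade), , drop = FALSE]
    clade[i] <- h$clade[1L]
  }
  tibble::tibble(gene_id = genes, clade = clade)
}

# Interval-union length by position enumeration (independent of the sweep).
oracle_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  length(unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE))))
}

# Exhaustive single-genus clade enumeration over every internal node, using
# ape's clade extraction rather than the package's postorder sweep.
oracle_multiplied_fractions <- function(tree, genera, min_size = 2) {
  n_tip <- length(tree$tip.label)
  nodes <- seq(n_tip + 1L, n_tip + tree$Nnode)
  clades <- lapply(nodes, function(nd) {
    ape::extract.clade(tree, nd)$tip.label
  })
  qualifying <- Filter(function(tips) {
    length(tips) >= min_size && length(unique(genera[tips])) == 1L
  }, clades)
  # maximal = not a strict subset of another qualifying clade
  maximal <- Filter(function(tips) {
    !any(vapply(qualifying, function(other) {
      length(other) > length(tips) && all(tips %in% other)
    }, logical(1)))
  }, qualifying)
  mult_leaves <- unique(unlist(maximal))
  all_genera <- sort(unique(unname(genera[tree$tip.label])))
  tibble::tibble(
    genus = all_genera,
    total_leaves = vapply(all_genera, function(g) {
      sum(genera[tree$tip.label] == g)
    }, integer(1)),
    multiplied_leaves = vapply(all_genera, function(g) {
      sum(genera[mult_leaves] == g)
    }, integer(1))
  ) |>
    dplyr::mutate(fraction = multiplied_leaves / total_leaves)
}

# Random genus-labelled rooted tree.
random_genus_tree <- function(n_leaves, n_genera = 3, seed = 1L) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_leaves)
    tree$tip.label <- sprintf("G%d_%03d",
                              sample.int(n_genera, n_leaves, replace = TRUE),
                              seq_len(n_leaves))
  })
  genus_tree(tree, "prefix")
}

# Random gene-domain profiles for set-algebra oracles.
random_profiles <- function(n_genes, sigs, mean_domains = 2, seed = 1L) {
  withr::with_seed(seed, {
    k <- pmin(length(sigs), 1L + stats::rpois(n_genes, mean_domains - 1))
    tibble::tibble(
      gene_id = rep(sprintf("g%04d", seq_len(n_genes)), k),
      signature_id = unlist(lapply(k, function(m) sample(sigs, m)))
    )
  })
}
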