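#' Simulate a k-mer depth histogram with known truth
#'
#' Generates the canonical shape of a shotgun k-mer spectrum: an error
#' component decaying geometrically from depth 1, a Poisson-shaped
#' homozygous component centred at the sequencing coverage `C` carrying the
#' unique fraction of the genome, and a repeat component centred at `2C`
#' carrying the two-copy repeat fraction (so the k-mer mass beyond the
#' error trough equals `genome_size * C` in expectation and
#' [size_from_kmers()] recovers the genome size).  Per-bin Poisson noise is
#' applied on top of the expected counts.
#'
#' @param genome_size Genome size in bases (distinct genomic k-mers).
#' @param coverage Homozygous k-mer depth `C` (>= 10 for separable peaks).
#' @param repeat_fraction Fraction of the genome present in two-copy
#'   repeats, in `[0, 1)`.
#' @param error_mass Total number of distinct error k-mers (default twice
#'   the genome size, dominating the low-depth bins as in real spectra).
#' @param error_decay Per-depth retention of the geometric error component
#'   (default 0.5).
#' @param noise Add Poisson noise per bin (default `TRUE`).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A dense histogram tibble (`depth`, `count`) with attribute
#'   `truth = list(genome_size, coverage, repeat_fraction)`.
#' @examples
#' h <- simulate_kmer_histogram(genome_size = 1e6, coverage = 44,
#'                              repeat_fraction = 0.2, seed = 7)
#' analyze_kmer_spectrum(h, smooth = 5)
#' @export
simulate_kmer_histogram <- function(genome_size, coverage,
                                    repeat_fraction = 0,
                                    error_mass = 2 * genome_size,
                                    error_decay = 0.5,
                                    noise = TRUE, seed = 1L) {
  stopifnot(genome_size > 0, coverage >= 10,
            repeat_fraction >= 0, repeat_fraction < 1,
            error_decay > 0, error_decay < 1)
  max_depth <- as.integer(ceiling(3.5 * coverage))
  depth <- seq_len(max_depth)
  g_unique <- genome_size * (1 - repeat_fraction)
  g_repeat <- genome_size * repeat_fraction
  expected <-
    error_mass * (1 - error_decay) * error_decay^(depth - 1) +
    g_unique * dpois(depth, coverage) +
    (g_repeat / 2) * dpois(depth, 2 * coverage)
  counts <- if (noise) {
    withr::with_seed(seed, rpois(max_depth, expected))
  } else {
    expected
  }
  h <- tibble(depth = depth, count = counts)
  attr(h, "truth") <- list(genome_size = genome_size, coverage = coverage,
                           repeat_fraction = repeat_fraction)
  h
}

#' Simulate per-genus annotation tables with a known count matrix
#'
#' Draws a baseline gene count for every (genus, signature) cell from a
#' shared Poisson rate, multiplies planted cells by their expansion fold,
#' and expands the counts into per-gene annotation records.  With
#' `dup_noise > 0` some genes receive a second record of the same signature,
#' exercising downstream deduplication; the truth matrix is unaffected.
#'
#' @param genera Character vector of genus labels (>= 2).
#' @param n_signatures Number of superfamily signatures (ids `SF0001`...).
#' @param base_rate Poisson mean of the baseline gene count per cell.
#' @param expansions Optional tibble with columns `genus`, `signature_id`,
#'   `fold`: those cells' counts are multiplied by `fold` (rounded half away
#'   from zero).
#' @param dup_noise Probability that an annotated gene gets a duplicate
#'   record of its signature (default 0.2).
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps the baseline Poisson.
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble `genus`, `gene_id`,
#'   `signature_id`, `signature_name`) and `truth` (count tibble `genus`,
#'   `signature_id`, `n` matching [build_count_matrix()] output).
#' @export
simulate_annotations <- function(genera, n_signatures = 20, base_rate = 25,
                                 expansions = NULL, dup_noise = 0.2,
                                 dispersion = NULL, seed = 1L) {
  if (length(genera) < 2L) abort("need at least 2 genera")
  if (anyDuplicated(genera)) abort("duplicate genus labels")
  sigs <- sprintf("SF%04d", seq_len(n_signatures))
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(genus = genera, signature_id = sigs)
    grid$n <- if (is.null(dispersion)) {
      rpois(nrow(grid), base_rate)
    } else {
      rnbinom(nrow(grid), size = dispersion, mu = base_rate)
    }
    if (!is.null(expansions)) {
      check_columns(expansions, c("genus", "signature_id", "fold"), "expansions")
      for (i in seq_len(nrow(expansions))) {
        j <- which(grid$genus == expansions$genus[i] &
                     grid$signature_id == expansions$signature_id[i])
        if (length(j) != 1L) abort("expansion cell not found in the grid")
        grid$n[j] <- round_half_away(grid$n[j] * expansions$fold[i], 0)
      }
    }
    recs <- grid[grid$n > 0L, , drop = FALSE] %>%
      mutate(gene_id = purrr::map2(.data$genus, .data$n, function(g, k) {
        sprintf("%s_g%06d", g, sample.int(1e6, k))
      })) %>%
      tidyr::unnest("gene_id") %>%
      select("genus", "gene_id", "signature_id")
    dup <- recs[stats::runif(nrow(recs)) < dup_noise, , drop = FALSE]
    annotations <- bind_rows(recs, dup) %>%
      mutate(signature_name = paste("superfamily", .data$signature_id)) %>%
      arrange(.data$genus, .data$gene_id, .data$signature_id)
  })
  truth <- grid %>%
    mutate(genus = factor(.data$genus, levels = genera)) %>%
    arrange(.data$signature_id, .data$genus) %>%
    mutate(genus = as.character(.data$genus), n = as.integer(.data$n))
  list(annotations = annotations, truth = truth)
}

#' Simulate a genus-labelled tree with planted multiplied clusters
#'
#' Builds a rooted tree in which, for each genus, a chosen share of leaves
#' forms one single-genus clade (a planted "multiplied cluster") and the
#' remaining leaves are interleaved along the backbone so that no two of
#' them can form a single-genus clade.  The planted per-genus fractions are
#' therefore recovered exactly by [find_multiplied_clusters()]; the truth is
#' guaranteed by construction, not statistically.
#'
#' @param genus_leaves Named integer vector: leaves per genus (each >= 2).
#' @param multiplied_fraction Named numeric vector (same names): planted
#'   fraction of each genus's leaves inside its multiplied cluster.  The
#'   implied leaf count `round(fraction * leaves)` must be 0 or >= 2.
#' @param seed Integer seed (controls the interleaving order only).
#' @return A `genus_tree` with attribute `truth`: tibble `genus`,
#'   `total_leaves`, `multiplied_leaves`, `fraction`.
#' @examples
#' gt <- simulate_genus_tree(c(Tco = 10, Tci = 8),
#'                           c(Tco = 0.6, Tci = 0.5), seed = 3)
#' find_multiplied_clusters(gt)$per_genus
#' @export
simulate_genus_tree <- function(genus_leaves, multiplied_fraction, seed = 1L) {
  if (is.null(names(genus_leaves)) || is.null(names(multiplied_fraction))) {
    abort("genus_leaves and multiplied_fraction must be named")
  }
  if (!setequal(names(genus_leaves), names(multiplied_fraction))) {
    abort("genus_leaves and multiplied_fraction must cover the same genera")
  }
  if (length(genus_leaves) < 2L) abort("need at least 2 genera")
  if (any(genus_leaves < 2L)) abort("each genus needs >= 2 leaves")

  genera <- names(genus_leaves)
  m <- round_half_away(multiplied_fraction[genera] * genus_leaves[genera], 0)
  if (any(m == 1)) {
    abort(sprintf(
      "planted fraction for %s implies a singleton cluster; need 0 or >= 2 leaves",
      paste(genera[m == 1], collapse = ", ")))
  }
  units <- list()   # each unit: list(genus = <chr>, newick = <chr>)
  for (g in genera) {
    labels <- sprintf("%s_%03d", g, seq_len(genus_leaves[[g]]))
    k <- m[[g]]
    if (k >= 2) {
      units <- c(units, list(list(genus = g, newick = caterpillar(labels[seq_len(k)]))))
    }
    for (lab in labels[seq_len(genus_leaves[[g]] - k) + k]) {
      units <- c(units, list(list(genus = g, newick = lab)))
    }
  }
  if (length(units) < 2L) abort("configuration yields fewer than 2 tree units")

  units <- withr::with_seed(seed, sample(units))
  # only the two deepest caterpillar positions can create an unplanned
  # single-genus clade; make sure they host different genera
  gs <- vapply(units, `[[`, "", "genus")
  if (gs[1L] == gs[2L]) {
    other <- which(gs != gs[1L])[1L]
    units[c(2L, other)] <- units[c(other, 2L)]
  }
  nwk <- paste0(caterpillar(vapply(units, `[[`, "", "newick")), ";")
  tree <- ape::read.tree(text = nwk)
  gt <- genus_tree(tree, "prefix")
  attr(gt, "truth") <- tibble(
    genus = genera,
    total_leaves = as.integer(genus_leaves[genera]),
    multiplied_leaves = as.integer(m),
    fraction = as.numeric(m / genus_leaves[genera])
  ) %>% arrange(.data$genus)
  gt
}

# Ladderized newick subtree over the given (sub)clades, no trailing ";".
caterpillar <- function(parts) {
  if (length(parts) == 1L) return(parts)
  out <- sprintf("(%s,%s)", parts[1L], parts[2L])
  for (p in parts[-(1:2)]) out <- sprintf("(%s,%s)", out, p)
  out
}
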