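#' Render a multiplication-odds table in the publication layout
#'
#' Formats each cell as `"<score>(<count>)"` with the score rounded to two
#' decimals half away from zero (ASCII hyphen for negatives), one column per
#' genus, with optional category labels attached.
#'
#' @param result An `odds_tbl` from [odds_score()].
#' @param categories Optional tibble with columns `signature_id`,
#'   `category` (and optionally `signature_name`).
#' @param genus_order Optional character vector fixing the column order.
#' @return A tibble of character columns: `category` (when supplied),
#'   `signature_id`, `signature_name` (when available), then one column per
#'   genus.
#' @seealso [parse_odds_table()] for the inverse.
#' @export
render_odds_table <- function(result, categories = NULL, genus_order = NULL) {
  check_columns(result, c("genus", "signature_id", "n", "score"), "odds result")
  d <- as_tibble(result)
  if (is.null(genus_order)) genus_order <- unique(d$genus)
  d$cell <- sprintf("%.2f(%d)", round_half_away(d$score, 2), as.integer(d$n))
  wide <- d %>%
    select("signature_id", dplyr::any_of("signature_name"), "genus", "cell") %>%
    tidyr::pivot_wider(names_from = "genus", values_from = "cell") %>%
    select("signature_id", dplyr::any_of("signature_name"), all_of(genus_order))
  if (!is.null(categories)) {
    check_columns(categories, c("signature_id", "category"), "category map")
    wide <- left_join(wide, as_tibble(categories), by = "signature_id") %>%
      select("category", dplyr::everything())
  }
  wide
}

#' Parse a rendered odds table back into scores and counts
#'
#' Inverse of [render_odds_table()]: splits each `"<score>(<count>)"` cell
#' back into its rounded score and gene count.
#'
#' @param rendered A tibble as produced by [render_odds_table()].
#' @param genera Character vector naming the genus columns; defaults to all
#'   columns matching the cell pattern.
#' @return A long tibble with columns `genus`, `signature_id`, `n`, `score`.
#' @export
parse_odds_table <- function(rendered, genera = NULL) {
  rendered <- as_tibble(rendered)
  if (is.null(genera)) {
    is_cell <- vapply(rendered, function(col) {
      is.character(col) && all(grepl("^-?[0-9.]+\\([0-9]+\\)$", col))
    }, logical(1))
    genera <- names(rendered)[is_cell]
  }
  if (length(genera) == 0L) abort("no genus cell columns found")
  rendered %>%
    select("signature_id", all_of(genera)) %>%
    tidyr::pivot_longer(all_of(genera), names_to = "genus", values_to = "cell") %>%
    mutate(
      score = as.numeric(sub("\\(.*$", "", .data$cell)),
      n = as.integer(sub("^.*\\(([0-9]+)\\)$", "\\1", .data$cell))
    ) %>%
    select("genus", "signature_id", "n", "score")
}

#' Run the profiling pipeline end to end
#'
#' Executes every stage for which the configuration supplies inputs, in
#' dependency order, and writes one tab-separated report per stage plus a
#' machine-readable JSON manifest (parameters, seed, package version, input
#' digests).  Outputs are deterministic: the same configuration and seed
#' produce byte-identical files.  A failing stage aborts with the stage
#' name; its partial output (if any) is kept with a `.partial` suffix.
#'
#' @param config A list; recognized elements:
#'   \describe{
#'     \item{kmer_histo}{path to a depth histogram; optional `reads` list
#'       (`n_reads`, `read_length`, `k`) and `cutoff`/`smooth` overrides.}
#'     \item{domain_hits}{path to a domain-hit digest for the TE landscape.}
#'     \item{annotations}{named character vector of per-genus annotation TSV
#'       paths (>= 2) for the odds score.}
#'     \item{tree}{path to a Newick file; optional `genus_map`, and
#'       `midpoint` flag.}
#'     \item{venn}{length-2 character vector of signature ids.}
#'     \item{rip}{`TRUE` to emit RIP type calls (needs `annotations`).}
#'     \item{categories}{path to a TSV with `signature_id`, `category`.}
#'     \item{params}{list of overrides: `ps`, `evalue_cutoff`, `min_size`,
#'       `top_n`, `secondary_frac`, `genome_size_gb`.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed matters when configs point at simulated
#'   inputs regenerated elsewhere).
#' @return Invisibly, a named list of the tibbles written, plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (!is.list(config) || length(config) == 0L) {
    abort("empty configuration: nothing to run (see ?run_pipeline)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(
    list(ps = 5.0, evalue_cutoff = 1.0, min_size = 2L, top_n = 5L,
         secondary_frac = 0.1, smooth = 1L, genome_size_gb = NA_real_),
    config$params %||% list()
  )
  results <- list()
  inputs <- character()

  run_stage <- function(name, file, fn) {
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
    path <- file.path(out_dir, file)
    write_report_tsv(out, paste0(path, ".partial"))
    file.rename(paste0(path, ".partial"), path)
    results[[name]] <<- out
    out
  }

  if (!is.null(config$kmer_histo)) {
    inputs <- c(inputs, kmer_histo = config$kmer_histo)
    run_stage("spectrum", "spectrum_report.tsv", function() {
      h <- read_kmer_histo(config$kmer_histo)
      sp <- analyze_kmer_spectrum(h, cutoff = config$cutoff,
                                  reads = config$reads,
                                  secondary_frac = params$secondary_frac,
                                  smooth = params$smooth)
      tidy(sp)
    })
  }

  if (!is.null(config$domain_hits)) {
    inputs <- c(inputs, domain_hits = config$domain_hits)
    landscape <- run_stage("te_landscape", "te_landscape.tsv", function() {
      hits <- call_tes(read_domain_hits(config$domain_hits),
                       evalue_cutoff = params$evalue_cutoff)
      accumulation_scores(hits)
    })
    run_stage("te_ranking", "te_ranking.tsv", function() {
      rk <- rank_clades(landscape, top_n = params$top_n)
      if (!is.na(params$genome_size_gb)) {
        rk <- mutate(rk, te_per_gb = te_density(
          attr(landscape, "total_te_genes"), params$genome_size_gb))
      }
      rk
    })
  }

  annotations <- NULL
  if (!is.null(config$annotations)) {
    if (is.null(names(config$annotations))) {
      abort("stage odds failed: annotations must be a genus-named vector of paths")
    }
    inputs <- c(inputs, config$annotations)
    annotations <- purrr::imap_dfr(config$annotations, function(p, g) {
      mutate(read_interproscan_tsv(p), genus = g)
    })
    categories <- NULL
    if (!is.null(config$categories)) {
      inputs <- c(inputs, categories = config$categories)
      categories <- readr::read_tsv(config$categories, show_col_types = FALSE,
                                    progress = FALSE)
    }
    run_stage("odds", "odds_table.tsv", function() {
      counts <- build_count_matrix(annotations)
      render_odds_table(odds_score(counts, ps = params$ps), categories = categories)
    })
  }

  if (!is.null(config$tree)) {
    inputs <- c(inputs, tree = config$tree)
    run_stage("multiplied_clusters", "multiplied_clusters.tsv", function() {
      gt <- read_genus_tree(config$tree, genus_map = config$genus_map)
      if (isTRUE(config$midpoint)) gt <- midpoint_root(gt)
      multiplied_report(find_multiplied_clusters(
        gt, min_size = params$min_size,
        collapse_below = config$collapse_below))
    })
  }

  if (!is.null(config$venn) && !is.null(annotations)) {
    run_stage("venn", "venn_partition.tsv", function() {
      venn_partition(annotations, config$venn[[1L]], config$venn[[2L]])
    })
  }
  if (isTRUE(config$rip) && !is.null(annotations)) {
    run_stage("rip", "rip_types.tsv", function() classify_rip(annotations))
  }

  manifest <- list(
    package = "genoprof",
    version = as.character(utils::packageVersion("genoprof")),
    seed = seed,
    params = params,
    stages = names(results),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), names(inputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
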