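#' Filter domain hits at an E-value threshold (TE calling)
#'
#' Retains hits whose E-value is at or below the cutoff.  The permissive
#' default of 1.0 reflects the screening role of the step: candidate
#' transposable-element genes are anything with a recognizable retroelement
#' domain, and clade assignment afterwards uses only the best hit per gene.
#'
#' @param hits A domain-hit tibble (see [read_domain_hits()]) with columns
#'   `gene_id`, `clade`, `evalue`, `ali_start`, `ali_end`.
#' @param evalue_cutoff Inclusive E-value threshold (default 1.0).
#' @return The filtered hit tibble.
#' @export
call_tes <- function(hits, evalue_cutoff = 1.0) {
  hits <- as_tibble(hits)
  check_columns(hits, c("gene_id", "clade", "evalue"), "domain-hit table")
  hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
}

#' Assign each gene to a single clade by best hit
#'
#' Every gene is assigned the clade of its lowest-E-value hit; ties go to
#' the hit with the longer alignment span, then to the lexicographically
#' smaller clade name.  One clade per gene keeps downstream accumulation
#' ratios from double-counting.
#'
#' @param hits An E-value-filtered domain-hit tibble (see [call_tes()]).
#' @return A tibble with columns `gene_id`, `clade` (one row per gene).
#' @export
assign_clades <- function(hits) {
  hits <- as_tibble(hits)
  check_columns(hits, c("gene_id", "clade", "evalue", "ali_start", "ali_end"),
                "domain-hit table")
  if (nrow(hits) == 0L) return(tibble(gene_id = character(), clade = character()))
  hits %>%
    mutate(span = .data$ali_end - .data$ali_start + 1L) %>%
    arrange(.data$gene_id, .data$evalue, desc(.data$span), .data$clade) %>%
    group_by(.data$gene_id) %>%
    slice_head(n = 1L) %>%
    ungroup() %>%
    select("gene_id", "clade")
}

#' Per-clade accumulation scores of a TE landscape
#'
#' For each gene (assigned to one clade by [assign_clades()]) the occupied
#' length is the union of that gene's alignment spans from its assigned
#' clade; per-clade occupancy is summed over genes, and the accumulation
#' score is the percentage of the total TE-occupied length attributable to
#' the clade.  With `weight = "count"` each gene contributes 1 instead of
#' its occupied length, giving element-count percentages.
#'
#' @param hits An E-value-filtered domain-hit tibble.
#' @param assignment Optional gene-to-clade assignment; computed with
#'   [assign_clades()] when `NULL`.
#' @param weight `"length"` (default; union of alignment spans) or
#'   `"count"` (one unit per gene).
#' @return A `te_landscape` tibble with columns `clade`, `te_gene_count`,
#'   `occupied_length`, `ratio_percent`, sorted by decreasing ratio.
#'   Attributes `total_te_genes` and `total_te_length` carry the totals.
#' @examples
#' hits <- tibble::tibble(
#'   gene_id = c("g1", "g2"), clade = c("del", "sire"),
#'   evalue = c(1e-10, 1e-12), ali_start = c(1L, 1L), ali_end = c(100L, 300L)
#' )
#' accumulation_scores(hits)
#' @export
accumulation_scores <- function(hits, assignment = NULL, weight = c("length", "count")) {
  weight <- arg_match(weight)
  hits <- as_tibble(hits)
  check_columns(hits, c("gene_id", "clade", "evalue", "ali_start", "ali_end"),
                "domain-hit table")
  if (is.null(assignment)) assignment <- assign_clades(hits)
  check_columns(assignment, c("gene_id", "clade"), "clade assignment")
  if (nrow(assignment) == 0L) abort("no TE genes: total occupied length is zero")

  assigned_hits <- dplyr::inner_join(hits, assignment,
                                     by = c("gene_id", "clade"))
  per_gene <- assigned_hits %>%
    group_by(.data$gene_id, .data$clade) %>%
    summarise(occupied = merged_span_length(.data$ali_start, .data$ali_end),
              .groups = "drop")
  if (weight == "count") per_gene$occupied <- 1L
  per_clade <- per_gene %>%
    group_by(.data$clade) %>%
    summarise(te_gene_count = dplyr::n(),
              occupied_length = sum(.data$occupied), .groups = "drop")
  total_len <- sum(per_clade$occupied_length)
  if (total_len <= 0) abort("total TE-occupied length is zero")
  out <- per_clade %>%
    mutate(ratio_percent = 100 * .data$occupied_length / total_len) %>%
    arrange(desc(.data$ratio_percent), .data$clade)
  attr(out, "total_te_genes") <- sum(out$te_gene_count)
  attr(out, "total_te_length") <- total_len
  class(out) <- c("te_landscape", class(out))
  out
}

#' TE density per gigabase
#'
#' @param total_te_genes Number of TE genes detected in the genome.
#' @param genome_size_gb Genome size in gigabases.
#' @return Integer TEs/Gb, rounded half away from zero.
#' @examples
#' te_density(772794, 9.4)  # 82212
#' @export
te_density <- function(total_te_genes, genome_size_gb) {
  stopifnot(genome_size_gb > 0)
  as.integer(round_half_away(total_te_genes / genome_size_gb, 0))
}

#' Rank clades by accumulation score
#'
#' @param landscape A `te_landscape` from [accumulation_scores()].
#' @param top_n Number of clades to keep (default 5; the full list is
#'   returned when fewer clades exist).
#' @return A tibble with columns `rank`, `clade`, `ratio_percent`, sorted
#'   by decreasing ratio with alphabetical tie-break.
#' @export
rank_clades <- function(landscape, top_n = 5) {
  check_columns(landscape, c("clade", "ratio_percent"), "TE landscape")
  as_tibble(landscape) %>%
    arrange(desc(.data$ratio_percent), .data$clade) %>%
    slice_head(n = top_n) %>%
    mutate(rank = dplyr::row_number(), .before = 1L) %>%
    select("rank", "clade", "ratio_percent")
}

#' @export
print.te_landscape <- function(x, ...) {
  cat(sprintf("<te_landscape> %d TE genes, %d clades, total occupied length %s\n",
              attr(x, "total_te_genes"), nrow(x),
              format(attr(x, "total_te_length"), big.mark = ",")))
  NextMethod()
}

#' @rdname accumulation_scores
#' @param object A `te_landscape` object.
#' @param ... Unused.
#' @export
autoplot.te_landscape <- function(object, ...) {
  d <- as_tibble(object)
  d$clade <- stats::reorder(d$clade, d$ratio_percent)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio_percent, y = .data$clade)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "accumulation score (% of TE regions)", y = NULL,
                  title = "TE clade landscape")
}
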