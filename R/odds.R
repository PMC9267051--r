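#' Build a genus-by-superfamily gene-count matrix
#'
#' Counts, for every genus and protein-superfamily signature, the number of
#' genes carrying at least one annotation record with that signature.  A
#' gene with several hits of the same signature counts once (deduplication);
#' a gene with two different signatures counts once under each.  Cells with
#' no annotated gene are completed with zero so every genus covers the same
#' signature set.
#'
#' @param annotations A long annotation tibble with columns `genus`,
#'   `gene_id`, `signature_id` and optionally `signature_name` (e.g. several
#'   [read_interproscan_tsv()] results bound together with a `genus`
#'   column, or [simulate_annotations()] output).
#' @param signatures Optional character vector restricting the signatures
#'   counted (e.g. superfamily-level IPR ids only).
#' @param dedupe Count distinct genes (`TRUE`, default) or raw annotation
#'   records (`FALSE`).
#' @return A long count tibble with columns `genus`, `signature_id`,
#'   (`signature_name` when available) and `n`, genera ordered as first
#'   encountered.
#' @export
build_count_matrix <- function(annotations, signatures = NULL, dedupe = TRUE) {
  annotations <- as_tibble(annotations)
  check_columns(annotations, c("genus", "gene_id", "signature_id"), "annotation table")
  if (!is.null(signatures)) {
    annotations <- annotations[annotations$signature_id %in% signatures, , drop = FALSE]
  }
  genera <- unique(annotations$genus)
  if (length(genera) < 2L) abort("need annotations from at least 2 genera")
  base <- annotations
  if (dedupe) base <- distinct(base, .data$genus, .data$gene_id, .data$signature_id)
  counts <- base %>%
    count(.data$genus, .data$signature_id, name = "n") %>%
    tidyr::complete(genus = genera,
                    signature_id = unique(annotations$signature_id),
                    fill = list(n = 0L)) %>%
    mutate(genus = factor(.data$genus, levels = genera)) %>%
    arrange(.data$signature_id, .data$genus) %>%
    mutate(genus = as.character(.data$genus))
  if ("signature_name" %in% names(annotations)) {
    names_tbl <- annotations %>%
      distinct(.data$signature_id, .data$signature_name) %>%
      group_by(.data$signature_id) %>% slice_head(n = 1L) %>% ungroup()
    counts <- left_join(counts, names_tbl, by = "signature_id")
  }
  counts
}

#' Multiplication odds score over a genus-by-superfamily count matrix
#'
#' For each genus `g` and signature `s` with gene count `N[g, s]`, the score
#' is
#' \deqn{\mathrm{score}(g, s) = \log_2 \frac{N(g, s) + PS}{\bar N(s) + PS}}
#' where \eqn{\bar N(s)} is the arithmetic mean of the counts over all
#' genera in the matrix (the focal genus included) and `PS` is a
#' pseudo-count constant, by default 5.00, which keeps zero counts finite
#' and shrinks scores for rare signatures.  A positive score marks a genus
#' carrying more genes of that superfamily than the cross-genus average
#' (lineage-specific multiplication); a negative score marks relative
#' contraction.
#'
#' @param counts A count matrix in long form (columns `genus`,
#'   `signature_id`, `n`; see [build_count_matrix()]) or a numeric matrix
#'   with genera as rows and signatures as columns.
#' @param ps Pseudo-count constant `PS` (default 5.00).  Must be positive
#'   unless every count is positive.
#' @return An `odds_tbl`: the input tibble with added columns `n_mean`
#'   (the cross-genus mean for the signature) and `score`.  Attribute `ps`
#'   records the pseudo-count.  Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' counts <- tibble::tibble(
#'   genus = rep(c("Tco", "Tci"), each = 1),
#'   signature_id = "IPR036041",
#'   n = c(159L, 98L)
#' )
#' odds_score(counts, ps = 5)
#' @export
odds_score <- function(counts, ps = 5.0) {
  if (is.matrix(counts)) counts <- count_matrix_to_long(counts)
  counts <- as_tibble(counts)
  check_columns(counts, c("genus", "signature_id", "n"), "count matrix")
  if (any(counts$n < 0)) abort("counts must be non-negative")
  if (n_distinct(counts$genus) < 2L) {
    abort("odds score needs at least 2 genera (the cross-genus mean is degenerate)")
  }
  if (ps < 0) abort("ps must be non-negative")
  if (ps == 0 && any(counts$n == 0)) {
    abort("ps = 0 with zero counts gives infinite scores; use ps > 0")
  }
  dup <- counts %>%
    count(.data$genus, .data$signature_id, name = "n_rows") %>%
    filter(.data$n_rows > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate (genus, signature) cell: %s / %s",
                  dup$genus[1L], dup$signature_id[1L]))
  }
  out <- counts %>%
    group_by(.data$signature_id) %>%
    mutate(n_mean = mean(.data$n),
           score = log2((.data$n + ps) / (.data$n_mean + ps))) %>%
    ungroup()
  attr(out, "ps") <- ps
  class(out) <- c("odds_tbl", class(out))
  out
}

count_matrix_to_long <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("count matrix needs genus rownames and signature colnames")
  }
  tibble(
    genus = rep(rownames(m), times = ncol(m)),
    signature_id = rep(colnames(m), each = nrow(m)),
    n = as.vector(m)
  )
}

#' Rank superfamilies by a genus's odds scores
#'
#' @param result An `odds_tbl` from [odds_score()].
#' @param genus Focal genus label.
#' @param categories Optional curation table with columns `signature_id`,
#'   `category` (e.g. biodefense / signaling / metabolism), attached
#'   pass-through.
#' @return A list with tibbles `highest` (score descending) and `lowest`
#'   (score ascending); ties break by signature id.
#' @export
rank_odds <- function(result, genus, categories = NULL) {
  check_columns(result, c("genus", "signature_id", "n", "score"), "odds result")
  if (!genus %in% result$genus) abort(sprintf("unknown genus: %s", genus))
  rows <- as_tibble(result) %>% filter(.data$genus == !!genus)
  if (!is.null(categories)) {
    check_columns(categories, c("signature_id", "category"), "category map")
    rows <- left_join(rows, as_tibble(categories), by = "signature_id")
  }
  list(
    highest = arrange(rows, desc(.data$score), .data$signature_id),
    lowest  = arrange(rows, .data$score, .data$signature_id)
  )
}

#' @export
print.odds_tbl <- function(x, ...) {
  if (!all(c("genus", "signature_id") %in% names(x))) return(NextMethod())
  cat(sprintf("<odds_tbl> %d genera x %d signatures, PS = %s\n",
              n_distinct(x$genus), n_distinct(x$signature_id),
              format(attr(x, "ps"))))
  NextMethod()
}

#' @rdname odds_score
#' @param x An `odds_tbl` object.
#' @param ... Unused.
#' @export
tidy.odds_tbl <- function(x, ...) {
  as_tibble(unclass_odds(x))
}

#' @rdname odds_score
#' @export
glance.odds_tbl <- function(x, ...) {
  tibble(
    n_genera = n_distinct(x$genus),
    n_signatures = n_distinct(x$signature_id),
    ps = attr(x, "ps"),
    max_score = max(x$score),
    min_score = min(x$score)
  )
}

unclass_odds <- function(x) {
  class(x) <- setdiff(class(x), "odds_tbl")
  x
}

#' @rdname odds_score
#' @param object An `odds_tbl` object.
#' @export
autoplot.odds_tbl <- function(object, ...) {
  d <- as_tibble(unclass_odds(object))
  d$genus <- factor(d$genus, levels = unique(d$genus))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genus, y = .data$signature_id,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 odds",
                  title = "Multiplication odds scores")
}
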