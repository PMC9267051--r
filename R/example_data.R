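#' Published genus-by-superfamily gene counts
#'
#' The per-genus gene counts for sixteen protein superfamilies across eight
#' plant genera (Tco, Tci, Cs, Aa, Ha, Nt, Os, At), as tabulated in the
#' comparative draft-genome study this package models.  These counts are the
#' substrate of the multiplication odds score and make a convenient worked
#' example; the scores themselves are always recomputed with [odds_score()].
#'
#' @param long Return the long form used by [odds_score()] (default) or the
#'   wide table as shipped.
#' @return A tibble.  Long form: `genus`, `signature_id`, `signature_name`,
#'   `category`, `n`.  Wide form: `category`, `signature_id`,
#'   `signature_name`, one count column per genus.
#' @examples
#' counts <- superfamily_counts()
#' odds_score(counts, ps = 5)
#' @export
superfamily_counts <- function(long = TRUE) {
  path <- system.file("extdata", "superfamily_counts.tsv", package = "genoprof")
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!long) return(wide)
  genera <- setdiff(names(wide), c("category", "signature_id", "signature_name"))
  wide %>%
    tidyr::pivot_longer(all_of(genera), names_to = "genus", values_to = "n") %>%
    mutate(genus = factor(.data$genus, levels = genera)) %>%
    arrange(.data$signature_id, .data$genus) %>%
    mutate(genus = as.character(.data$genus)) %>%
    select("genus", "signature_id", "signature_name", "category", "n")
}
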