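#' Read an InterProScan TSV annotation file
#'
#' Parses the tab-separated output of InterProScan 5 (protein accession in
#' column 1, analysis in column 4, member-database signature accession in
#' column 5, description in column 6, start/stop in columns 7-8, e-value in
#' column 9, and, when present, the InterPro accession and description in
#' columns 12-13).  When a row carries an InterPro accession (`IPR...`) it
#' becomes the record's `signature_id` and the member-database accession is
#' retained in `source_db`; otherwise the member accession itself is the
#' signature.  A minimal three-column dialect (`gene_id`, `signature_id`,
#' `signature_name`) is also accepted so small hand-written tables can drive
#' the downstream counting.
#'
#' @param path Path to a tab-separated annotation file (no header; lines
#'   starting with `#` are ignored).
#' @return A tibble of annotation records with columns `gene_id`,
#'   `signature_id`, `signature_name`, `source_db`, `start`, `end`,
#'   `evalue`.  E-values printed as `-` become `NA`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines("g1\tIPR036041\tRibosome-inactivating protein", tsv)
#' read_interproscan_tsv(tsv)
#' @export
read_interproscan_tsv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("empty annotation file: %s", path))
    return(empty_annotation_tbl())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  if (all(nf == 3L)) {  # minimal fixture dialect
    recs <- tibble(
      gene_id        = vapply(fields, `[[`, "", 1L),
      signature_id   = vapply(fields, `[[`, "", 2L),
      signature_name = vapply(fields, `[[`, "", 3L),
      source_db      = NA_character_,
      start          = NA_integer_,
      end            = NA_integer_,
      evalue         = NA_real_
    )
    return(validate_annotation_tbl(recs, path))
  }

  bad <- which(nf < 11L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed annotation file %s: row %d has %d column(s), expected >= 11",
      path, bad[1L], nf[bad[1L]]
    ))
  }
  get_col <- function(j) {
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_, "")
  }
  member_acc  <- get_col(5L)
  member_name <- get_col(6L)
  ipr_acc     <- get_col(12L)
  ipr_name    <- get_col(13L)
  has_ipr <- !is.na(ipr_acc) & ipr_acc != "-" & nzchar(ipr_acc)
  ev_raw <- get_col(9L)
  recs <- tibble(
    gene_id        = get_col(1L),
    signature_id   = ifelse(has_ipr, ipr_acc, member_acc),
    signature_name = ifelse(has_ipr & !is.na(ipr_name), ipr_name, member_name),
    source_db      = ifelse(has_ipr, member_acc, get_col(4L)),
    start          = as.integer(get_col(7L)),
    end            = as.integer(get_col(8L)),
    evalue         = suppressWarnings(
      ifelse(ev_raw == "-" | is.na(ev_raw), NA_real_, as.numeric(ev_raw))
    )
  )
  validate_annotation_tbl(recs, path)
}

empty_annotation_tbl <- function() {
  tibble(
    gene_id = character(), signature_id = character(),
    signature_name = character(), source_db = character(),
    start = integer(), end = integer(), evalue = double()
  )
}

validate_annotation_tbl <- function(recs, path) {
  if (any(is.na(recs$signature_id) | !nzchar(recs$signature_id))) {
    abort(sprintf("annotation file %s: empty signature accession (row %d)",
                  path, which(is.na(recs$signature_id) | !nzchar(recs$signature_id))[1L]))
  }
  with_coords <- !is.na(recs$start) & !is.na(recs$end)
  if (any(with_coords & (recs$start < 1L | recs$end < recs$start))) {
    bad <- which(with_coords & (recs$start < 1L | recs$end < recs$start))[1L]
    abort(sprintf("annotation file %s: invalid coordinates at row %d", path, bad))
  }
  recs
}

#' Read a normalized domain-hit table
#'
#' Reads a tab-separated digest of profile-HMM search results with columns
#' `gene_id`, `clade`, `evalue`, `ali_start`, `ali_end` (1-based inclusive
#' protein coordinates).  An optional header line starting with `#` is
#' skipped.  All rows are retained; e-value filtering is [call_tes()]'s job.
#'
#' @param path Path to the tab-separated hit table.
#' @return A tibble with columns `gene_id`, `clade`, `evalue`, `ali_start`,
#'   `ali_end`; empty tibble for an empty file.
#' @seealso [call_tes()], [assign_clades()], [accumulation_scores()]
#' @export
read_domain_hits <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hits_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    abort(sprintf("domain-hit file %s: row %d has %d column(s), expected 5",
                  path, which(nf < 5L)[1L], nf[which(nf < 5L)[1L]]))
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(ev)) {
    abort(sprintf("domain-hit file %s: non-numeric e-value at row %d",
                  path, which(is.na(ev))[1L]))
  }
  hits <- tibble(
    gene_id   = vapply(fields, `[[`, "", 1L),
    clade     = vapply(fields, `[[`, "", 2L),
    evalue    = ev,
    ali_start = as.integer(vapply(fields, `[[`, "", 4L)),
    ali_end   = as.integer(vapply(fields, `[[`, "", 5L))
  )
  if (any(hits$ali_end < hits$ali_start)) {
    abort(sprintf("domain-hit file %s: ali_end < ali_start at row %d",
                  path, which(hits$ali_end < hits$ali_start)[1L]))
  }
  hits
}

empty_hits_tbl <- function() {
  tibble(gene_id = character(), clade = character(), evalue = double(),
         ali_start = integer(), ali_end = integer())
}

#' Read a k-mer depth histogram (Jellyfish "histo" format)
#'
#' Two whitespace-separated columns per line: depth (positive integer,
#' strictly increasing) and the number of distinct k-mers observed at that
#' depth.  Depths absent from the file are imputed with count 0 so the
#' returned histogram is dense from the smallest to the largest depth.
#'
#' @param path Path to the histogram file.
#' @param k Optional k-mer size recorded as metadata (attribute `k`).
#' @return A tibble with integer columns `depth` and `count`.
#' @seealso [find_cutoff()], [find_peaks()], [size_from_kmers()]
#' @export
read_kmer_histo <- function(path, k = NULL) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, header = FALSE, col.names = c("depth", "count"),
                         colClasses = "numeric")
  if (nrow(x) == 0L) abort(sprintf("empty histogram file: %s", path))
  if (any(x$depth < 1 | x$depth != floor(x$depth))) {
    abort(sprintf("histogram %s: depths must be positive integers", path))
  }
  if (any(diff(x$depth) <= 0)) {
    abort(sprintf("histogram %s: depths must be strictly increasing (violated at line %d)",
                  path, which(diff(x$depth) <= 0)[1L] + 1L))
  }
  if (any(x$count < 0)) {
    abort(sprintf("histogram %s: negative count at line %d",
                  path, which(x$count < 0)[1L]))
  }
  h <- densify_histogram(tibble(depth = as.integer(x$depth), count = x$count))
  if (!is.null(k)) attr(h, "k") <- as.integer(k)
  h
}

# Fill gaps in a depth->count table with zero counts.
densify_histogram <- function(h) {
  check_columns(h, c("depth", "count"), "k-mer histogram")
  depths <- seq(min(h$depth), max(h$depth))
  out <- tibble(depth = as.integer(depths), count = 0)
  out$count[match(h$depth, depths)] <- h$count
  out
}

#' Read a Newick tree and label its leaves with genera
#'
#' @param path Path to a Newick tree file.
#' @param genus_map Either `NULL` / `"prefix"` to derive each leaf's genus
#'   from the substring before the first underscore of its label, or an
#'   explicit mapping: a named character vector (`names` = leaf labels) or a
#'   data frame with columns `leaf` and `genus`.
#' @return A `genus_tree`: a list with elements `tree` (an [ape::phylo])
#'   and `genera` (named character vector, one genus per leaf).
#' @examples
#' nwk <- tempfile(fileext = ".nwk")
#' writeLines("((Tco_a,Tco_b),(Tci_c,Tci_d));", nwk)
#' gt <- read_genus_tree(nwk)
#' table(gt$genera)
#' @export
read_genus_tree <- function(path, genus_map = NULL) {
  stopifnot(file.exists(path))
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) abort(sprintf("could not parse Newick file: %s", path))
  genus_tree(tree, genus_map)
}

#' Construct a genus-labelled tree
#'
#' @param tree An [ape::phylo] object with at least 2 leaves.
#' @param genus_map See [read_genus_tree()].
#' @return A `genus_tree` object.
#' @export
genus_tree <- function(tree, genus_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) abort("tree must have at least 2 leaves")
  tips <- tree$tip.label
  if (is.null(genus_map) || identical(genus_map, "prefix")) {
    genera <- sub("_.*$", "", tips)
  } else if (is.data.frame(genus_map)) {
    check_columns(genus_map, c("leaf", "genus"), "genus map")
    genera <- genus_map$genus[match(tips, genus_map$leaf)]
  } else if (is.character(genus_map) && !is.null(names(genus_map))) {
    genera <- unname(genus_map[tips])
  } else {
    abort("genus_map must be NULL, \"prefix\", a named character vector, or a leaf/genus data frame")
  }
  missing <- tips[is.na(genera) | !nzchar(genera)]
  if (length(missing) > 0L) {
    abort(sprintf("no genus assignment for leaf/leaves: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(list(tree = tree, genera = setNames(genera, tips)),
            class = "genus_tree")
}

#' @export
print.genus_tree <- function(x, ...) {
  cat(sprintf("<genus_tree> %d leaves, %d genera: %s\n",
              length(x$tree$tip.label), length(unique(x$genera)),
              paste(sort(unique(x$genera)), collapse = ", ")))
  invisible(x)
}

# Write a tibble as a "#"-headed TSV (the package's report dialect).
write_report_tsv <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  body <- do.call(paste, c(lapply(x, format_tsv_col), list(sep = "\t")))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

format_tsv_col <- function(col) {
  if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE, digits = 15)
  else as.character(col)
}

# Read back the report dialect.
read_report_tsv <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  nm <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1L]]
  readr::read_tsv(path, skip = 1L, col_names = nm, show_col_types = FALSE,
                  progress = FALSE)
}
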