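#' Locate the trough between the error and signal k-mer distributions
#'
#' A k-mer depth histogram from shotgun reads is bimodal: sequencing errors
#' produce a component that decays from depth 1, and genomic k-mers form a
#' hump around the sequencing coverage.  The depth cutoff separating the two
#' is taken as the first local minimum: the smallest depth `d >= 2` with
#' `count(d) <= count(d - 1)` and `count(d) <= count(d + 1)`.  Ties break
#' toward smaller depth.  An optional centred moving-average window guards
#' the detection against single-bin noise (the returned depth is still a
#' depth of the original histogram).
#'
#' @param h A k-mer histogram: data frame with columns `depth`, `count`
#'   (see [read_kmer_histo()]).  Gaps are densified with zero counts.
#' @param smooth Odd window width for the moving average used during
#'   detection; 1 (default) means no smoothing.
#' @return The cutoff depth (integer).
#' @examples
#' h <- tibble::tibble(depth = 1:7, count = c(100, 40, 10, 5, 8, 20, 12))
#' find_cutoff(h)  # 4
#' @export
find_cutoff <- function(h, smooth = 1) {
  h <- densify_histogram(as_tibble(h))
  if (nrow(h) < 3L) abort("histogram too short for trough detection")
  counts <- smooth_counts(h$count, smooth)
  n <- length(counts)
  # candidate positions must have both neighbours and depth >= 2
  idx <- which(h$depth >= 2L)
  idx <- idx[idx > 1L & idx < n]
  is_min <- counts[idx] <= counts[idx - 1L] & counts[idx] <= counts[idx + 1L]
  if (!any(is_min)) {
    abort(paste0("no local minimum found in histogram head; ",
                 "the error component may be absent - supply the cutoff explicitly"))
  }
  h$depth[idx[which(is_min)[1L]]]
}

smooth_counts <- function(counts, smooth) {
  smooth <- as.integer(smooth)
  if (smooth <= 1L) return(counts)
  if (smooth %% 2L == 0L) abort("smooth window must be odd")
  half <- smooth %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Find the homozygous coverage peak and secondary peaks
#'
#' Beyond the error/signal cutoff, the main peak `C` is the depth with the
#' largest count (smallest depth on ties).  Secondary peaks -- e.g. a repeat
#' shoulder near `2C` -- are all other local maxima at or beyond the cutoff
#' whose count is at least `secondary_frac` of the main peak's count.
#'
#' @inheritParams find_cutoff
#' @param cutoff Depth cutoff from [find_cutoff()] (or supplied manually).
#' @param secondary_frac Minimum height of a secondary peak, as a fraction
#'   of the main peak's count (default 0.1).
#' @return A list with elements `peak` (the depth `C`) and `secondary`
#'   (integer vector of depths, sorted increasing; may be empty).
#' @export
find_peaks <- function(h, cutoff, secondary_frac = 0.1) {
  h <- densify_histogram(as_tibble(h))
  h <- h[h$depth >= cutoff, , drop = FALSE]
  if (nrow(h) == 0L) abort("no histogram bins at or beyond the cutoff")
  counts <- h$count
  peak <- h$depth[which.max(counts)]  # which.max: first (smallest depth) on ties
  n <- length(counts)
  left  <- c(-Inf, counts[-n])   # pad so a rising first bin is not a maximum
  right <- c(counts[-1L], -Inf)  # trailing bin can be a maximum
  # first bin of a plateau counts as the maximum; later plateau bins do not
  is_max <- counts > left & counts >= right
  is_max[1L] <- counts[1L] >= right[1L]
  cand <- h$depth[is_max & counts >= secondary_frac * max(counts)]
  list(peak = peak, secondary = sort(setdiff(cand, peak)))
}

#' Genome size from read statistics and coverage
#'
#' Converts read-level statistics into a genome-size estimate with the
#' standard coverage identity: each read of length `L` contributes
#' `L - k + 1` k-mers, and the genomic k-mer pool is covered `C` times, so
#' `size = n * (L - k + 1) / C` bases.
#'
#' @param n_reads Total number of reads.
#' @param read_length Average read length (bases).
#' @param k K-mer size; must be smaller than `read_length`.
#' @param coverage Homozygous peak depth `C` (from [find_peaks()]).
#' @return Estimated genome size in bases (not rounded).
#' @examples
#' size_from_reads(1000, 100, 21, 10)  # 8000
#' @export
size_from_reads <- function(n_reads, read_length, k, coverage) {
  stopifnot(n_reads > 0, coverage >= 1)
  if (read_length <= k) abort("read_length must exceed k (reads yield no k-mers otherwise)")
  n_reads * (read_length - k + 1) / coverage
}

#' Genome size from k-mer mass beyond the cutoff
#'
#' Sums the k-mer mass (depth times count) over all depths at or beyond the
#' error cutoff and divides by the homozygous coverage `C`:
#' `size = sum(d * count(d)) / C`.  Repeat k-mers sit at multiples of `C`
#' and thus contribute their genomic copy number, so the estimate covers the
#' repetitive fraction too.
#'
#' @inheritParams find_peaks
#' @param coverage Homozygous peak depth `C`.
#' @return Estimated genome size in bases.
#' @export
size_from_kmers <- function(h, cutoff, coverage) {
  stopifnot(coverage >= 1)
  h <- as_tibble(h)
  check_columns(h, c("depth", "count"), "k-mer histogram")
  keep <- h$depth >= cutoff
  mass <- sum(as.numeric(h$depth[keep]) * as.numeric(h$count[keep]))
  if (mass <= 0) abort("no k-mer mass at or beyond the cutoff")
  mass / coverage
}

#' Analyze a k-mer spectrum end to end
#'
#' Runs trough detection, peak finding and both genome-size estimators and
#' bundles the results.  The spectrum-based estimate is always computed; the
#' read-based estimate is added when read statistics are supplied.
#'
#' @inheritParams find_cutoff
#' @param cutoff Optional explicit cutoff; when `NULL` it is detected with
#'   [find_cutoff()].
#' @param reads Optional list with elements `n_reads`, `read_length`, `k`
#'   for the read-based estimator.
#' @param secondary_frac Passed to [find_peaks()].
#' @return A `kmer_spectrum` object: list with `histogram`, `cutoff`,
#'   `peak`, `secondary`, `size_spectrum`, and `size_reads` (`NA` when read
#'   statistics are absent).  Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' h <- simulate_kmer_histogram(genome_size = 1e6, coverage = 44, seed = 1)
#' analyze_kmer_spectrum(h, smooth = 5)
#' @export
analyze_kmer_spectrum <- function(h, cutoff = NULL, reads = NULL,
                                  secondary_frac = 0.1, smooth = 1) {
  h <- densify_histogram(as_tibble(h))
  if (is.null(cutoff)) cutoff <- find_cutoff(h, smooth = smooth)
  pk <- find_peaks(h, cutoff, secondary_frac = secondary_frac)
  size_sp <- size_from_kmers(h, cutoff, pk$peak)
  size_rd <- NA_real_
  if (!is.null(reads)) {
    size_rd <- size_from_reads(reads$n_reads, reads$read_length, reads$k, pk$peak)
  }
  structure(
    list(histogram = h, cutoff = cutoff, peak = pk$peak,
         secondary = pk$secondary, size_spectrum = size_sp,
         size_reads = size_rd),
    class = "kmer_spectrum"
  )
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("<kmer_spectrum>\n")
  cat(sprintf("  cutoff (error/signal trough): %d\n", x$cutoff))
  cat(sprintf("  homozygous peak C: %d\n", x$peak))
  cat(sprintf("  secondary peaks: %s\n",
              if (length(x$secondary)) paste(x$secondary, collapse = ", ") else "none"))
  cat(sprintf("  genome size (spectrum-based): %.4g bases\n", x$size_spectrum))
  if (!is.na(x$size_reads)) {
    cat(sprintf("  genome size (read-based):     %.4g bases\n", x$size_reads))
  }
  invisible(x)
}

#' @rdname analyze_kmer_spectrum
#' @param x A `kmer_spectrum` object.
#' @param ... Unused.
#' @export
tidy.kmer_spectrum <- function(x, ...) {
  tibble(
    quantity = c("cutoff", "peak",
                 paste0("secondary_peak_", seq_along(x$secondary)),
                 "size_spectrum", "size_reads"),
    value = c(x$cutoff, x$peak, x$secondary, x$size_spectrum, x$size_reads)
  )
}

#' @rdname analyze_kmer_spectrum
#' @export
glance.kmer_spectrum <- function(x, ...) {
  tibble(cutoff = x$cutoff, peak = x$peak,
         n_secondary = length(x$secondary),
         size_spectrum = x$size_spectrum, size_reads = x$size_reads)
}

#' @rdname analyze_kmer_spectrum
#' @param object A `kmer_spectrum` object.
#' @export
autoplot.kmer_spectrum <- function(object, ...) {
  h <- object$histogram
  h <- h[h$count > 0, , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$depth, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$peak, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mers",
                  title = sprintf("k-mer spectrum (cutoff %d, peak %d)",
                                  object$cutoff, object$peak))
}
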