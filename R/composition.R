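#' Per-record GC/AT composition
#'
#' GC fraction per record over unambiguous bases only: `N` is excluded
#' from both numerator and denominator. Records with zero unambiguous
#' bases get `NA` and are flagged `usable = FALSE`; downstream summaries
#' drop them.
#'
#' @param records `DNAStringSet` or named character vector.
#' @return Data frame of class `composition_profile`: `id`, `gc`, `at`,
#'   `n_unambiguous`, `usable`.
#' @export
per_record_gc <- function(records) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (length(records) == 0L) stop("no records supplied")
  freq <- Biostrings::alphabetFrequency(records, baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  n_un <- rowSums(acgt)
  gc <- ifelse(n_un > 0, (acgt[, "G"] + acgt[, "C"]) / n_un, NA_real_)
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_along(records))
  out <- data.frame(id = ids, gc = gc, at = 1 - gc,
                    n_unambiguous = n_un, usable = n_un > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Smoothed GC density curve with mode detection
#'
#' Histogram of per-record GC at `bin_width`, plus a Gaussian-kernel
#' density on a fixed grid over [0, 1]. Modes are strict local maxima of
#' the smoothed density whose height is at least `prominence` times the
#' maximum density (suppressing noise wiggles); they are reported in
#' descending density order.
#'
#' @param profile A `composition_profile` (or numeric vector of GC
#'   fractions).
#' @param bin_width Histogram bin width (default 0.01).
#' @param bandwidth Kernel bandwidth; `NULL` uses Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @param prominence Minimum mode height as a fraction of the maximum
#'   density (default 0.05).
#' @param grid_n Number of grid points (default 512).
#' @return List of class `density_curve`: `grid`, `density`, `histogram`
#'   (`bin_lower`, `count`), `modes` (positions, descending density),
#'   `bandwidth`, `n`.
#' @export
density_with_modes <- function(profile, bin_width = 0.01, bandwidth = NULL,
                               prominence = 0.05, grid_n = 512L) {
  gc <- if (is.numeric(profile)) profile else profile$gc[profile$usable]
  gc <- gc[!is.na(gc)]
  if (length(gc) < 2L) stop("need at least 2 usable records")
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(gc) else bandwidth
  if (bw <= 0) bw <- 1e-4  # degenerate all-identical input
  d <- stats::density(gc, bw = bw, n = grid_n, from = 0, to = 1)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(y) >= 2L) {
    if (y[1] > y[2]) is_max <- c(1L, is_max)
    if (y[length(y)] > y[length(y) - 1L]) is_max <- c(is_max, length(y))
  }
  is_max <- is_max[y[is_max] >= prominence * max(y)]
  modes <- d$x[is_max][order(y[is_max], decreasing = TRUE)]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(gc, breaks = breaks, plot = FALSE)
  out <- list(grid = d$x, density = y,
              histogram = data.frame(bin_lower = utils::head(h$breaks, -1),
                                     count = h$counts),
              modes = modes, bandwidth = bw, n = length(gc))
  class(out) <- "density_curve"
  out
}
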