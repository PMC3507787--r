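#' Canonical k-mer spectrum of a read set
#'
#' Counts every length-`k` window containing only `A/C/G/T` once, after
#' canonicalization (the lexicographically smaller of the k-mer and its
#' reverse complement), and tabulates how many distinct canonical k-mers
#' occur at each multiplicity. Windows containing `N` are skipped. `k`
#' must be odd so that no k-mer is its own reverse complement.
#'
#' @param reads `DNAStringSet` or character vector of reads.
#' @param k Odd integer >= 3 (default 17).
#' @return Object of class `kmer_spectrum`: list with `k`, `histogram`
#'   (data frame `multiplicity`, `n_kmers`, sorted by multiplicity) and
#'   `total_instances` (= sum of multiplicity * n_kmers = number of valid
#'   windows counted).
#' @export
count_kmer_spectrum <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  if (k %% 2L == 0L) {
    stop("k must be odd (even k admits self-complementary k-mers)")
  }
  seqs <- if (is.character(reads)) reads else as.character(reads)
  if (length(seqs) == 0L) stop("no reads supplied")
  if (max(nchar(seqs)) < k) stop("k exceeds every read length")
  m <- .kmer_spectrum_cpp(seqs, k)
  if (nrow(m) == 0L) {
    hist <- data.frame(multiplicity = integer(0), n_kmers = integer(0))
  } else {
    hist <- data.frame(multiplicity = m[, 1], n_kmers = m[, 2])
    hist <- hist[order(hist$multiplicity), , drop = FALSE]
    rownames(hist) <- NULL
  }
  out <- list(k = k, histogram = hist,
              total_instances = sum(as.numeric(hist$multiplicity) *
                                      hist$n_kmers))
  class(out) <- "kmer_spectrum"
  out
}

#' Genome-size estimate from a k-mer spectrum
#'
#' Scans the multiplicity histogram upward from m = 1 for the error
#' valley: the first multiplicity at which the k-mer count stops
#' decreasing. If the histogram rises immediately (no error peak at
#' m = 1), the valley is m = 1. The coverage peak is the most populous
#' multiplicity at or beyond the valley, and the genome size is the
#' number of k-mer instances at or beyond the valley divided by the peak
#' multiplicity:
#' \deqn{\hat G = \sum_{m \ge m_{min}} m\,c_m \; / \; m_{peak}.}
#'
#' @param spectrum A `kmer_spectrum`.
#' @return Object of class `genome_size_estimate`: `error_valley`,
#'   `coverage_peak`, `genome_size_bp`, `k`.
#' @export
estimate_genome_size <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  h <- spectrum$histogram
  if (nrow(h) == 0L) stop("empty k-mer spectrum")
  m <- h$multiplicity
  cm <- as.numeric(h$n_kmers)
  # first index where the count stops decreasing (plateaus break toward
  # smaller m); if the histogram only ever decreases there is no peak
  valley_idx <- NA_integer_
  if (nrow(h) == 1L) {
    stop("spectrum lacks coverage peak; depth too low or error rate too high")
  }
  for (i in seq_len(nrow(h) - 1L)) {
    if (cm[i] <= cm[i + 1L]) { valley_idx <- i; break }
  }
  if (is.na(valley_idx)) {
    stop("spectrum lacks coverage peak; depth too low or error rate too high")
  }
  keep <- valley_idx:nrow(h)
  peak_idx <- keep[which.max(cm[keep])]
  m_min <- m[valley_idx]
  m_peak <- m[peak_idx]
  size <- sum(as.numeric(m[keep]) * cm[keep]) / m_peak
  out <- list(error_valley = m_min, coverage_peak = m_peak,
              genome_size_bp = size, k = spectrum$k)
  class(out) <- "genome_size_estimate"
  out
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "Genome size estimate: %s bp (k = %d, error valley m = %d, coverage peak m = %d)\n",
    format(round(x$genome_size_bp), big.mark = ","), x$k,
    x$error_valley, x$coverage_peak))
  invisible(x)
}

#' Write a k-mer spectrum histogram as TSV
#' @param spectrum A `kmer_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(spectrum$histogram, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
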