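#' Single-strand k-mer counts
#'
#' Counts length-`k` windows on the given strand only (no strand
#' canonicalization -- Chargaff's second parity rule is a statement about
#' a single strand). Windows containing `N` are skipped; counts are
#' pooled over all records. All 4^k k-mers are reported, including those
#' with zero count, so downstream pairing is total.
#'
#' @param records `DNAStringSet` or character vector.
#' @param k Word size (default 4; must be <= 12 so the dense 4^k table
#'   stays small).
#' @return Named integer vector of length 4^k (names = k-mers,
#'   lexicographic order).
#' @export
strand_kmer_counts <- function(records, k = 4L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 12L) stop("k > 12 not supported for dense symmetry tables")
  seqs <- if (is.character(records)) records else as.character(records)
  if (length(seqs) == 0L) stop("no records supplied")
  if (max(nchar(seqs)) < k) stop("k exceeds every record length")
  res <- .strand_kmer_counts_cpp(seqs, k)
  all_kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts <- stats::setNames(integer(length(all_kmers)), all_kmers)
  counts[res$kmer] <- res$count
  counts
}

#' Reverse-complement symmetry table
#'
#' Pairs every k-mer with its reverse complement and computes, per pair,
#' the symmetry ratio S = f(w) / (f(w) + f(w-bar)), keyed by the
#' lexicographically smaller member. Palindromic k-mers (their own
#' reverse complement; possible only for even k) are flagged and have
#' S = 0.5 identically. Pairs with zero total count are excluded and
#' counted in the `n_zero_total` attribute.
#'
#' @param counts Named vector from [strand_kmer_counts()].
#' @return Data frame of class `symmetry_table`: `kmer`, `revcomp`,
#'   `f_w`, `f_wbar`, `S`, `palindrome`; attribute `k` and
#'   `n_zero_total`.
#' @export
symmetry_table <- function(counts) {
  kmers <- names(counts)
  if (is.null(kmers)) stop("counts must be a named vector of k-mer counts")
  k <- nchar(kmers[1])
  rc <- revcomp(kmers)
  is_pal <- kmers == rc
  keep <- kmers <= rc  # one row per pair, keyed by smaller member
  w <- kmers[keep]
  wbar <- rc[keep]
  f_w <- unname(counts[w])
  f_wbar <- unname(counts[wbar])
  tot <- f_w + f_wbar
  S <- ifelse(is_pal[keep], 0.5, ifelse(tot > 0, f_w / tot, NA_real_))
  out <- data.frame(kmer = w, revcomp = wbar, f_w = f_w, f_wbar = f_wbar,
                    S = S, palindrome = is_pal[keep],
                    stringsAsFactors = FALSE)
  n_zero <- sum(is.na(out$S))
  out <- out[!is.na(out$S), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "n_zero_total") <- n_zero
  class(out) <- c("symmetry_table", "data.frame")
  out
}

#' Symmetry dispersion summary
#'
#' Summarizes a symmetry table over the non-palindromic pairs with
#' nonzero total count: mean and sample SD of S, the median, the
#' fraction of pairs within `eps` of 0.5, and a histogram of S.
#' Palindromes are excluded because their S is 0.5 by construction and
#' would artificially tighten the distribution.
#'
#' @param table A `symmetry_table`.
#' @param eps Half-width of the symmetry window around 0.5 (default 0.01).
#' @param bin_width Histogram bin width on S (default 0.01).
#' @return List of class `symmetry_summary`: `k`, `eps`, `n_pairs`,
#'   `mean_S`, `sd_S`, `median_S`, `fraction_within_eps`, `histogram`.
#' @export
symmetry_summary <- function(table, eps = 0.01, bin_width = 0.01) {
  stopifnot(inherits(table, "symmetry_table"))
  s <- table$S[!table$palindrome]
  if (length(s) == 0L) stop("no non-palindromic pairs with counts")
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  out <- list(
    k = attr(table, "k"),
    eps = eps,
    n_pairs = length(s),
    mean_S = mean(s),
    sd_S = stats::sd(s),
    median_S = stats::median(s),
    fraction_within_eps = mean(abs(s - 0.5) <= eps),
    histogram = data.frame(bin_lower = utils::head(h$breaks, -1),
                           count = h$counts)
  )
  class(out) <- "symmetry_summary"
  out
}

#' Compare symmetry tightness between two assemblies
#'
#' Reports the dispersion metrics of both summaries and declares the one
#' with the smaller SD of S "tighter" around 0.5 (ties reported as
#' equal). Both summaries must share k and eps.
#'
#' @param summary_a,summary_b `symmetry_summary` objects.
#' @param label_a,label_b Display labels.
#' @return List of class `symmetry_comparison` with per-assembly metrics
#'   and `tighter` (one of the labels, or `"equal"`).
#' @export
compare_symmetry <- function(summary_a, summary_b,
                             label_a = "A", label_b = "B") {
  stopifnot(inherits(summary_a, "symmetry_summary"),
            inherits(summary_b, "symmetry_summary"))
  if (summary_a$k != summary_b$k) stop("summaries computed at different k")
  if (summary_a$eps != summary_b$eps) stop("summaries use different eps")
  tighter <- if (isTRUE(all.equal(summary_a$sd_S, summary_b$sd_S))) {
    "equal"
  } else if (summary_a$sd_S < summary_b$sd_S) label_a else label_b
  out <- list(
    k = summary_a$k, eps = summary_a$eps,
    labels = c(label_a, label_b),
    sd_S = stats::setNames(c(summary_a$sd_S, summary_b$sd_S),
                           c(label_a, label_b)),
    fraction_within_eps = stats::setNames(
      c(summary_a$fraction_within_eps, summary_b$fraction_within_eps),
      c(label_a, label_b)),
    tighter = tighter
  )
  class(out) <- "symmetry_comparison"
  out
}

#' @export
print.symmetry_comparison <- function(x, ...) {
  cat(sprintf("Symmetry comparison at k = %d (eps = %g)\n", x$k, x$eps))
  for (lab in x$labels) {
    cat(sprintf("  %s: sd(S) = %.5f, fraction within eps of 0.5 = %.3f\n",
                lab, x$sd_S[[lab]], x$fraction_within_eps[[lab]]))
  }
  cat("  tighter:", x$tighter, "\n")
  invisible(x)
}
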