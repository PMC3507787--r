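#' Global alignment of a 5'/3' LTR pair
#'
#' End-to-end (Needleman-Wunsch) alignment under affine gap scoring,
#' delegated to [Biostrings::pairwiseAlignment()]. Defaults follow the
#' common nucleotide convention: match +5, mismatch -4, gap open 10,
#' gap extend 0.5 (penalties subtracted). LTR pairs are near-identical,
#' so the scoring choice is second-order for dating.
#'
#' @param five_prime,three_prime Nucleotide strings (or `DNAString`s).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive values).
#' @return List of class `ltr_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `n_valid_columns` (columns
#'   with unambiguous `A/C/G/T` in both rows).
#' @export
align_ltr_pair <- function(five_prime, three_prime, match = 5,
                           mismatch = -4, gap_open = 10, gap_extend = 0.5) {
  a <- toupper(as.character(five_prime))
  b <- toupper(as.character(three_prime))
  if (!nzchar(a) || !nzchar(b)) stop("empty LTR sequence")
  if (!grepl("[ACGT]", a) || !grepl("[ACGT]", b)) {
    stop("LTR sequence contains no unambiguous bases")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  valid <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  out <- list(aligned_a = ga, aligned_b = gb,
              score = Biostrings::score(aln),
              n_valid_columns = sum(valid))
  class(out) <- "ltr_alignment"
  out
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' Over the valid columns of the alignment (both bases in `A/C/G/T`;
#' gap and ambiguous columns removed, i.e. pairwise deletion), computes
#' the transition proportion P (A<->G, C<->T), the transversion
#' proportion Q, and the K2P distance
#' \deqn{K = -\tfrac12 \ln\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].}
#'
#' @param alignment An `ltr_alignment`, or any list with `aligned_a` and
#'   `aligned_b` gapped strings of equal length.
#' @return List of class `k2p_distance`: `P`, `Q`, `K`, `n_valid_columns`.
#' @export
k2p_from_alignment <- function(alignment) {
  ca <- strsplit(toupper(alignment$aligned_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(alignment$aligned_b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  acgt <- c("A", "C", "G", "T")
  valid <- ca %in% acgt & cb %in% acgt
  n <- sum(valid)
  if (n == 0L) stop("alignment has no valid (unambiguous, ungapped) columns")
  x <- ca[valid]; y <- cb[valid]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  k2p_distance(P, Q, n_valid_columns = n)
}

#' K2P distance from transition/transversion proportions
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @param n_valid_columns Optional number of sites (carried through).
#' @return List of class `k2p_distance`: `P`, `Q`, `K`,
#'   `n_valid_columns`.
#' @export
k2p_distance <- function(P, Q, n_valid_columns = NA_integer_) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(sprintf(
      "K2P distance saturated (P = %.4f, Q = %.4f): 1-2P-Q = %.4f, 1-2Q = %.4f",
      P, Q, w1, w2))
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  out <- list(P = P, Q = Q, K = K, n_valid_columns = n_valid_columns)
  class(out) <- "k2p_distance"
  out
}

#' Insertion age from a K2P distance
#'
#' The two LTRs of a retrotransposon are identical at insertion time and
#' diverge thereafter on two independent branches, so their pairwise
#' distance K accumulates at rate 2r and the insertion age is
#' \deqn{T = K / (2r)} years, with r the substitution rate per site per
#' year (default 1.3e-8, the rate commonly adopted for plant LTRs).
#'
#' @param K K2P distance (substitutions/site), or a `k2p_distance`.
#' @param rate Substitution rate r per site per year.
#' @return Age in years.
#' @export
insertion_age <- function(K, rate = 1.3e-8) {
  if (inherits(K, "k2p_distance")) K <- K$K
  stopifnot(is.numeric(K), all(K >= 0))
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  K / (2 * rate)
}

#' Date a collection of LTR pairs
#'
#' Runs alignment, K2P estimation and age conversion for each element of
#' an `ltr_pairs` table. Saturated pairs (K2P out of domain) are not
#' clamped: they are dropped from the result and counted in the
#' `n_saturated` attribute.
#'
#' @param pairs An `ltr_pairs` data frame.
#' @param rate Substitution rate per site per year.
#' @param ... Scoring parameters passed to [align_ltr_pair()].
#' @return Data frame (`element_id`, `P`, `Q`, `K`, `T_years`,
#'   `n_valid_columns`) with attribute `n_saturated`.
#' @export
ltr_insertion_ages <- function(pairs, rate = 1.3e-8, ...) {
  stopifnot(inherits(pairs, "ltr_pairs") || is.data.frame(pairs))
  rows <- vector("list", nrow(pairs))
  n_sat <- 0L
  for (i in seq_len(nrow(pairs))) {
    aln <- align_ltr_pair(pairs$five_prime[i], pairs$three_prime[i], ...)
    d <- tryCatch(k2p_from_alignment(aln), error = function(e) e)
    if (inherits(d, "error")) {
      n_sat <- n_sat + 1L
      next
    }
    rows[[i]] <- data.frame(
      element_id = pairs$element_id[i], P = d$P, Q = d$Q, K = d$K,
      T_years = insertion_age(d$K, rate),
      n_valid_columns = d$n_valid_columns,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("all pairs saturated; no ages estimable")
  rownames(out) <- NULL
  attr(out, "n_saturated") <- n_sat
  out
}

#' Insertion-age frequency distribution
#'
#' Bins ages into half-open intervals `[lower, lower + width)` starting
#' at 0 and reports the modal bin and the oldest insertion.
#'
#' @param ages_years Numeric vector of ages (years), all >= 0.
#' @param bin_width Bin width in years (default 5e5).
#' @return List of class `age_distribution`: `bin_width`, `bins` (data
#'   frame `lower`, `count`), `n_elements`, `max_age`, `modal_bin_lower`.
#' @export
age_distribution <- function(ages_years, bin_width = 5e5) {
  if (length(ages_years) == 0L) stop("no ages supplied")
  stopifnot(all(ages_years >= 0), bin_width > 0)
  idx <- floor(ages_years / bin_width)
  tab <- table(idx)
  lower <- as.numeric(names(tab)) * bin_width
  bins <- data.frame(lower = lower, count = as.integer(tab))
  bins <- bins[order(bins$lower), , drop = FALSE]
  rownames(bins) <- NULL
  out <- list(bin_width = bin_width, bins = bins,
              n_elements = length(ages_years),
              max_age = max(ages_years),
              modal_bin_lower = bins$lower[which.max(bins$count)])
  class(out) <- "age_distribution"
  out
}

#' @export
print.age_distribution <- function(x, ...) {
  cat(sprintf(
    "Insertion ages: n = %d, modal bin [%.2f, %.2f) My, oldest %.2f My\n",
    x$n_elements, x$modal_bin_lower / 1e6,
    (x$modal_bin_lower + x$bin_width) / 1e6, x$max_age / 1e6))
  invisible(x)
}
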