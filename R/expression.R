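#' log2-transform an FPKM table
#'
#' Either drops zero cells (setting them `NA` and counting them in the
#' `n_dropped` attribute) or applies a pseudocount `log2(FPKM + c)`.
#'
#' @param table Expression matrix (genes x organs, FPKM).
#' @param zero_policy `"drop"` or `"pseudocount"`.
#' @param pseudocount Positive constant c for the pseudocount policy.
#' @return Matrix of log2 values; attribute `n_dropped` counts excluded
#'   zero cells under the drop policy.
#' @export
log2_fpkm <- function(table, zero_policy = c("drop", "pseudocount"),
                      pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  m <- expression_table(table)
  if (zero_policy == "pseudocount") {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    out <- log2(m + pseudocount)
    attr(out, "n_dropped") <- 0L
  } else {
    out <- m
    zero <- m == 0
    out[zero] <- NA_real_
    out[!zero] <- log2(m[!zero])
    attr(out, "n_dropped") <- sum(zero)
  }
  out
}

#' GC-binned expression histograms
#'
#' Assigns each transcript to a half-open GC bin (`[0, gc_bin)`,
#' `[gc_bin, 2 gc_bin)`, ...; lower edge inclusive) and histograms the
#' log2 FPKM values within each bin at `expr_bin` width. Also reports
#' the (GC bin, expression bin) cell of maximum count.
#'
#' @param table Expression matrix (FPKM); all columns are pooled.
#' @param gc_profile A `composition_profile` covering every table id.
#' @param gc_bin GC bin width (default 0.20).
#' @param expr_bin log2 FPKM bin width (default 0.5).
#' @param zero_policy Passed to [log2_fpkm()].
#' @return List of class `gc_binned_expression`: `cells` (data frame
#'   `gc_bin_lower`, `expr_bin_lower`, `count`), `max_cell`,
#'   `n_transcripts` (transcripts contributing at least one cell).
#' @export
gc_binned_expression <- function(table, gc_profile, gc_bin = 0.20,
                                 expr_bin = 0.5, zero_policy = "drop") {
  m <- log2_fpkm(table, zero_policy = zero_policy)
  missing_ids <- setdiff(rownames(m), gc_profile$id)
  if (length(missing_ids) > 0L) {
    stop("ids missing from GC profile: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  gc <- gc_profile$gc[match(rownames(m), gc_profile$id)]
  gbin <- floor(gc / gc_bin) * gc_bin
  rows <- list()
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    keep <- !is.na(v)
    if (!any(keep)) next
    ebin <- floor(v[keep] / expr_bin) * expr_bin
    rows[[j]] <- data.frame(gc_bin_lower = gbin[keep],
                            expr_bin_lower = ebin)
  }
  all_cells <- do.call(rbind, rows)
  if (is.null(all_cells) || nrow(all_cells) == 0L) {
    stop("no nonzero cells to bin")
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(all_cells))),
                          by = all_cells, FUN = sum)
  agg <- agg[order(agg$gc_bin_lower, agg$expr_bin_lower), , drop = FALSE]
  rownames(agg) <- NULL
  max_cell <- agg[which.max(agg$count), , drop = FALSE]
  out <- list(cells = agg, max_cell = max_cell,
              gc_bin = gc_bin, expr_bin = expr_bin,
              n_values = nrow(all_cells))
  class(out) <- "gc_binned_expression"
  out
}

#' Normalize an expression table to its EF1A row
#'
#' Divides every cell by the same-column FPKM of the designated
#' housekeeping gene (elongation factor 1-alpha), which must be present
#' and positive in every column; its row becomes identically 1. The
#' result is invariant to rescaling any column by a constant, which is
#' what makes cross-species comparison meaningful.
#'
#' @param table Expression matrix (FPKM).
#' @param ef1a_id Row identifier of the reference gene.
#' @return Normalized matrix (same dimnames).
#' @export
ef1a_normalize <- function(table, ef1a_id) {
  m <- expression_table(table)
  if (!ef1a_id %in% rownames(m)) {
    stop("EF1A id '", ef1a_id, "' not in the table")
  }
  ref <- m[ef1a_id, ]
  bad <- colnames(m)[ref <= 0]
  if (length(bad) > 0L) {
    stop("EF1A has zero FPKM in column '", bad[1], "'")
  }
  sweep(m, 2, ref, "/")
}

#' Cross-species differential expression indices (EF1A-normalized)
#'
#' For each mapped gene, computes
#' `log2[(FPKM_gene / FPKM_EF1A)_ref / (FPKM_gene / FPKM_EF1A)_other]`
#' in one organ. The index of EF1A against itself is 0, and swapping the
#' two species negates every index. Genes with zero normalized abundance
#' in either species are excluded and counted; unmapped table genes are
#' skipped with a count.
#'
#' @param ref_table,other_table Expression matrices (FPKM).
#' @param ortholog_map Data frame (`ref_id`, `other_id`).
#' @param ef1a_ref,ef1a_other EF1A row ids in the two tables.
#' @param organ Organ column present in both tables (default `"leaf"`).
#' @return Data frame of class `differential_index` (`ref_id`,
#'   `other_id`, `index`), attributes `n_zero_excluded`, `n_unmapped`.
#' @export
differential_index <- function(ref_table, other_table, ortholog_map,
                               ef1a_ref, ef1a_other, organ = "leaf") {
  for (m in list(ref_table, other_table)) {
    if (!organ %in% colnames(m)) stop("organ '", organ, "' missing")
  }
  ref_n <- ef1a_normalize(ref_table, ef1a_ref)[, organ]
  oth_n <- ef1a_normalize(other_table, ef1a_other)[, organ]
  map <- ortholog_map[ortholog_map$ref_id %in% names(ref_n) &
                        ortholog_map$other_id %in% names(oth_n), ,
                      drop = FALSE]
  n_unmapped <- nrow(ortholog_map) - nrow(map)
  if (nrow(map) == 0L) stop("no mapped genes present in both tables")
  a <- ref_n[map$ref_id]
  b <- oth_n[map$other_id]
  nonzero <- a > 0 & b > 0
  out <- data.frame(ref_id = map$ref_id[nonzero],
                    other_id = map$other_id[nonzero],
                    index = log2(a[nonzero] / b[nonzero]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_zero_excluded") <- sum(!nonzero)
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("differential_index", "data.frame")
  out
}

#' Top and bottom expressed genes in one organ
#'
#' Ranks by descending FPKM with deterministic tie-break by gene id and
#' returns the top-n and bottom-n identifiers together with a
#' heat-map-ready log2 FPKM matrix over all organs for their union.
#'
#' @param table Expression matrix (FPKM).
#' @param organ Organ column.
#' @param n Set size.
#' @param zero_policy Passed to [log2_fpkm()] for the matrix.
#' @return List of class `top_bottom`: `top`, `bottom` (id vectors),
#'   `matrix` (union x organs, log2 FPKM).
#' @export
top_bottom <- function(table, organ, n, zero_policy = "pseudocount") {
  m <- expression_table(table)
  if (!organ %in% colnames(m)) stop("organ '", organ, "' missing")
  if (n < 1) stop("n must be >= 1")
  if (nrow(m) < 2L * n) stop("need at least ", 2L * n, " genes")
  ids <- rownames(m)
  ord <- order(-m[, organ], ids)
  top <- ids[ord[seq_len(n)]]
  bottom <- ids[rev(ord)[seq_len(n)]]
  union_ids <- unique(c(top, bottom))
  lm <- log2_fpkm(m[union_ids, , drop = FALSE], zero_policy = zero_policy)
  out <- list(top = top, bottom = bottom, matrix = lm, organ = organ)
  class(out) <- "top_bottom"
  out
}

#' Unique loci behind the top unannotated transcripts
#'
#' Per organ, selects the `n` highest-FPKM transcripts among those not
#' flagged as annotated, unions the selections across organs, collapses
#' transcripts to their loci and reports the unique locus set with its
#' expression matrix.
#'
#' @param table Expression matrix (transcripts x organs, FPKM).
#' @param annotated Logical vector or character vector: transcripts that
#'   carry an annotation (these are excluded). A character vector is
#'   treated as the set of annotated ids.
#' @param locus_map Data frame (`transcript_id`, `locus_id`).
#' @param n Transcripts taken per organ (default 300).
#' @return List of class `unannotated_loci`: `loci` (unique locus ids),
#'   `n_unique`, `transcripts` (selected transcript union), `matrix`
#'   (selected transcripts x organs, FPKM).
#' @export
unannotated_top_loci <- function(table, annotated, locus_map, n = 300L) {
  m <- expression_table(table)
  ids <- rownames(m)
  if (is.character(annotated)) annotated <- ids %in% annotated
  stopifnot(length(annotated) == nrow(m))
  cand <- ids[!annotated]
  if (length(cand) == 0L) {
    out <- list(loci = character(0), n_unique = 0L,
                transcripts = character(0),
                matrix = m[character(0), , drop = FALSE])
    class(out) <- "unannotated_loci"
    return(out)
  }
  sel <- character(0)
  for (organ in colnames(m)) {
    v <- m[cand, organ]
    ord <- order(-v, cand)
    sel <- union(sel, cand[ord[seq_len(min(n, length(cand)))]])
  }
  sel <- sort(sel)
  missing_locus <- setdiff(sel, locus_map$transcript_id)
  if (length(missing_locus) > 0L) {
    stop("no locus mapping for transcript: ", missing_locus[1])
  }
  loci <- sort(unique(locus_map$locus_id[
    match(sel, locus_map$transcript_id)]))
  out <- list(loci = loci, n_unique = length(loci), transcripts = sel,
              matrix = m[sel, , drop = FALSE])
  class(out) <- "unannotated_loci"
  out
}
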