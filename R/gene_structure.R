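#' Derive introns from a gene-model table
#'
#' Introns are the gaps between consecutive exons in genomic order:
#' `[exon_i.end + 1, exon_{i+1}.start - 1]` (1-based inclusive). A gene
#' with n exons yields n - 1 introns; single-exon genes yield none.
#'
#' @param models A `gene_models` table (one or more genes).
#' @return Data frame: `gene_id`, `scaffold`, `strand`, `start`, `end`,
#'   one row per intron, genomic order within gene.
#' @export
derive_introns <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  by_gene <- split(seq_len(nrow(models)), models$gene_id)
  rows <- lapply(by_gene, function(idx) {
    if (length(idx) < 2L) return(NULL)
    data.frame(gene_id = models$gene_id[idx[1]],
               scaffold = models$scaffold[idx[1]],
               strand = models$strand[idx[1]],
               start = models$end[idx[-length(idx)]] + 1L,
               end = models$start[idx[-1]] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), scaffold = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Total intron length per gene
#' @param models A `gene_models` table.
#' @return Named numeric vector (0 for single-exon genes).
#' @export
total_intron_length <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ids <- sort(unique(models$gene_id))
  introns <- derive_introns(models)
  len <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(introns) > 0L) {
    s <- tapply(introns$end - introns$start + 1, introns$gene_id, sum)
    len[names(s)] <- s
  }
  len
}

#' Gene-structure summary statistics
#'
#' Per-gene statistics aggregated to mean and sample SD (n - 1):
#' gene length (exons + introns), exon length (over all exons), intron
#' length (over all introns), exons and introns per gene, and exonic /
#' intronic GC percent. GC is computed over the concatenated exonic
#' (resp. intronic) sequence of each gene, then averaged across genes.
#'
#' @param models A `gene_models` table.
#' @param genome `DNAStringSet` containing every scaffold the models
#'   reference.
#' @return List of class `structure_summary` with `n_genes` and a
#'   `stats` data frame (`feature`, `mean`, `sd`).
#' @export
structure_summary <- function(models, genome) {
  stopifnot(inherits(models, "gene_models"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (nrow(models) == 0L) stop("empty gene-model set")
  missing_sc <- setdiff(unique(models$scaffold), names(genome))
  if (length(missing_sc) > 0L) {
    stop("scaffold not in genome: ", missing_sc[1])
  }
  sc_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(models$end > sc_len[models$scaffold])) {
    stop("gene model extends beyond the end of its scaffold")
  }
  introns <- derive_introns(models)
  by_gene <- split(seq_len(nrow(models)), models$gene_id)
  ids <- names(by_gene)
  n_ex <- vapply(by_gene, length, integer(1))
  span <- vapply(by_gene, function(idx) {
    max(models$end[idx]) - min(models$start[idx]) + 1
  }, numeric(1))
  exon_lens <- models$end - models$start + 1
  intron_lens <- if (nrow(introns)) introns$end - introns$start + 1 else numeric(0)

  gc_of <- function(tab) {
    # per-gene GC over concatenated parts; NA for genes with no parts
    out <- stats::setNames(rep(NA_real_, length(ids)), ids)
    if (nrow(tab) == 0L) return(out)
    gcp <- numeric(nrow(tab))
    tot <- numeric(nrow(tab))
    for (sc in unique(tab$scaffold)) {
      sel <- which(tab$scaffold == sc)
      seqs <- Biostrings::extractAt(
        genome[[sc]],
        IRanges::IRanges(start = tab$start[sel], end = tab$end[sel]))
      freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
      gcp[sel] <- freq[, "G"] + freq[, "C"]
      tot[sel] <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    }
    gg <- tapply(gcp, tab$gene_id, sum) / tapply(tot, tab$gene_id, sum)
    out[names(gg)] <- gg
    out
  }
  exonic_gc <- gc_of(as.data.frame(models))
  intronic_gc <- gc_of(introns)

  row <- function(feature, x) {
    x <- x[!is.na(x)]
    data.frame(feature = feature, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  }
  stats_df <- rbind(
    row("gene_length", span),
    row("exon_length", exon_lens),
    row("intron_length", intron_lens),
    row("exons_per_gene", as.numeric(n_ex)),
    row("introns_per_gene", as.numeric(n_ex - 1L)),
    row("exonic_gc_pct", 100 * exonic_gc),
    row("intronic_gc_pct", 100 * intronic_gc))
  out <- list(n_genes = length(ids), stats = stats_df)
  class(out) <- "structure_summary"
  out
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("Gene-structure summary (", x$n_genes, " genes)\n", sep = "")
  df <- x$stats
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-18s mean %10.2f  sd %10.2f\n",
                df$feature[i], df$mean[i], df$sd[i]))
  }
  invisible(x)
}

#' First exon and first intron per gene (transcript orientation)
#'
#' "First" follows the transcript's 5' end: for minus-strand genes the
#' genomically last exon/intron is the first.
#'
#' @param models A `gene_models` table.
#' @return Data frame: `gene_id`, `strand`, `first_exon_start/end`,
#'   `first_intron_start/end` (NA for single-exon genes).
#' @export
first_elements <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  introns <- derive_introns(models)
  by_gene <- split(seq_len(nrow(models)), models$gene_id)
  int_by_gene <- split(seq_len(nrow(introns)), introns$gene_id)
  rows <- lapply(names(by_gene), function(gid) {
    idx <- by_gene[[gid]]
    st <- models$strand[idx[1]]
    e_idx <- if (st == "+") idx[1] else idx[length(idx)]
    ii <- int_by_gene[[gid]]
    if (is.null(ii)) {
      fi_s <- NA_integer_; fi_e <- NA_integer_
    } else {
      i_idx <- if (st == "+") ii[1] else ii[length(ii)]
      fi_s <- introns$start[i_idx]; fi_e <- introns$end[i_idx]
    }
    data.frame(gene_id = gid, strand = st,
               first_exon_start = models$start[e_idx],
               first_exon_end = models$end[e_idx],
               first_intron_start = fi_s, first_intron_end = fi_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structure of the most- and least-expressed genes
#'
#' Ranks the genes shared between the expression table and the model set
#' by FPKM in one organ (ties broken by gene id) and contrasts the mean
#' and SD of exon and intron lengths between the top-n and bottom-n
#' sets. An optional id filter restricts the ranking to a subset (e.g.
#' genes carrying a functional annotation).
#'
#' @param models A `gene_models` table.
#' @param expression Expression matrix (genes x organs).
#' @param organ Organ column to rank by.
#' @param n Set size (default 10).
#' @param id_filter Optional character vector of eligible gene ids.
#' @return List of class `structure_expression`: `organ`, `n`,
#'   `top`/`bottom` (each: `gene_ids`, `mean_intron_length`,
#'   `sd_intron_length`, `mean_exon_length`, `sd_exon_length`), and
#'   `per_gene` (structure listing for the union).
#' @export
structure_vs_expression <- function(models, expression, organ, n = 10L,
                                    id_filter = NULL) {
  stopifnot(inherits(models, "gene_models"))
  if (!organ %in% colnames(expression)) {
    stop("organ '", organ, "' absent from expression table")
  }
  ids <- intersect(rownames(expression), unique(models$gene_id))
  if (!is.null(id_filter)) ids <- intersect(ids, id_filter)
  if (length(ids) < 2L * n) {
    stop("need at least ", 2L * n, " genes present in both inputs")
  }
  fpkm <- expression[ids, organ]
  ord <- order(-fpkm, ids)  # descending FPKM, ties by id
  top_ids <- ids[ord[seq_len(n)]]
  bottom_ids <- ids[rev(ord)[seq_len(n)]]
  exon_lens <- models$end - models$start + 1
  introns <- derive_introns(models)
  intron_lens <- if (nrow(introns)) introns$end - introns$start + 1 else numeric(0)
  set_stats <- function(set) {
    ex <- exon_lens[models$gene_id %in% set]
    il <- intron_lens[introns$gene_id %in% set]
    # a set whose genes carry no introns has mean intron size 0
    list(gene_ids = set,
         mean_exon_length = mean(ex),
         sd_exon_length = stats::sd(ex),
         n_introns = length(il),
         mean_intron_length = if (length(il)) mean(il) else 0,
         sd_intron_length = if (length(il) > 1) stats::sd(il) else NA_real_)
  }
  union_ids <- c(top_ids, bottom_ids)
  per_gene <- data.frame(
    gene_id = union_ids,
    set = rep(c("top", "bottom"), each = n),
    fpkm = expression[union_ids, organ],
    n_exons = vapply(union_ids, function(g) sum(models$gene_id == g),
                     integer(1)),
    total_intron_length = total_intron_length(models)[union_ids],
    stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  out <- list(organ = organ, n = n,
              top = set_stats(top_ids), bottom = set_stats(bottom_ids),
              per_gene = per_gene)
  class(out) <- "structure_expression"
  out
}
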