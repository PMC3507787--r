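#' Read nucleotide sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' package-wide sequence conventions: sequences are uppercased, FASTQ
#' qualities are validated by the parser but discarded, and characters
#' outside `A/C/G/T/N` are either rejected or mapped to `N`.
#'
#' @param path Path to a FASTA or FASTQ file (plain or gzipped).
#' @param format `"fasta"` or `"fastq"`.
#' @param invalid What to do with IUPAC ambiguity codes other than `N`
#'   (and any other non-ACGTN letter): `"error"` rejects the file naming
#'   the offending character, `"mask"` silently converts them to `N`.
#' @return A [Biostrings::DNAStringSet] with one element per record,
#'   input order preserved, names set to the record identifiers (first
#'   whitespace-delimited token of the header).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           invalid = c("error", "mask")) {
  format <- match.arg(format)
  invalid <- match.arg(invalid)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (invalid == "error") {
      offending <- regmatches(seqs[bad][1],
                              regexpr("[^ACGTN]", seqs[bad][1]))
      stop("record '", names(x)[bad][1], "' contains invalid character '",
           offending, "'; use invalid = \"mask\" to convert to N")
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' Deterministic FASTA writer: identical input always yields a
#' byte-identical file. `read_sequences()` on the output recovers the
#' identifiers, sequences and order exactly.
#'
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  stopifnot(width >= 1)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = as.integer(width))
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file bearing `gene`/`mRNA`/`exon` features into the
#' package's gene-model table (see [gene_models()]). Exons are grouped by
#' their `Parent` attribute; one model is produced per mRNA, or per gene
#' when exons attach directly to genes. Coordinates stay in the 1-based
#' inclusive convention used throughout Bioconductor.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` data frame: one row per exon with columns
#'   `gene_id`, `scaffold`, `strand`, `start`, `end`, exons sorted by
#'   genomic start within each model.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  exons <- gff[type == "exon"]
  if (length(exons) == 0L) stop("no exon features in ", path)
  parents <- gff$Parent
  par1 <- vapply(as.list(parents[type == "exon"]), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1]]
  }, character(1))
  if (anyNA(par1)) stop("exon without a Parent attribute in ", path)
  known <- gff$ID[type %in% c("gene", "mRNA")]
  missing_parent <- setdiff(unique(par1), known)
  if (length(missing_parent) > 0L) {
    stop("exon Parent not resolvable to a gene/mRNA feature: ",
         paste(utils::head(missing_parent, 3), collapse = ", "))
  }
  df <- data.frame(
    gene_id = par1,
    scaffold = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    stringsAsFactors = FALSE
  )
  gene_models(df)
}

#' Construct / validate a gene-model table
#'
#' The package represents a set of gene models as a plain data frame with
#' one row per exon: columns `gene_id`, `scaffold`, `strand` (`+`/`-`),
#' `start`, `end` (1-based inclusive). Exons of one model must be
#' non-overlapping and separated by at least 1 bp (the intron); they are
#' stored sorted by genomic start.
#'
#' @param df Data frame with the columns above.
#' @return The validated, sorted data frame with class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "scaffold", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$end < df$start)) stop("exon with end < start")
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # overlapping or abutting exons within one model are malformed
  by_gene <- split(seq_len(nrow(df)), df$gene_id)
  for (idx in by_gene) {
    if (length(idx) > 1L) {
      s <- df$start[idx]; e <- df$end[idx]
      if (any(s[-1] <= e[-length(e)])) {
        stop("overlapping or abutting exons in gene '", df$gene_id[idx[1]], "'")
      }
      if (length(unique(df$strand[idx])) != 1L ||
          length(unique(df$scaffold[idx])) != 1L) {
        stop("inconsistent strand/scaffold within gene '",
             df$gene_id[idx[1]], "'")
      }
    }
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read an expression table (genes x organs/species, FPKM)
#'
#' Expects a header line whose first column holds gene identifiers and
#' whose remaining columns hold organ or species labels; cells are FPKM
#' values, finite and non-negative. Duplicate gene identifiers and
#' missing or negative cells are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, rownames = gene ids, colnames = organ labels.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs an id column plus data")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id: ", ids[duplicated(ids)][1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0L) {
      stop("non-numeric FPKM at row ", ids[bad[1]],
           ", column ", names(vals)[j])
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (anyNA(m)) stop("missing FPKM cell in ", path)
  if (any(m < 0)) stop("negative FPKM (must be >= 0) in ", path)
  rownames(m) <- ids
  expression_table(m)
}

#' Validate an expression matrix
#' @param m Numeric matrix, rownames gene ids, colnames organ labels.
#' @return `m` with class attribute checked (returned as plain matrix).
#' @export
expression_table <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs row (gene) and column (organ) names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite FPKM cell")
  if (any(m < 0)) stop("negative FPKM")
  m
}

#' Read an ortholog map (two-column TSV: ref_id, other_id)
#' @param path Path to a tab-separated file with a header.
#' @return Data frame with columns `ref_id`, `other_id`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog map needs two columns")
  out <- data.frame(ref_id = as.character(df[[1]]),
                    other_id = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$ref_id)) stop("duplicate reference id in ortholog map")
  out
}

#' Read LTR pairs from a paired FASTA
#'
#' Elements are identified by FASTA ids of the form `<element>_5p` and
#' `<element>_3p`; each element must have exactly one of each.
#'
#' @param path Paired FASTA file.
#' @return An `ltr_pairs` data frame (`element_id`, `five_prime`,
#'   `three_prime`).
#' @export
read_ltr_pairs <- function(path) {
  x <- read_sequences(path, format = "fasta")
  ids <- names(x)
  is5 <- grepl("_5p$", ids)
  is3 <- grepl("_3p$", ids)
  if (!all(is5 | is3)) {
    stop("ids must end in _5p or _3p; offending: ",
         ids[!(is5 | is3)][1])
  }
  el5 <- sub("_5p$", "", ids[is5])
  el3 <- sub("_3p$", "", ids[is3])
  if (!setequal(el5, el3) || anyDuplicated(el5) || anyDuplicated(el3)) {
    stop("each element needs exactly one _5p and one _3p sequence")
  }
  el <- sort(unique(el5))
  seqs <- as.character(x)
  ltr_pairs(data.frame(
    element_id = el,
    five_prime = unname(seqs[match(paste0(el, "_5p"), ids)]),
    three_prime = unname(seqs[match(paste0(el, "_3p"), ids)]),
    stringsAsFactors = FALSE
  ))
}

#' Construct / validate an LTR pair table
#' @param df Data frame with columns `element_id`, `five_prime`,
#'   `three_prime` (nucleotide strings).
#' @return The data frame with class `ltr_pairs`.
#' @export
ltr_pairs <- function(df) {
  need <- c("element_id", "five_prime", "three_prime")
  if (!all(need %in% names(df))) {
    stop("ltr pair table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(df$five_prime)) || any(!nzchar(df$three_prime))) {
    stop("empty LTR sequence")
  }
  if (anyDuplicated(df$element_id)) stop("duplicate element_id")
  rownames(df) <- NULL
  class(df) <- c("ltr_pairs", "data.frame")
  df
}

#' Assembly length statistics (N50/N90)
#'
#' Nx is defined as the length of the sequence at which the descending
#' cumulative length first reaches x% of the assembly total.
#'
#' @param x `DNAStringSet`, or a numeric vector of sequence lengths.
#' @return List of class `assembly_stats`: `n_sequences`, `total_length`,
#'   `longest`, `n50`, `n90`.
#' @export
assembly_stats <- function(x) {
  len <- if (is.numeric(x)) as.numeric(x) else as.numeric(Biostrings::width(x))
  if (length(len) == 0L) stop("assembly_stats needs at least one sequence")
  if (any(len <= 0)) stop("sequences must have positive length")
  len <- sort(len, decreasing = TRUE)
  total <- sum(len)
  cum <- cumsum(len)
  nx <- function(frac) len[which(cum >= frac * total)[1]]
  out <- list(n_sequences = length(len), total_length = total,
              longest = len[1], n50 = nx(0.5), n90 = nx(0.9))
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n",
      "  sequences:    ", x$n_sequences, "\n",
      "  total length: ", format(x$total_length, big.mark = ","), " bp\n",
      "  longest:      ", format(x$longest, big.mark = ","), " bp\n",
      "  N50:          ", format(x$n50, big.mark = ","), " bp\n",
      "  N90:          ", format(x$n90, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Reverse complement of plain character sequences
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
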