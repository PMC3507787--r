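#' @useDynLib draftqc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_spec_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("spec must carry an integer seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# uniform integer draws on [lo, hi], safe when lo == hi
sample_int_range <- function(lo, hi, n) {
  if (lo == hi) rep.int(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

sample_bases <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

#' Specification for a synthetic genome with mixture GC composition
#'
#' Bases are i.i.d. within segments; each segment's GC level is drawn
#' from a finite mixture, which produces the bimodal GC landscapes seen
#' in many plant genomes.
#'
#' @param length Genome length in bp.
#' @param gc_components Data frame (`gc_mean`, `weight`) or list of
#'   `c(gc_mean, weight)` pairs; weights must sum to 1, means in (0,1).
#' @param segment_length Granularity (bp) at which a GC component is
#'   chosen (default 1000).
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(length, gc_components = data.frame(
                          gc_mean = 0.35, weight = 1),
                        segment_length = 1000L, seed = 1L) {
  if (is.list(gc_components) && !is.data.frame(gc_components)) {
    gc_components <- do.call(rbind, lapply(gc_components, function(p) {
      data.frame(gc_mean = p[1], weight = p[2])
    }))
  }
  stopifnot(all(gc_components$gc_mean > 0 & gc_components$gc_mean < 1),
            abs(sum(gc_components$weight) - 1) < 1e-8,
            length >= segment_length, segment_length >= 1)
  out <- list(length = as.integer(length), gc_components = gc_components,
              segment_length = as.integer(segment_length),
              seed = as.integer(seed))
  class(out) <- "genome_spec"
  out
}

#' Generate a synthetic genome
#'
#' @param spec A [genome_spec()].
#' @return List: `genome` (single-element named `DNAStringSet`) and
#'   `truth` (list with `genome_size_bp` and per-segment GC table).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_spec_seed(spec$seed, {
    L <- spec$length
    seg <- spec$segment_length
    n_seg <- ceiling(L / seg)
    comp <- sample.int(nrow(spec$gc_components), n_seg, replace = TRUE,
                       prob = spec$gc_components$weight)
    gc_seg <- spec$gc_components$gc_mean[comp]
    gc_base <- rep(gc_seg, each = seg)[seq_len(L)]
    is_gc <- stats::runif(L) < gc_base
    coin <- stats::runif(L) < 0.5
    bases <- ifelse(is_gc, ifelse(coin, "G", "C"), ifelse(coin, "A", "T"))
    genome <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
    names(genome) <- "synthetic_genome"
    seg_start <- (seq_len(n_seg) - 1L) * seg + 1L
    truth <- list(
      genome_size_bp = L,
      segments = data.frame(start = seg_start,
                            end = pmin(seg_start + seg - 1L, L),
                            gc_mean = gc_seg))
    list(genome = genome, truth = truth)
  })
}

#' Specification for planting LTR retrotransposons
#'
#' Each element is built from one ancestral LTR whose 5' and 3' copies
#' then evolve independently for the element's age under an exact
#' Kimura two-parameter substitution process (per-site transition
#' probabilities from the K2P matrix exponential at branch length
#' `rate_r * age`), so the expected pairwise distance between the two
#' copies is `2 * rate_r * age` for any age.
#'
#' @param n_elements Number of elements to plant.
#' @param ltr_length_range `c(min, max)` LTR length in bp.
#' @param internal_length_range `c(min, max)` internal-region length.
#' @param age_components Data frame (`age_mode`, `sdlog`, `weight`):
#'   ages in years are drawn from a mixture of log-normals, each
#'   parameterized by its mode (the peak of the age histogram) and the
#'   log-scale SD. Real insertion-age distributions are right-skewed,
#'   which the log-normal reproduces; a mode of 0 yields age exactly 0.
#' @param rate_r Substitution rate per site per year (default 1.3e-8).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @return List of class `ltr_plant_spec`.
#' @export
ltr_plant_spec <- function(n_elements, ltr_length_range = c(2000L, 2000L),
                           internal_length_range = c(1000L, 3000L),
                           age_components = data.frame(
                             age_mode = c(1e6, 6e6, 11e6),
                             sdlog = c(0.25, 0.12, 0.08),
                             weight = c(0.7, 0.2, 0.1)),
                           rate_r = 1.3e-8, kappa = 2, seed = 1L) {
  stopifnot(n_elements >= 1, rate_r > 0, kappa > 0,
            all(age_components$age_mode >= 0),
            all(age_components$sdlog >= 0),
            abs(sum(age_components$weight) - 1) < 1e-8,
            ltr_length_range[1] >= 1,
            ltr_length_range[2] >= ltr_length_range[1])
  out <- list(n_elements = as.integer(n_elements),
              ltr_length_range = as.integer(ltr_length_range),
              internal_length_range = as.integer(internal_length_range),
              age_components = age_components,
              rate_r = rate_r, kappa = kappa, seed = as.integer(seed))
  class(out) <- "ltr_plant_spec"
  out
}

# exact K2P per-site substitution probabilities at branch length d
# (expected substitutions/site), transition:transversion rate ratio kappa
k2p_site_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
    0.5 * exp(-2 * (alpha + beta) * d)
  p_tv_each <- 0.25 - 0.25 * exp(-4 * beta * d)
  c(same = 1 - p_ts - 2 * p_tv_each, ts = p_ts, tv_each = p_tv_each)
}

# evolve a base vector for branch length d under K2P
evolve_k2p <- function(bases, d, kappa) {
  p <- k2p_site_probs(d, kappa)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_a <- c(A = "C", G = "C", C = "A", T = "A")
  tv_b <- c(A = "T", G = "T", C = "G", T = "G")
  u <- stats::runif(length(bases))
  coin <- stats::runif(length(bases)) < 0.5
  out <- bases
  is_ts <- u < p[["ts"]]
  is_tv <- !is_ts & u < p[["ts"]] + 2 * p[["tv_each"]]
  out[is_ts] <- ts_partner[bases[is_ts]]
  out[is_tv] <- ifelse(coin[is_tv], tv_a[bases[is_tv]], tv_b[bases[is_tv]])
  out
}

#' Plant LTR retrotransposons into a genome
#'
#' Elements (5' LTR -- internal region -- 3' LTR) are inserted at
#' uniformly drawn, sorted positions; insertion lengthens the sequence,
#' so elements never overlap or nest. The returned truth table records,
#' for each element, its position in the modified genome, the planted
#' age, and the expected divergence `true_expected_K = 2 * rate_r * age`.
#'
#' @param genome Single-sequence `DNAStringSet` (or the list returned by
#'   [generate_genome()]).
#' @param spec An [ltr_plant_spec()].
#' @return List: `genome` (modified), `pairs` (`ltr_pairs` table of the
#'   evolved 5'/3' copies), `truth` (data frame with coordinates, ages,
#'   expected K).
#' @export
plant_ltr_elements <- function(genome, spec) {
  stopifnot(inherits(spec, "ltr_plant_spec"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  gseq <- as.character(genome[[1]])
  gname <- names(genome)[1]
  with_spec_seed(spec$seed, {
    n <- spec$n_elements
    comp <- sample.int(nrow(spec$age_components), n, replace = TRUE,
                       prob = spec$age_components$weight)
    mode_c <- spec$age_components$age_mode[comp]
    sdlog_c <- spec$age_components$sdlog[comp]
    # log-normal with stated mode: meanlog = log(mode) + sdlog^2
    ages <- ifelse(mode_c <= 0, 0,
                   stats::rlnorm(n, meanlog = log(pmax(mode_c, 1e-300)) +
                                   sdlog_c^2, sdlog = sdlog_c))
    ltr_len <- sample_int_range(spec$ltr_length_range[1],
                                spec$ltr_length_range[2], n)
    int_len <- sample_int_range(spec$internal_length_range[1],
                                spec$internal_length_range[2], n)
    five <- character(n); three <- character(n); elem <- character(n)
    for (i in seq_len(n)) {
      anc <- sample_bases(ltr_len[i], 0.5)
      d <- spec$rate_r * ages[i]
      five[i] <- paste0(evolve_k2p(anc, d, spec$kappa), collapse = "")
      three[i] <- paste0(evolve_k2p(anc, d, spec$kappa), collapse = "")
      elem[i] <- paste0(five[i],
                        paste0(sample_bases(int_len[i], 0.5), collapse = ""),
                        three[i])
    }
    # insertion points in the original sequence, sorted
    ins <- sort(sample.int(nchar(gseq) + 1L, n, replace = TRUE)) - 1L
    pieces <- character(2L * n + 1L)
    prev <- 0L
    offset <- 0L
    start_new <- integer(n)
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- substr(gseq, prev + 1L, ins[i])
      pieces[2L * i] <- elem[i]
      start_new[i] <- ins[i] + offset + 1L
      offset <- offset + nchar(elem[i])
      prev <- ins[i]
    }
    pieces[2L * n + 1L] <- substr(gseq, prev + 1L, nchar(gseq))
    new_seq <- paste0(pieces, collapse = "")
    ids <- sprintf("ltr_element_%04d", seq_len(n))
    truth <- data.frame(
      element_id = ids,
      scaffold = gname,
      start = start_new,
      end = start_new + nchar(elem) - 1L,
      ltr5_start = start_new,
      ltr5_end = start_new + ltr_len - 1L,
      ltr3_start = start_new + ltr_len + int_len,
      ltr3_end = start_new + 2L * ltr_len + int_len - 1L,
      ltr_length = ltr_len,
      internal_length = int_len,
      true_age_years = ages,
      true_expected_K = 2 * spec$rate_r * ages,
      stringsAsFactors = FALSE)
    out_genome <- Biostrings::DNAStringSet(new_seq)
    names(out_genome) <- gname
    pairs <- ltr_pairs(data.frame(element_id = ids, five_prime = five,
                                  three_prime = three,
                                  stringsAsFactors = FALSE))
    list(genome = out_genome, pairs = pairs, truth = truth)
  })
}

#' Specification for a synthetic gene set
#'
#' Defaults reproduce the structure statistics typical of a compact
#' plant genome: mean exon length 208.28 bp (SD 210.62), mean intron
#' length 388.62 bp (SD 393.41), mean 3.5 exons per gene (SD 2.96),
#' exonic GC 42.74%, intronic GC 30.04%. Length laws are log-normal
#' (matched to the stated mean/SD by moments) so lengths stay positive;
#' exon counts are a shifted negative binomial over {1, 2, ...} matched
#' to the stated mean/SD.
#'
#' @param n_genes Number of genes.
#' @param exon_count_mean,exon_count_sd Mean/SD of exons per gene.
#' @param exon_length_mean,exon_length_sd Mean/SD of exon length (bp).
#' @param intron_length_mean,intron_length_sd Mean/SD of intron length.
#' @param exonic_gc,intronic_gc GC fractions in (0,1).
#' @param seed Integer seed.
#' @return List of class `gene_set_spec`.
#' @export
gene_set_spec <- function(n_genes, exon_count_mean = 3.5,
                          exon_count_sd = 2.96,
                          exon_length_mean = 208.28,
                          exon_length_sd = 210.62,
                          intron_length_mean = 388.62,
                          intron_length_sd = 393.41,
                          exonic_gc = 0.4274, intronic_gc = 0.3004,
                          seed = 1L) {
  stopifnot(n_genes >= 1, exon_count_mean >= 1,
            exon_length_mean > 0, intron_length_mean > 0,
            exonic_gc > 0, exonic_gc < 1, intronic_gc > 0, intronic_gc < 1)
  out <- list(n_genes = as.integer(n_genes),
              exon_count_mean = exon_count_mean,
              exon_count_sd = exon_count_sd,
              exon_length_mean = exon_length_mean,
              exon_length_sd = exon_length_sd,
              intron_length_mean = intron_length_mean,
              intron_length_sd = intron_length_sd,
              exonic_gc = exonic_gc, intronic_gc = intronic_gc,
              seed = as.integer(seed))
  class(out) <- "gene_set_spec"
  out
}

# log-normal draws matched by moments to (mean, sd), rounded to >= 1 bp
rlnorm_matched <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  x <- stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2,
                     sdlog = sqrt(sdlog2))
  pmax(1L, as.integer(round(x)))
}

# shifted (>= 1) count draws matched to (mean, sd); negative binomial on
# the excess when overdispersed, Poisson otherwise
rcount_matched <- function(n, mean, sd) {
  mu <- mean - 1
  if (mu <= 0) return(rep(1L, n))
  v <- sd^2
  if (v > mu) {
    size <- mu^2 / (v - mu)
    1L + stats::rnbinom(n, size = size, mu = mu)
  } else {
    1L + stats::rpois(n, mu)
  }
}

#' Plant gene models into a genome
#'
#' Genes (alternating exon/intron parts, exonic and intronic base
#' composition enforced by sampling at the target GC) are inserted at
#' uniformly drawn, sorted positions; insertion lengthens the sequence,
#' so genes never overlap. Strand is drawn uniformly.
#'
#' @param genome Single-sequence `DNAStringSet` (or [generate_genome()]
#'   output).
#' @param spec A [gene_set_spec()].
#' @return List: `genome` (modified), `models` (`gene_models` exon
#'   table), `truth` (per-gene data frame: counts, total lengths, age of
#'   structure laws used).
#' @export
plant_gene_models <- function(genome, spec) {
  stopifnot(inherits(spec, "gene_set_spec"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  gseq <- as.character(genome[[1]])
  gname <- names(genome)[1]
  with_spec_seed(spec$seed, {
    n <- spec$n_genes
    n_exons <- rcount_matched(n, spec$exon_count_mean, spec$exon_count_sd)
    n_introns <- n_exons - 1L
    exon_lens <- rlnorm_matched(sum(n_exons), spec$exon_length_mean,
                                spec$exon_length_sd)
    intron_lens <- rlnorm_matched(sum(n_introns), spec$intron_length_mean,
                                  spec$intron_length_sd)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # pooled base synthesis per compartment, then sliced per part
    exon_str <- paste0(sample_bases(sum(exon_lens), spec$exonic_gc),
                       collapse = "")
    intron_str <- paste0(sample_bases(sum(intron_lens), spec$intronic_gc),
                         collapse = "")
    exon_end <- cumsum(exon_lens)
    exon_seqs <- substring(exon_str, exon_end - exon_lens + 1L, exon_end)
    if (length(intron_lens) > 0L) {
      intron_end <- cumsum(intron_lens)
      intron_seqs <- substring(intron_str, intron_end - intron_lens + 1L,
                               intron_end)
    } else {
      intron_seqs <- character(0)
    }
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    exon_gene <- rep.int(seq_len(n), n_exons)
    intron_gene <- rep.int(seq_len(n), n_introns)
    exon_by_gene <- split(exon_seqs, exon_gene)
    intron_by_gene <- split(intron_seqs, factor(intron_gene,
                                                levels = seq_len(n)))
    gene_seq <- vapply(seq_len(n), function(i) {
      ex <- exon_by_gene[[i]]
      intr <- intron_by_gene[[i]]
      m <- length(ex)
      parts <- character(2L * m - 1L)
      parts[seq(1L, 2L * m - 1L, by = 2L)] <- ex
      if (m > 1L) parts[seq(2L, 2L * m - 2L, by = 2L)] <- intr
      paste0(parts, collapse = "")
    }, character(1))
    gene_len <- nchar(gene_seq)
    ins <- sort(sample.int(nchar(gseq) + 1L, n, replace = TRUE)) - 1L
    pieces <- character(2L * n + 1L)
    prev <- 0L; offset <- 0L
    gene_start <- integer(n)
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- substr(gseq, prev + 1L, ins[i])
      pieces[2L * i] <- gene_seq[i]
      gene_start[i] <- ins[i] + offset + 1L
      offset <- offset + gene_len[i]
      prev <- ins[i]
    }
    pieces[2L * n + 1L] <- substr(gseq, prev + 1L, nchar(gseq))
    new_seq <- paste0(pieces, collapse = "")
    # exon genomic coordinates from per-gene part layout
    exon_rows <- vector("list", n)
    el_by_gene <- split(exon_lens, exon_gene)
    il_by_gene <- split(intron_lens, factor(intron_gene, levels = seq_len(n)))
    for (i in seq_len(n)) {
      el <- el_by_gene[[i]]
      il <- il_by_gene[[i]]
      m <- length(el)
      part_len <- numeric(2L * m - 1L)
      part_len[seq(1L, 2L * m - 1L, by = 2L)] <- el
      if (m > 1L) part_len[seq(2L, 2L * m - 2L, by = 2L)] <- il
      starts <- gene_start[i] + c(0, cumsum(part_len))[seq_len(2L * m - 1L)]
      exon_idx <- seq(1L, 2L * m - 1L, by = 2L)
      exon_rows[[i]] <- data.frame(
        gene_id = gene_ids[i], scaffold = gname, strand = strand[i],
        start = as.integer(starts[exon_idx]),
        end = as.integer(starts[exon_idx] + el - 1L),
        stringsAsFactors = FALSE)
    }
    models <- gene_models(do.call(rbind, exon_rows))
    truth <- data.frame(
      gene_id = gene_ids, strand = strand, n_exons = n_exons,
      n_introns = n_introns,
      exonic_bp = vapply(el_by_gene, sum, numeric(1)),
      intronic_bp = vapply(il_by_gene, function(x) {
        if (length(x)) sum(x) else 0
      }, numeric(1)),
      gene_start = gene_start, gene_length = gene_len,
      stringsAsFactors = FALSE)
    out_genome <- Biostrings::DNAStringSet(new_seq)
    names(out_genome) <- gname
    list(genome = out_genome, models = models, truth = truth)
  })
}

#' Write gene models as GFF3 (gene/mRNA/exon)
#'
#' Deterministic emitter: identical models always yield a byte-identical
#' file.
#'
#' @param models A `gene_models` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  by_gene <- split(seq_len(nrow(models)), models$gene_id)
  for (gid in sort(names(by_gene))) {
    idx <- by_gene[[gid]]
    s <- min(models$start[idx]); e <- max(models$end[idx])
    sc <- models$scaffold[idx[1]]; st <- models$strand[idx[1]]
    writeLines(c(
      sprintf("%s\tdraftqc\tgene\t%d\t%d\t.\t%s\t.\tID=%s", sc, s, e, st, gid),
      sprintf("%s\tdraftqc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              sc, s, e, st, gid, gid),
      sprintf("%s\tdraftqc\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
              sc, models$start[idx], models$end[idx], st, gid,
              seq_along(idx), gid)), con)
  }
  invisible(path)
}

#' Write planted LTR elements as GFF3
#'
#' Emits one `LTR_retrotransposon` feature per element with two child
#' `long_terminal_repeat` features.
#'
#' @param truth Truth table from [plant_ltr_elements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ltr_truth_gff3 <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(truth))) {
    id <- truth$element_id[i]
    writeLines(c(
      sprintf("%s\tdraftqc\tLTR_retrotransposon\t%d\t%d\t.\t+\t.\tID=%s",
              truth$scaffold[i], truth$start[i], truth$end[i], id),
      sprintf("%s\tdraftqc\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_5p;Parent=%s",
              truth$scaffold[i], truth$ltr5_start[i], truth$ltr5_end[i],
              id, id),
      sprintf("%s\tdraftqc\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_3p;Parent=%s",
              truth$scaffold[i], truth$ltr3_start[i], truth$ltr3_end[i],
              id, id)), con)
  }
  invisible(path)
}

#' Specification for uniform-coverage read simulation
#'
#' @param depth Fold coverage (> 0).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability (in [0, 0.2)).
#' @param seed Integer seed.
#' @return List of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth, read_length = 100L, error_rate = 0,
                          seed = 1L) {
  stopifnot(depth > 0, read_length >= 1, error_rate >= 0, error_rate < 0.2)
  out <- list(depth = depth, read_length = as.integer(read_length),
              error_rate = error_rate, seed = as.integer(seed))
  class(out) <- "read_sim_spec"
  out
}

#' Simulate uniform-coverage shotgun reads
#'
#' Read count is `round(genome_length * depth / read_length)`; start
#' positions uniform over the genome, strand uniform (half the reads are
#' reverse-complemented), substitution errors injected at `error_rate`
#' per base.
#'
#' @param genome Single-sequence `DNAStringSet` (or [generate_genome()]
#'   output).
#' @param spec A [read_sim_spec()].
#' @return `DNAStringSet` of reads named `read_1`, `read_2`, ...
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  gseq <- as.character(genome[[1]])
  L <- nchar(gseq)
  rl <- spec$read_length
  if (rl > L) stop("read_length exceeds genome length")
  with_spec_seed(spec$seed, {
    n_reads <- round(L * spec$depth / rl)
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    reads <- substring(gseq, starts, starts + rl - 1L)
    rc <- stats::runif(n_reads) < 0.5
    if (any(rc)) reads[rc] <- revcomp(reads[rc])
    if (spec$error_rate > 0) {
      n_err <- stats::rbinom(1L, n_reads * rl, spec$error_rate)
      if (n_err > 0) {
        pos <- sample.int(n_reads * rl, n_err)  # global base index
        ri <- (pos - 1L) %/% rl + 1L
        pj <- (pos - 1L) %% rl + 1L
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        pick <- sample.int(3L, n_err, replace = TRUE)
        for (e in seq_len(n_err)) {
          b <- substr(reads[ri[e]], pj[e], pj[e])
          substr(reads[ri[e]], pj[e], pj[e]) <- alt[[b]][pick[e]]
        }
      }
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- paste0("read_", seq_len(n_reads))
    out
  })
}

#' Write reads as FASTQ with constant quality
#' @param reads `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Specification for expression-table simulation
#'
#' FPKM values are log-normal: log2(FPKM) is Gaussian with the stated
#' mean and SD. `structure_coupling` is a Gaussian-copula correlation
#' between a gene's total intron length and its expression in every
#' organ; 0 decouples them, values near 1 make intron-rich genes the
#' most expressed (a coupling of 0.8 yields a Spearman rank correlation
#' of about 0.78).
#'
#' @param organs Organ labels (default root, leaf, stem, flower).
#' @param log_fpkm_mean,log_fpkm_sd Mean/SD of log2 FPKM (defaults 5, 2).
#' @param structure_coupling Copula correlation in [0, 1] (default 0).
#' @param ef1a_id Identifier for the housekeeping reference row
#'   (default `"EF1A"`), always present with positive FPKM.
#' @param seed Integer seed.
#' @return List of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(organs = c("root", "leaf", "stem", "flower"),
                                log_fpkm_mean = 5, log_fpkm_sd = 2,
                                structure_coupling = 0,
                                ef1a_id = "EF1A", seed = 1L) {
  stopifnot(length(organs) >= 1, log_fpkm_sd > 0,
            structure_coupling >= 0, structure_coupling <= 1,
            nzchar(ef1a_id))
  out <- list(organs = organs, log_fpkm_mean = log_fpkm_mean,
              log_fpkm_sd = log_fpkm_sd,
              structure_coupling = structure_coupling,
              ef1a_id = ef1a_id, seed = as.integer(seed))
  class(out) <- "expression_sim_spec"
  out
}

#' Simulate an FPKM expression table over organs
#'
#' @param genes A `gene_models` table, the list returned by
#'   [plant_gene_models()], or a named numeric vector of per-gene total
#'   intron lengths (names = gene ids).
#' @param spec An [expression_sim_spec()].
#' @return Expression matrix (genes + the EF1A row) x organs, FPKM.
#' @export
simulate_expression <- function(genes, spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (is.list(genes) && !is.null(genes$models)) genes <- genes$models
  if (inherits(genes, "gene_models")) {
    intron_len <- total_intron_length(genes)
  } else {
    stopifnot(is.numeric(genes), !is.null(names(genes)))
    intron_len <- genes
  }
  ids <- names(intron_len)
  if (spec$ef1a_id %in% ids) {
    stop("ef1a_id '", spec$ef1a_id, "' collides with a gene id")
  }
  n <- length(intron_len)
  with_spec_seed(spec$seed, {
    rho <- spec$structure_coupling
    # normal scores of the intron-length ranks (random tie-break)
    r <- rank(intron_len, ties.method = "random")
    z_struct <- stats::qnorm((r - 0.5) / n)
    m <- matrix(NA_real_, n + 1L, length(spec$organs),
                dimnames = list(c(ids, spec$ef1a_id), spec$organs))
    for (j in seq_along(spec$organs)) {
      eps <- stats::rnorm(n)
      z <- rho * z_struct + sqrt(1 - rho^2) * eps
      m[seq_len(n), j] <- 2^(spec$log_fpkm_mean + spec$log_fpkm_sd * z)
      m[n + 1L, j] <- 2^(spec$log_fpkm_mean + spec$log_fpkm_sd *
                           stats::rnorm(1))
    }
    expression_table(m)
  })
}

#' Write an expression matrix as TSV
#' @param m Expression matrix.
#' @param path Output path.
#' @param id_column Name of the identifier column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
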