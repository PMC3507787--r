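test_that("generated genomes hit their GC targets and are reproducible", {
  spec <- genome_spec(10000, data.frame(gc_mean = 0.5, weight = 1),
                      seed = 51)
  g <- generate_genome(spec)
  expect_equal(Biostrings::width(g$genome)[[1]], 10000)
  gc <- per_record_gc(g$genome)$gc
  expect_lt(abs(gc - 0.5), 0.03)  # ~6 binomial SDs at n = 10k

  g2 <- generate_genome(spec)
  expect_identical(as.character(g$genome), as.character(g2$genome))

  # distinct seed, distinct sequence
  g3 <- generate_genome(genome_spec(10000,
                                    data.frame(gc_mean = 0.5, weight = 1),
                                    seed = 52))
  expect_false(identical(as.character(g$genome), as.character(g3$genome)))
})

test_that("two-component genomes show two per-segment GC modes", {
  spec <- genome_spec(400000,
                      data.frame(gc_mean = c(0.30, 0.45),
                                 weight = c(0.5, 0.5)),
                      segment_length = 1000, seed = 53)
  g <- generate_genome(spec)
  segs <- g$truth$segments
  seq_ <- as.character(g$genome[[1]])
  seg_seqs <- substring(seq_, segs$start, segs$end)
  d <- density_with_modes(per_record_gc(seg_seqs))
  top2 <- sort(d$modes[1:2])
  expect_lt(abs(top2[1] - 0.30), 0.02)
  expect_lt(abs(top2[2] - 0.45), 0.02)
})

test_that("zero-age elements have identical LTR copies", {
  g <- generate_genome(genome_spec(20000, seed = 54))
  pl <- plant_ltr_elements(g, ltr_plant_spec(
    5, c(800, 800), c(100, 200),
    age_components = data.frame(age_mode = 0, sdlog = 0, weight = 1),
    seed = 55))
  expect_identical(pl$pairs$five_prime, pl$pairs$three_prime)
  expect_true(all(pl$truth$true_age_years == 0))
  expect_true(all(pl$truth$true_expected_K == 0))
})

test_that("planted-truth coordinates reproduce the planted sequences", {
  g <- generate_genome(genome_spec(30000, seed = 56))
  pl <- plant_ltr_elements(g, ltr_plant_spec(8, c(500, 700), c(100, 400),
                                             seed = 57))
  gs <- as.character(pl$genome[[1]])
  expect_identical(substring(gs, pl$truth$ltr5_start, pl$truth$ltr5_end),
                   pl$pairs$five_prime)
  expect_identical(substring(gs, pl$truth$ltr3_start, pl$truth$ltr3_end),
                   pl$pairs$three_prime)
  # genome grew by exactly the planted element lengths
  expect_equal(nchar(gs),
               30000 + sum(pl$truth$end - pl$truth$start + 1))

  pg <- plant_gene_models(g, gene_set_spec(30, seed = 58))
  gs2 <- as.character(pg$genome[[1]])
  exon_seqs <- substring(gs2, pg$models$start, pg$models$end)
  expect_equal(sum(nchar(exon_seqs)),
               sum(pg$truth$exonic_bp))
  # exon GC clearly above intron GC by construction
  ex_gc <- mean(per_record_gc(exon_seqs)$gc)
  expect_lt(abs(ex_gc - 0.4274), 0.03)
})

test_that("planted K estimates are unbiased for 2rT", {
  g <- generate_genome(genome_spec(50000, seed = 59))
  pl <- plant_ltr_elements(g, ltr_plant_spec(
    100, c(2000, 2000), c(200, 400),
    age_components = data.frame(age_mode = 1e6, sdlog = 0.1, weight = 1),
    seed = 60))
  ages <- ltr_insertion_ages(pl$pairs)
  tr <- merge(ages, pl$truth, by = "element_id")
  expect_lt(abs(mean(tr$K) / mean(tr$true_expected_K) - 1), 0.1)
})

test_that("gene planting respects counts, laws and determinism", {
  g <- generate_genome(genome_spec(20000, seed = 61))
  spec1 <- gene_set_spec(40, exon_count_mean = 1, exon_count_sd = 0,
                         seed = 62)
  single <- plant_gene_models(g, spec1)
  expect_true(all(single$truth$n_exons == 1))
  expect_identical(nrow(derive_introns(single$models)), 0L)

  spec2 <- gene_set_spec(40, seed = 63)
  a <- plant_gene_models(g, spec2)
  b <- plant_gene_models(g, spec2)
  pa <- withr::local_tempfile(fileext = ".gff3")
  pb <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(a$models, pa)
  write_gene_models_gff3(b$models, pb)
  expect_identical(readLines(pa), readLines(pb))

  # GFF3 round trip through the reader recovers the exon table
  rt <- read_gene_models(pa)
  expect_equal(rt$start, a$models$start)
  expect_equal(rt$end, a$models$end)
  expect_equal(as.character(rt$strand), a$models$strand)
})

test_that("read simulation honors count, purity and coverage", {
  g <- generate_genome(genome_spec(10000, seed = 64))
  reads <- simulate_reads(g, read_sim_spec(depth = 10, read_length = 100,
                                           seed = 65))
  expect_length(reads, 1000)

  gseq <- as.character(g$genome[[1]])
  both <- c(gseq, revcomp(gseq))
  set.seed(66)
  for (r in as.character(reads[sample(1000, 25)])) {
    expect_true(any(vapply(both, grepl, logical(1), pattern = r,
                           fixed = TRUE)))
  }

  # mean per-base coverage across replicates close to the target depth
  cov <- vapply(1:10, function(s) {
    rd <- simulate_reads(g, read_sim_spec(depth = 5, read_length = 100,
                                          seed = s))
    sum(Biostrings::width(rd)) / 10000
  }, numeric(1))
  expect_lt(abs(mean(cov) - 5) / 5, 0.05)
  expect_error(
    simulate_reads(g, read_sim_spec(depth = 1, read_length = 20000,
                                    seed = 1)),
    "exceeds genome length")
})

test_that("fastq output carries constant quality and parses back", {
  g <- generate_genome(genome_spec(5000, seed = 67))
  reads <- simulate_reads(g, read_sim_spec(depth = 2, read_length = 80,
                                           seed = 68))
  path <- withr::local_tempfile(fileext = ".fq")
  write_reads_fastq(reads, path)
  back <- read_sequences(path, format = "fastq")
  expect_identical(as.character(back), as.character(reads))
  expect_true(all(grepl("^I+$",
                        readLines(path)[seq(4, 4 * length(reads), 4)])))
})

test_that("expression simulation couples structure as requested", {
  intron_len <- stats::setNames(round(stats::rlnorm(2000, 5, 1)),
                                paste0("g", 1:2000))
  e0 <- simulate_expression(intron_len,
                            expression_sim_spec(structure_coupling = 0,
                                                seed = 71))
  expect_identical(colnames(e0), c("root", "leaf", "stem", "flower"))
  expect_true("EF1A" %in% rownames(e0))
  expect_true(all(e0["EF1A", ] > 0))
  rho0 <- stats::cor(e0[names(intron_len), "leaf"], intron_len,
                     method = "spearman")
  expect_lt(abs(rho0), 0.1)

  e8 <- simulate_expression(intron_len,
                            expression_sim_spec(structure_coupling = 0.8,
                                                seed = 72))
  rho8 <- stats::cor(e8[names(intron_len), "leaf"], intron_len,
                     method = "spearman")
  expect_gte(rho8, 0.5)

  collide <- stats::setNames(1, "EF1A")
  expect_error(
    simulate_expression(collide, expression_sim_spec(seed = 73)),
    "collides")
})
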