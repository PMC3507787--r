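test_that("introns are the gaps between consecutive exons", {
  m <- gene_models(data.frame(
    gene_id = "g", scaffold = "s", strand = "+",
    start = c(1L, 151L), end = c(100L, 300L)))
  intr <- derive_introns(m)
  expect_equal(intr$start, 101L)
  expect_equal(intr$end, 150L)
  expect_equal(intr$end - intr$start + 1, 50)

  single <- gene_models(data.frame(gene_id = "g", scaffold = "s",
                                   strand = "+", start = 1L, end = 500L))
  expect_identical(nrow(derive_introns(single)), 0L)

  four <- gene_models(data.frame(
    gene_id = "g", scaffold = "s", strand = "+",
    start = c(1L, 201L, 401L, 601L), end = c(100L, 300L, 500L, 700L)))
  expect_identical(nrow(derive_introns(four)), 3L)
})

test_that("exon + intron lengths always sum to the gene span", {
  set.seed(91)
  g <- generate_genome(genome_spec(20000, seed = 91))
  pg <- plant_gene_models(g, gene_set_spec(60, seed = 92))
  introns <- derive_introns(pg$models)
  for (gid in unique(pg$models$gene_id)) {
    ex <- pg$models[pg$models$gene_id == gid, ]
    il <- introns[introns$gene_id == gid, ]
    span <- max(ex$end) - min(ex$start) + 1
    expect_equal(sum(ex$end - ex$start + 1) +
                   sum(il$end - il$start + 1), span)
  }
})

test_that("structure summary matches the two-gene hand example", {
  # g1: exons 100 and 200 bp separated by a 50 bp intron; g2: one 300 bp exon
  m <- gene_models(data.frame(
    gene_id = c("g1", "g1", "g2"), scaffold = "s1", strand = "+",
    start = c(1L, 151L, 401L), end = c(100L, 350L, 700L)))
  genome <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 200)))
  ss <- structure_summary(m, genome)
  st <- function(f) ss$stats$mean[ss$stats$feature == f]
  expect_equal(st("exon_length"), 200)       # (100+200+300)/3
  expect_equal(st("intron_length"), 50)
  expect_equal(st("exons_per_gene"), 1.5)
  expect_equal(st("introns_per_gene"), 0.5)
  expect_equal(st("gene_length"), (350 + 300) / 2)
  expect_equal(ss$n_genes, 2)

  expect_error(structure_summary(m, Biostrings::DNAStringSet(c(other = "ACGT"))),
               "not in genome")
  short <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
  expect_error(structure_summary(m, short), "beyond the end")
})

test_that("summary recovers the generator's structure laws", {
  g <- generate_genome(genome_spec(30000, seed = 93))
  pg <- plant_gene_models(g, gene_set_spec(800, seed = 94))
  ss <- structure_summary(pg$models, pg$genome)
  st <- function(f) ss$stats$mean[ss$stats$feature == f]
  # counts agree with planted truth exactly
  expect_equal(st("exons_per_gene"), mean(pg$truth$n_exons))
  expect_equal(st("introns_per_gene"), mean(pg$truth$n_introns))
  # GC per compartment near target
  expect_lt(abs(st("exonic_gc_pct") / 100 - 0.4274), 0.01)
  expect_lt(abs(st("intronic_gc_pct") / 100 - 0.3004), 0.01)
})

test_that("first exon/intron follow transcript orientation", {
  plus <- gene_models(data.frame(
    gene_id = "p", scaffold = "s", strand = "+",
    start = c(1L, 151L), end = c(100L, 300L)))
  fe <- first_elements(plus)
  expect_equal(fe$first_exon_start, 1L)
  expect_equal(fe$first_intron_start, 101L)
  expect_equal(fe$first_intron_end, 150L)

  minus <- gene_models(data.frame(
    gene_id = "m", scaffold = "s", strand = "-",
    start = c(1L, 201L), end = c(100L, 300L)))
  fm <- first_elements(minus)
  expect_equal(fm$first_exon_start, 201L)  # genomically last
  expect_equal(fm$first_intron_start, 101L)
  expect_equal(fm$first_intron_end, 200L)

  single <- gene_models(data.frame(gene_id = "s1", scaffold = "s",
                                   strand = "+", start = 1L, end = 50L))
  fs <- first_elements(single)
  expect_true(is.na(fs$first_intron_start))

  # strand flip mirrors the choice
  flipped <- plus
  flipped$strand <- "-"
  ff <- first_elements(gene_models(as.data.frame(flipped)))
  expect_equal(ff$first_exon_start, 151L)
})

test_that("structure-vs-expression contrasts top and bottom sets", {
  m <- toy_models()
  expr <- expression_table(matrix(
    c(10, 1), nrow = 2, dimnames = list(c("g1", "g2"), "leaf")))
  sv <- structure_vs_expression(m, expr, "leaf", n = 1)
  expect_identical(sv$top$gene_ids, "g1")
  expect_identical(sv$bottom$gene_ids, "g2")
  expect_equal(sv$top$mean_intron_length, 50)
  expect_equal(sv$bottom$mean_intron_length, 0)  # intronless set

  expect_error(structure_vs_expression(m, expr, "root", n = 1), "absent")
  expect_error(structure_vs_expression(m, expr, "leaf", n = 2),
               "at least 4")
})

test_that("planted coupling raises intron length of top expressors", {
  g <- generate_genome(genome_spec(30000, seed = 95))
  pg <- plant_gene_models(g, gene_set_spec(300, seed = 96))
  ex <- simulate_expression(pg, expression_sim_spec(
    structure_coupling = 0.8, seed = 97))
  sv <- structure_vs_expression(pg$models, ex, "leaf", n = 10)
  expect_gt(sv$top$mean_intron_length, sv$bottom$mean_intron_length)
})
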