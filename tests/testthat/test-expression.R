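make_table <- function(values, organs = c("root", "leaf")) {
  m <- matrix(values, ncol = length(organs),
              dimnames = list(paste0("g", seq_len(length(values) %/%
                                                    length(organs))),
                              organs))
  expression_table(m)
}

test_that("log2 transform honors the zero policy", {
  m <- expression_table(matrix(c(32, 0, 1), ncol = 1,
                               dimnames = list(c("a", "b", "c"), "leaf")))
  dropped <- log2_fpkm(m, "drop")
  expect_equal(dropped["a", 1], 5)
  expect_true(is.na(dropped["b", 1]))
  expect_equal(attr(dropped, "n_dropped"), 1L)

  pc <- log2_fpkm(m, "pseudocount", pseudocount = 1)
  expect_equal(pc["b", 1], 0)
  expect_error(log2_fpkm(m, "pseudocount", pseudocount = 0), "> 0")
})

test_that("GC-binned expression uses half-open bins and conserves counts", {
  m <- expression_table(matrix(rep(32, 3), ncol = 1,
                               dimnames = list(c("t1", "t2", "t3"), "leaf")))
  prof <- data.frame(id = c("t1", "t2", "t3"), gc = c(0.35, 0.35, 0.20),
                     at = NA, n_unambiguous = 100, usable = TRUE)
  class(prof) <- c("composition_profile", "data.frame")
  gb <- gc_binned_expression(m, prof)
  # gc 0.20 falls in [0.2, 0.4): a single cell with all three transcripts
  expect_identical(nrow(gb$cells), 1L)
  expect_equal(gb$cells$gc_bin_lower, 0.2)
  expect_equal(gb$cells$expr_bin_lower, 5.0)
  expect_equal(gb$cells$count, 3L)
  expect_equal(sum(gb$cells$count), gb$n_values)

  bad_prof <- prof[1:2, ]
  expect_error(gc_binned_expression(m, bad_prof), "missing from GC profile")
})

test_that("max-density cell sits where the simulation concentrates", {
  set.seed(101)
  n <- 2000
  ids <- paste0("t", 1:n)
  fpkm <- 2^rnorm(n, 5.2, 0.15)
  m <- expression_table(matrix(fpkm, ncol = 1,
                               dimnames = list(ids, "leaf")))
  prof <- data.frame(id = ids, gc = rnorm(n, 0.40, 0.02), at = NA,
                     n_unambiguous = 500, usable = TRUE)
  class(prof) <- c("composition_profile", "data.frame")
  gb <- gc_binned_expression(m, prof)
  expect_equal(gb$max_cell$expr_bin_lower, 5.0)
  expect_true(gb$max_cell$gc_bin_lower %in% c(0.2, 0.4))
})

test_that("EF1A normalization is exact and scale-invariant", {
  m <- expression_table(matrix(c(40, 20, 80, 10), ncol = 2,
                               dimnames = list(c("x", "EF1A"),
                                               c("root", "leaf"))))
  nm <- ef1a_normalize(m, "EF1A")
  expect_equal(nm["x", "root"], 2)
  expect_equal(nm["x", "leaf"], 8)
  expect_true(all(nm["EF1A", ] == 1))

  scaled <- m
  scaled[, "leaf"] <- scaled[, "leaf"] * 7
  expect_equal(ef1a_normalize(scaled, "EF1A"), nm)

  zero <- m
  zero["EF1A", "leaf"] <- 0
  expect_error(ef1a_normalize(zero, "EF1A"), "leaf")
  expect_error(ef1a_normalize(m, "nope"), "not in the table")
})

test_that("differential indices are log2 ratios with exact identities", {
  ref <- expression_table(matrix(c(40, 20, 6), ncol = 1,
                                 dimnames = list(c("gA", "EF1A", "gB"),
                                                 "leaf")))
  oth <- expression_table(matrix(c(5, 10, 0), ncol = 1,
                                 dimnames = list(c("hA", "EF1Ab", "hB"),
                                                 "leaf")))
  map <- data.frame(ref_id = c("gA", "EF1A", "gB"),
                    other_id = c("hA", "EF1Ab", "hB"))
  di <- differential_index(ref, oth, map, "EF1A", "EF1Ab")
  # (40/20) / (5/10) = 4 -> index 2
  expect_equal(di$index[di$ref_id == "gA"], 2)
  expect_equal(di$index[di$ref_id == "EF1A"], 0)
  expect_equal(attr(di, "n_zero_excluded"), 1L)  # hB has FPKM 0

  swapped <- differential_index(oth, ref,
                                data.frame(ref_id = map$other_id,
                                           other_id = map$ref_id),
                                "EF1Ab", "EF1A")
  joined <- merge(as.data.frame(di), as.data.frame(swapped),
                  by.x = "ref_id", by.y = "other_id")
  expect_equal(joined$index.x, -joined$index.y, tolerance = 1e-12)

  expect_error(differential_index(ref, oth,
                                  data.frame(ref_id = "zz",
                                             other_id = "yy"),
                                  "EF1A", "EF1Ab"),
               "no mapped genes")
})

test_that("top/bottom selection ranks and tie-breaks deterministically", {
  m <- expression_table(matrix(c(1, 2, 3), ncol = 1,
                               dimnames = list(c("a", "b", "c"), "leaf")))
  tb <- top_bottom(m, "leaf", 1)
  expect_identical(tb$top, "c")
  expect_identical(tb$bottom, "a")

  tie <- expression_table(matrix(c(2, 2), ncol = 1,
                                 dimnames = list(c("a", "b"), "leaf")))
  expect_identical(top_bottom(tie, "leaf", 1)$top, "a")

  set.seed(102)
  big <- expression_table(matrix(runif(40, 1, 9), ncol = 4,
                                 dimnames = list(paste0("g", 1:10),
                                                 c("r", "l", "s", "f"))))
  tb2 <- top_bottom(big, "l", 2)
  expect_lte(nrow(tb2$matrix), 2 * 2 * 4)
  expect_error(top_bottom(m, "leaf", 0), ">= 1")
})

test_that("unannotated top loci dedup across organs matches a set-union oracle", {
  # all annotated -> empty
  m <- make_table(c(1, 2, 3, 4), organs = c("root", "leaf"))
  lm_ <- data.frame(transcript_id = rownames(m), locus_id = rownames(m))
  empty <- unannotated_top_loci(m, rep(TRUE, nrow(m)), lm_, n = 2)
  expect_identical(empty$n_unique, 0L)

  # two organs pick the same locus -> unique count 1
  m2 <- expression_table(matrix(c(9, 1, 8, 2), ncol = 2,
                                dimnames = list(c("t1", "t2"),
                                                c("root", "leaf"))))
  lmap <- data.frame(transcript_id = c("t1", "t2"),
                     locus_id = c("L1", "L1"))
  r <- unannotated_top_loci(m2, c(FALSE, TRUE), lmap, n = 1)
  expect_identical(r$loci, "L1")
  expect_identical(r$n_unique, 1L)

  # engineered overlaps vs brute-force union over organs
  set.seed(103)
  n <- 400
  ids <- paste0("t", seq_len(n))
  m3 <- expression_table(matrix(runif(n * 4, 0, 100), ncol = 4,
                                dimnames = list(ids,
                                                c("root", "leaf",
                                                  "stem", "flower"))))
  annotated <- runif(n) < 0.3
  locus <- paste0("L", sample(1:120, n, replace = TRUE))
  lmap3 <- data.frame(transcript_id = ids, locus_id = locus)
  res <- unannotated_top_loci(m3, annotated, lmap3, n = 50)
  oracle <- character(0)
  cand <- ids[!annotated]
  for (organ in colnames(m3)) {
    picked <- cand[order(-m3[cand, organ], cand)][1:50]
    oracle <- union(oracle, locus[match(picked, ids)])
  }
  expect_setequal(res$loci, oracle)
  expect_identical(res$n_unique, length(unique(oracle)))

  expect_error(unannotated_top_loci(m2, c(FALSE, FALSE),
                                    data.frame(transcript_id = "t1",
                                               locus_id = "L1"),
                                    n = 2),
               "no locus mapping")
})
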