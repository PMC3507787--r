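# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (enumeration, literal formulas, direct scans) and
# share no code with the implementation they check.

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
         collapse = "")
}

# descending cumulative-length scan for Nx
nx_oracle <- function(lengths, frac) {
  lengths <- sort(lengths, decreasing = TRUE)
  cum <- 0
  for (l in lengths) {
    cum <- cum + l
    if (cum >= frac * sum(lengths)) return(l)
  }
  NA_real_
}

# exhaustive enumeration of all global alignments under affine gaps;
# feasible only for tiny sequences
enum_align_score <- function(a, b, match = 5, mismatch = -4,
                             open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(A)) {
      pen <- extend + if (last == "ga") 0 else open
      best <- max(best, -pen + rec(i + 1, j, "ga"))
    }
    if (j <= length(B)) {
      pen <- extend + if (last == "gb") 0 else open
      best <- max(best, -pen + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# literal K2P re-derivation on a different algebraic path:
# K = (1/2) ln a + (1/4) ln b with a = 1/(1-2P-Q), b = 1/(1-2Q)
k2p_oracle <- function(P, Q) {
  a <- 1 / (1 - 2 * P - Q)
  b <- 1 / (1 - 2 * Q)
  0.5 * log(a) + 0.25 * log(b)
}

# direct count of valid (ACGT-only) length-k windows in a set of reads
valid_window_count <- function(seqs, k) {
  total <- 0L
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    ok <- ch %in% c("A", "C", "G", "T")
    if (length(ch) < k) next
    for (i in seq_len(length(ch) - k + 1L)) {
      if (all(ok[i:(i + k - 1L)])) total <- total + 1L
    }
  }
  total
}

# toy gene-model table used by several structure tests
toy_models <- function() {
  gene_models(data.frame(
    gene_id = c("g1", "g1", "g2"),
    scaffold = "s1",
    strand = c("+", "+", "+"),
    start = c(1L, 151L, 401L),
    end = c(100L, 350L, 700L),
    stringsAsFactors = FALSE))
}
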