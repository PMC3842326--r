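# brute-force three-layer affine-gap DP oracle written independently in R
brute_force_score <- function(a, b, params) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  open <- -params$gap_open; ext <- -params$gap_extend
  M <- GA <- GB <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) GA[1, j + 1] <- if (params$free_end_gaps) 0 else -(open + j * ext)
  for (i in seq_len(n)) GB[i + 1, 1] <- if (params$free_end_gaps) 0 else -(open + i * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) params$match else params$mismatch
    M[i + 1, j + 1] <- max(M[i, j], GA[i, j], GB[i, j]) + s
    GA[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, GA[i + 1, j] - ext,
                            GB[i + 1, j] - open - ext)
    GB[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, GB[i, j + 1] - ext,
                            GA[i, j + 1] - open - ext)
  }
  if (params$free_end_gaps) {
    best <- max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
    for (j in 0:m) best <- max(best, M[n + 1, j + 1], GA[n + 1, j + 1],
                               GB[n + 1, j + 1])
    for (i in 0:n) best <- max(best, M[i + 1, m + 1], GA[i + 1, m + 1],
                               GB[i + 1, m + 1])
    best
  } else {
    max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
  }
}

test_that("pairwise_align handles identity and terminal-gap cases", {
  aln <- pairwise_align("ACGT", "ACGT")
  expect_equal(aln$aligned_a, "ACGT")
  expect_equal(aln$aligned_b, "ACGT")
  expect_equal(aln$score, 4)

  aln <- pairwise_align("ACGT", "ACG")
  expect_equal(aln$aligned_a, "ACGT")
  expect_equal(aln$aligned_b, "ACG-")
  # degapping recovers the inputs
  expect_equal(gsub("-", "", aln$aligned_a), "ACGT")
  expect_equal(gsub("-", "", aln$aligned_b), "ACG")
  expect_error(pairwise_align("", "ACG"), "empty")
})

test_that("alignment score matches an exhaustive DP oracle", {
  p <- align_params(match = 1, mismatch = -1, gap_open = -2,
                    gap_extend = -0.5, free_end_gaps = FALSE)
  expect_equal(pairwise_align("AACCGG", "AAGG", p)$score,
               brute_force_score("AACCGG", "AAGG", p))
  set.seed(101)
  for (k in 1:40) {
    a <- random_seq(sample(5:25, 1))
    b <- random_seq(sample(5:25, 1))
    for (fe in c(TRUE, FALSE)) {
      pp <- align_params(free_end_gaps = fe)
      expect_equal(pairwise_align(a, b, pp)$score,
                   brute_force_score(a, b, pp))
    }
  }
})

test_that("p_distance counts only unambiguous differences over all columns", {
  expect_equal(p_distance(list(aligned_a = "ACGT", aligned_b = "ACGA")), 0.25)
  expect_equal(p_distance(list(aligned_a = "ACGT", aligned_b = "ACGT")), 0)
  expect_equal(p_distance(list(aligned_a = "ACGT", aligned_b = "ACGN")), 0)
  expect_equal(p_distance(list(aligned_a = "AC-T", aligned_b = "ACGT")), 0)
  expect_error(p_distance(list(aligned_a = "", aligned_b = "")))
})

test_that("distance_matrix equals pair-by-pair recomputation", {
  set.seed(7)
  specs <- list()
  for (s in 1:3) {
    base <- random_seq(80)
    specs[[paste0("Sp", s)]] <- list()
    for (i in 1:2) {
      specs[[paste0("Sp", s)]][[paste0("s", s, "_", i)]] <-
        c(m1 = sub_at(base, sample(80, 1), "A"))
    }
  }
  lib <- toy_library(specs)
  dm <- distance_matrix(lib, "m1")
  expect_true(isSymmetric(dm$p))
  expect_true(all(diag(dm$p) == 0))
  for (i in seq_along(dm$ids)) for (j in seq_along(dm$ids)) {
    if (i < j) {
      a <- lib$records$sequence[lib$records$specimen_id == dm$ids[i]]
      b <- lib$records$sequence[lib$records$specimen_id == dm$ids[j]]
      expect_equal(dm$p[i, j], p_distance(pairwise_align(a, b)))
    }
  }
  expect_error(distance_matrix(lib, "m2"), "missing")
})

test_that("identical and 1-substitution sequences give expected distances", {
  s <- strrep("ACGT", 25)
  lib <- toy_library(list(A = list(a1 = c(m1 = s), a2 = c(m1 = s)),
                          B = list(b1 = c(m1 = sub_at(s, 50, "A")))))
  dm <- distance_matrix(lib, "m1")
  expect_equal(dm$p["a1", "a2"], 0)
  expect_equal(dm$p["a1", "b1"], 0.01)
})

test_that("multilocus pooling sums differences and columns", {
  s1 <- strrep("AC", 50); s2 <- strrep("GT", 50); s3 <- strrep("AG", 50)
  lib <- toy_library(list(
    A = list(a = c(m1 = s1, m2 = s2, m3 = s3)),
    B = list(b = c(m1 = sub_at(s1, 10, "T"), m2 = s2,
                   m3 = sub_at(s3, 99, "C")))))
  expect_equal(multilocus_distance(lib, c("m1", "m2", "m3"), "a", "b"),
               2 / 300)
  expect_equal(multilocus_distance(lib, c("m2"), "a", "b"), 0)
  expect_error(multilocus_distance(lib, c("m4"), "a", "b"), "m4")
  dm <- multilocus_distance_matrix(lib, c("m1", "m2", "m3"))
  expect_equal(dm$p["a", "b"], 2 / 300)
  # single-marker pooling equals the plain per-marker distance
  expect_equal(multilocus_distance_matrix(lib, "m1")$p,
               distance_matrix(lib, "m1")$p)
})

test_that("p-distance behaves as a pseudo-metric on substitution-only sets", {
  # sequences derived from one template by substitutions align without
  # gaps, so p-distance reduces to normalised Hamming distance
  set.seed(33)
  base <- random_seq(200)
  seqs <- vapply(1:6, function(i) {
    s <- base
    for (pos in sample(200, sample(0:6, 1))) s <- sub_at(s, pos, "A")
    s
  }, character(1))
  lib <- toy_library(setNames(lapply(seq_along(seqs), function(i) {
    setNames(list(c(m1 = seqs[i])), paste0("s", i))
  }), paste0("Sp", seq_along(seqs))))
  p <- distance_matrix(lib, "m1")$p
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p, t(p))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(p[i, j], p[i, k] + p[k, j] + 1e-12)
  }
})

test_that("simple indel coding scores exact spans, absences and nesting", {
  msa <- c(r1 = "AC---GTAC", r2 = "AC---GTAC", r3 = "ACTTTGTAC",
           r4 = "ACTTTGTAC")
  m <- simple_indel_coding(msa)
  expect_equal(ncol(m), 1L)
  expect_equal(unname(m[, 1]), c("1", "1", "0", "0"))

  expect_equal(ncol(simple_indel_coding(c(a = "ACGT", b = "ACGT"))), 0L)

  # r3's larger gap strictly contains r1's span -> inapplicable
  msa <- c(r1 = "AC---GTAC", r2 = "ACTTTGTAC", r3 = "A-----TAC")
  m <- simple_indel_coding(msa)
  expect_equal(sort(colnames(m)), c("g2_7", "g3_6"))
  expect_equal(unname(m[, "g3_6"]), c("1", "0", "-"))
  expect_equal(unname(m[, "g2_7"]), c("0", "0", "1"))

  expect_error(simple_indel_coding(c("AC-", "ACGT")), "ragged")
})

test_that("nj_tree recovers an additive topology and is order-invariant", {
  # additive distances on ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.03
  d["c", "d"] <- d["d", "c"] <- 0.05
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- 0.11
  }
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 4L)
  ref <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(ref))), 0)
  perm <- c("d", "b", "a", "c")
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr2),
                                         ape::unroot(tr))), 0)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})
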