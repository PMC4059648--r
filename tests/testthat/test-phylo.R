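test_that("p-distance counts differing comparable sites and excludes
           gaps/N", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("A-CG", "AACG"), 0) # 3 comparable sites
  expect_equal(p_distance("ANCG", "AACG"), 0)
  expect_error(p_distance("----", "AAAA"), "no comparable sites")
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("Jukes-Cantor correction matches the closed form and flags
           saturation", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_gte(jc_distance(0.2), 0.2)
  expect_error(jc_distance(0.75), "saturated")
  expect_error(jc_distance(0.9), "saturated")
})

test_that("JC substitution simulation re-estimates the generating
           distance", {
  set.seed(91)
  n <- 10000L
  d_true <- 0.15
  a <- rand_dna(n)
  p_sub <- 0.75 * (1 - exp(-4 * d_true / 3))
  b <- mutate_test_seq(a, p_sub)
  d_hat <- jc_distance(p_distance(a, b))
  se <- sqrt(p_sub * (1 - p_sub) / n) / (1 - 4 * p_sub / 3)
  expect_lt(abs(d_hat - d_true), 3 * se)
})

test_that("three taxa solve the three-point equations exactly", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd["A", "B"], 0.3, tolerance = 1e-9)
  expect_equal(pd["A", "C"], 0.4, tolerance = 1e-9)
  expect_equal(pd["B", "C"], 0.5, tolerance = 1e-9)
})

test_that("NJ and BioNJ are exact on additive matrices from random trees", {
  set.seed(92)
  for (i in 1:8) {
    ntax <- sample(4:8, 1)
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.05, 0.4))
    d <- ape::cophenetic.phylo(tr)
    for (v in c("nj", "bionj")) {
      est <- nj_tree(d, variant = v)
      expect_equal(rf_distance(est, tr), 0)
      pd <- ape::cophenetic.phylo(est)
      expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-6)
    }
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("negative branch lengths are clamped with the deficit moved to
           the sister branch", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.12
  d["B", "C"] <- d["C", "B"] <- 0.05
  d["A", "D"] <- d["D", "A"] <- 0.4
  d["B", "D"] <- d["D", "B"] <- 0.45
  d["C", "D"] <- d["D", "C"] <- 0.43
  raw <- ape::nj(as.dist(d))
  clamped <- nj_tree(d)
  expect_true(all(clamped$edge.length >= 0))
  # total tree length is preserved when a deficit moves to the sister
  expect_equal(sum(clamped$edge.length), sum(raw$edge.length),
               tolerance = 1e-9)
})

test_that("reads project onto consensus coordinates with substitutions in
           place", {
  set.seed(93)
  cons <- rand_dna(500)
  read <- substr(cons, 101, 300)
  aln <- align_to_consensus(c(r1 = read), cons)
  expect_equal(ncol(aln), 500L)
  expect_equal(paste(aln[1, 101:300], collapse = ""), read)
  expect_true(all(aln[1, c(1:100, 301:500)] == "-"))
  # two substitutions appear at exactly two columns
  mut <- read
  substr(mut, 50, 50) <- if (substr(read, 50, 50) == "A") "C" else "A"
  substr(mut, 120, 120) <- if (substr(read, 120, 120) == "G") "T" else "G"
  aln2 <- align_to_consensus(c(r1 = mut), cons)
  ref_row <- strsplit(substr(cons, 101, 300), "")[[1]]
  expect_equal(sum(aln2[1, 101:300] != ref_row), 2L)
  # reverse-complement reads are re-oriented
  aln3 <- align_to_consensus(c(r1 = revcomp(read)), cons)
  expect_equal(paste(aln3[1, 101:300], collapse = ""), read)
  # dissimilar reads are excluded with a warning
  expect_warning(
    out <- align_to_consensus(c(bad = rand_dna(200)), cons,
                              min_identity = 0.8),
    "excluded")
  expect_equal(nrow(out), 0L)
})

test_that("consensus of aligned reads recovers the template and species
           divergence ranks correctly", {
  set.seed(94)
  cons <- rand_dna(400)
  near <- vapply(1:30, function(i) {
    s <- sample(1:201, 1)
    mutate_test_seq(substr(cons, s, s + 199), 0.03)
  }, character(1))
  far <- vapply(1:30, function(i) {
    s <- sample(1:201, 1)
    mutate_test_seq(substr(cons, s, s + 199), 0.12)
  }, character(1))
  names(near) <- paste0("n", 1:30); names(far) <- paste0("f", 1:30)
  aln_n <- align_to_consensus(near, cons)
  rec <- consensus_sequence(aln_n, min_cov = 2)
  comparable <- strsplit(rec, "")[[1]] != "N"
  expect_gt(mean(strsplit(rec, "")[[1]][comparable] ==
                   strsplit(cons, "")[[1]][comparable]), 0.99)
  # mean within-group p below mean between-group p at 3% vs 12%
  aln_f <- align_to_consensus(far, cons)
  rec_f <- consensus_sequence(aln_f, min_cov = 2)
  p_between <- p_distance(rec, rec_f)
  p_within <- p_distance(rec,
                         consensus_sequence(aln_n[16:30, , drop = FALSE],
                                            min_cov = 2))
  expect_lt(p_within, p_between)
})
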