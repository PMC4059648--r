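test_that("a family with zero copies leaves no trace in that species", {
  cfg <- sim_config(tree = "(A:0.01,B:0.01);",
                    background_bp = c(A = 30000, B = 30000),
                    families = list(
                      family_spec("FX", "dispersed_element", 500,
                                  c(A = 10, B = 0), 0, "LINE")),
                    n_reads = 100L, seed = 3L)
  sim <- evolve_genomes(cfg)
  cp <- sim$copies
  expect_true(all(cp$species == "A"))
  expect_equal(length(sim$genomes[["B"]]), 30000L)
  pb <- sim$proportions
  expect_equal(pb$percent[pb$species == "B" & pb$family == "background"],
               100)
})

test_that("zero branch lengths and zero intra-divergence give exact
           consensus copies", {
  cfg <- sim_config(tree = "(A:0.0,B:0.0);",
                    background_bp = c(A = 20000, B = 20000),
                    families = list(
                      family_spec("FX", "dispersed_element", 400,
                                  c(A = 5, B = 5), 0, "LINE")),
                    n_reads = 10L, seed = 11L)
  sim <- evolve_genomes(cfg)
  anc <- sim$consensus$FX$ancestral
  for (i in seq_len(nrow(sim$copies))) {
    row <- sim$copies[i, ]
    g <- as.character(sim$genomes[[row$species]])
    copy <- substr(g, row$start, row$end)
    if (row$strand == "-") copy <- revcomp(copy)
    expect_identical(copy, anc)
  }
})

test_that("truth proportions follow copies * unit_len / genome_len", {
  cfg <- sim_config(tree = "(A:0.0,B:0.0);",
                    background_bp = c(A = 1900000, B = 1900000),
                    families = list(
                      family_spec("FX", "dispersed_element", 1000,
                                  c(A = 100, B = 100), 0, "LINE")),
                    n_reads = 10L, seed = 2L)
  sim <- evolve_genomes(cfg)
  # 100 copies x 1000 nt in a 2 Mbp genome -> 5.0%
  p <- sim$proportions
  expect_equal(p$percent[p$species == "A" & p$family == "FX"], 5.0)
  expect_equal(length(sim$genomes[["A"]]), 2000000L)
})

test_that("per-species truth proportions always sum to 100", {
  sim <- small_run()$ds$sim
  sums <- tapply(sim$proportions$percent, sim$proportions$species, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})

test_that("error-free reads are exact genome substrings (either strand)
           and seeded sampling is reproducible", {
  cfg <- sim_config(tree = "(A:0.01,B:0.01);",
                    background_bp = c(A = 30000, B = 30000),
                    families = list(
                      family_spec("FX", "dispersed_element", 500,
                                  c(A = 10, B = 5), 0.01, "LINE")),
                    n_reads = 200L, error_rate = 0, seed = 5L)
  sim <- evolve_genomes(cfg)
  rd <- sample_reads(sim, seed = 9L)
  for (i in sample(length(rd$reads$seqs), 25)) {
    id <- names(rd$reads$seqs)[i]
    tr <- rd$truth[rd$truth$read_id == id, ]
    g <- as.character(sim$genomes[[tr$species]])
    sub <- substr(g, tr$start, tr$start + cfg$read_len - 1L)
    if (tr$strand == "-") sub <- revcomp(sub)
    expect_identical(as.character(rd$reads$seqs[[i]]), sub)
  }
  rd2 <- sample_reads(sim, seed = 9L)
  expect_identical(as.character(rd$reads$seqs),
                   as.character(rd2$reads$seqs))
})

test_that("read truth-label frequencies track genomic proportions
           (binomial oracle)", {
  cfg <- sim_config(tree = NULL, background_bp = c(A = 190000),
                    families = list(
                      family_spec("FX", "dispersed_element", 1000,
                                  c(A = 10), 0, "LINE")),
                    n_reads = 50000L, error_rate = 0, seed = 13L)
  sim <- evolve_genomes(cfg)
  rd <- sample_reads(sim)
  f_true <- 10 * 1000 / 200000 # 5% of the genome
  frac <- mean(rd$truth$family == "FX")
  se <- sqrt(f_true * (1 - f_true) / 50000)
  # family-labelled reads need >= 50% overlap, so the expected fraction
  # is the footprint fraction itself (span loss and gain cancel)
  expect_lt(abs(frac - f_true), 3 * se + 0.002)
})

test_that("same config and seed give byte-identical simulations", {
  cfg <- small_sim_config(seed = 21L, n_reads = 100L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.character(d1$sim$genomes),
                   as.character(d2$sim$genomes))
  expect_identical(as.character(d1$reads$seqs),
                   as.character(d2$reads$seqs))
  expect_identical(d1$truth, d2$truth)
})

test_that("with branch lengths far above intra-divergence, copies are
           monophyletic by species (within > between identity)", {
  cfg <- sim_config(tree = "(A:0.1,B:0.1);",
                    background_bp = c(A = 30000, B = 30000),
                    families = list(
                      family_spec("FX", "dispersed_element", 600,
                                  c(A = 6, B = 6), 0.005, "LINE")),
                    n_reads = 10L, seed = 17L)
  sim <- evolve_genomes(cfg)
  cp <- sim$copies
  seqs <- vapply(seq_len(nrow(cp)), function(i) {
    g <- as.character(sim$genomes[[cp$species[i]]])
    s <- substr(g, cp$start[i], cp$end[i])
    if (cp$strand[i] == "-") revcomp(s) else s
  }, character(1))
  pident <- function(x, y) 1 - p_distance(x, y)
  within <- c(); between <- c()
  for (i in 1:(nrow(cp) - 1)) {
    for (j in (i + 1):nrow(cp)) {
      v <- pident(seqs[i], seqs[j])
      if (cp$species[i] == cp$species[j]) within <- c(within, v)
      else between <- c(between, v)
    }
  }
  expect_gt(min(within), max(between))
})

test_that("insufficient background space is an error before any output", {
  expect_error(
    evolve_genomes(sim_config(
      tree = NULL, background_bp = c(A = 1000),
      families = list(family_spec("FX", "dispersed_element", 500,
                                  c(A = 50), 0, "LINE")),
      n_reads = 10L, seed = 1L)),
    "insufficient background space")
})
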