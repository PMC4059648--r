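ref_fixture <- function(seed = 71) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(c(
    "ele1|Ty1/copia:Angela" = rand_dna(800),
    "ele2|Ty3/gypsy:chromovirus:Reina" = rand_dna(700),
    "sat1|satellite:SatX" = rand_dna(120)))
  read_repeat_reference(seqs)
}

reads_from <- function(template, n, len = 200L, div = 0.02,
                       prefix = "r", species = "S1", seed = 72) {
  set.seed(seed)
  tl <- nchar(template)
  starts <- sample.int(tl - len + 1L, n, replace = TRUE)
  seqs <- vapply(starts, function(s) {
    mutate_test_seq(substr(template, s, s + len - 1L), div)
  }, character(1))
  names(seqs) <- paste0(prefix, seq_len(n))
  read_set(seqs, rep(species, n))
}

test_that("reference headers parse into ids and hierarchical labels", {
  ref <- ref_fixture()
  expect_equal(names(ref$seqs), c("ele1", "ele2", "sat1"))
  expect_equal(ref$label[1], "Ty1/copia:Angela")
  expect_error(read_repeat_reference(Biostrings::DNAStringSet()),
               "empty")
})

test_that("clusters of reads drawn from a reference entry identify it", {
  ref <- ref_fixture()
  rs <- reads_from(as.character(ref$seqs[["ele1"]]), 30)
  h <- find_hits(rs)
  cl <- cluster_reads(rs, h)
  ann <- classify_clusters(cl, rs, ref)
  expect_equal(ann$label[ann$cluster_id == "CL1"], "Ty1/copia:Angela")
  expect_equal(ann$vote_fraction[1], 1.0)
  expect_gte(ann$n_hit_reads[1], 25L)
})

test_that("clusters without reference similarity stay unclassified, as do
           ties below the vote threshold", {
  ref <- ref_fixture()
  set.seed(73)
  bg <- rand_dna(600)
  rs <- reads_from(bg, 25, seed = 74)
  cl <- cluster_reads(rs, find_hits(rs))
  ann <- classify_clusters(cl, rs, ref)
  expect_true(all(ann$label == "unclassified repetitive"))
  # constructed 50/50 split between two labels: below min_vote 0.6
  r1 <- reads_from(as.character(ref$seqs[["ele1"]]), 10, prefix = "a",
                   seed = 75)
  r2 <- reads_from(as.character(ref$seqs[["ele2"]]), 10, prefix = "b",
                   seed = 76)
  rs2 <- read_set(c(r1$seqs, r2$seqs), rep("S1", 20))
  fake_cl <- structure(list(
    membership = data.frame(read_id = names(rs2$seqs),
                            cluster_id = "CL1"),
    summary = data.frame(cluster_id = "CL1", size = 20L,
                         size_frac = 1, top = TRUE, n_S1 = 20L),
    total_reads = 20L, size_threshold = 3e-4), class = "cluster_set")
  ann2 <- classify_clusters(fake_cl, rs2, ref)
  expect_equal(ann2$label, "unclassified repetitive")
  expect_equal(ann2$vote_fraction, 0.5)
})

test_that("classification is invariant to read order", {
  ref <- ref_fixture()
  rs <- reads_from(as.character(ref$seqs[["ele2"]]), 24, seed = 77)
  cl <- cluster_reads(rs, find_hits(rs))
  ann1 <- classify_clusters(cl, rs, ref)
  set.seed(78)
  perm <- sample(length(rs$seqs))
  rs2 <- read_set(rs$seqs[perm], rs$species[perm])
  cl2 <- cluster_reads(rs2, find_hits(rs2))
  ann2 <- classify_clusters(cl2, rs2, ref)
  expect_equal(ann1$label, ann2$label)
  expect_equal(ann1$n_hit_reads, ann2$n_hit_reads)
})

test_that("protein domains are found in either strand and not in shuffled
           reads", {
  set.seed(79)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  orf <- paste(sample(codons, 40, replace = TRUE), collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  flank1 <- rand_dna(40); flank2 <- rand_dna(40)
  read_fwd <- paste0(flank1, orf, flank2)
  read_rev <- revcomp(read_fwd)
  shuffled <- vapply(1:50, function(i) {
    paste(sample(strsplit(read_fwd, "")[[1]]), collapse = "")
  }, character(1))
  rs <- read_set(setNames(c(read_fwd, read_rev, shuffled),
                          c("fwd", "rev", paste0("s", 1:50))),
                 rep("S1", 52))
  hits <- detect_domain_reads(rs, c(RT = prot))
  expect_true("fwd" %in% hits$read_id)
  expect_true("rev" %in% hits$read_id)
  expect_equal(hits$strand[hits$read_id == "fwd"], "+")
  expect_equal(hits$strand[hits$read_id == "rev"], "-")
  expect_equal(hits$frame[hits$read_id == "fwd"], 2L) # orf starts at 41
  # empirical null: shuffled reads of equal composition never reach the
  # default threshold
  expect_false(any(grepl("^s", hits$read_id)))
})

test_that("read databases partition annotated top-cluster reads by label", {
  ref <- ref_fixture()
  r1 <- reads_from(as.character(ref$seqs[["ele1"]]), 20, prefix = "a",
                   seed = 80)
  r2 <- reads_from(as.character(ref$seqs[["ele1"]]), 15, prefix = "b",
                   seed = 81)
  r3 <- reads_from(as.character(ref$seqs[["ele2"]]), 18, prefix = "c",
                   seed = 82)
  rs <- read_set(c(r1$seqs, r2$seqs, r3$seqs), rep("S1", 53))
  # force ele1 reads into two clusters by dropping cross edges
  h <- find_hits(rs)
  keep <- !(grepl("^a", h$read_a) & grepl("^b", h$read_b)) &
    !(grepl("^b", h$read_a) & grepl("^a", h$read_b))
  cl <- cluster_reads(rs, h[keep, ])
  ann <- classify_clusters(cl, rs, ref)
  dbs <- build_read_databases(cl, ann, rs)
  # two clusters with the same label merge into one database
  expect_equal(sum(grepl("Angela", names(dbs))), 1L)
  total_in_dbs <- sum(vapply(dbs, length, integer(1)))
  expect_equal(total_in_dbs,
               sum(cl$summary$size[cl$summary$top]))
  all_ids <- unlist(lapply(dbs, names))
  expect_false(any(duplicated(all_ids)))
})

test_that("tandem periodicity separates satellite from dispersed clusters", {
  set.seed(83)
  unit <- rand_dna(45)
  array_seq <- paste(vapply(1:12, function(i) mutate_test_seq(unit, 0.02),
                            character(1)), collapse = "")
  sat_reads <- reads_from(array_seq, 30, div = 0.01, prefix = "t",
                          seed = 84)
  out <- tandem_detect(sat_reads$seqs)
  expect_equal(out$flag, "tandem")
  expect_lt(abs(out$period - 45), 3)
  disp <- reads_from(rand_dna(5000), 30, prefix = "d", seed = 85)
  expect_equal(tandem_detect(disp$seqs)$flag, "dispersed")
  expect_equal(tandem_detect(disp$seqs[1:10])$flag, "unknown")
})
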