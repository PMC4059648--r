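make_hits <- function(a, b, score = 100L) {
  data.frame(read_a = a, read_b = b, identity = 1, overlap = 200L,
             orientation = "forward", score = score,
             stringsAsFactors = FALSE)
}

toy_reads <- function(n, species = "S1") {
  seqs <- setNames(vapply(seq_len(n), function(i) rand_dna(200),
                          character(1)), paste0("r", sprintf("%03d", 1:n)))
  read_set(seqs, rep(species, length.out = n))
}

test_that("graph construction counts nodes/edges and rejects dangling ids", {
  set.seed(51)
  rs <- toy_reads(6)
  h <- make_hits(c("r001", "r002"), c("r002", "r003"))
  g <- build_read_graph(rs, h)
  expect_equal(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(sum(igraph::degree(g)), 2L * igraph::ecount(g))
  expect_error(build_read_graph(rs, make_hits("r001", "zz9")), "zz9")
  g0 <- build_read_graph(rs, h[0, ])
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("connected components become clusters numbered by size then
           smallest member id", {
  set.seed(52)
  rs <- toy_reads(8)
  # component 1: r1-r2-r3; component 2: r7-r8 ; r4-r6 singletons
  h <- make_hits(c("r001", "r002", "r007"), c("r002", "r003", "r008"))
  cl <- cluster_reads(rs, h)
  expect_equal(cl$summary$cluster_id, c("CL1", "CL2"))
  expect_equal(cl$summary$size, c(3L, 2L))
  memb <- cl$membership
  expect_equal(sum(is.na(memb$cluster_id)), 3L)
  # partition: every read in exactly one cluster or singleton
  expect_setequal(memb$read_id, names(rs$seqs))
  # equal-size tie broken by smallest member read id
  h2 <- make_hits(c("r005", "r001"), c("r006", "r002"))
  cl2 <- cluster_reads(rs, h2)
  expect_equal(
    sort(cl2$membership$read_id[cl2$membership$cluster_id == "CL1"]),
    c("r001", "r002"))
})

test_that("a complete graph is never split; two cliques joined by one edge
           are split when refinement is on", {
  set.seed(53)
  rs <- toy_reads(100)
  ids <- names(rs$seqs)
  clique_edges <- function(members) {
    cmb <- t(combn(members, 2))
    make_hits(cmb[, 1], cmb[, 2])
  }
  # one 20-clique: no community structure
  h1 <- clique_edges(ids[1:20])
  cl <- cluster_reads(read_set(rs$seqs[1:20], rs$species[1:20]), h1,
                      refine = TRUE)
  expect_equal(nrow(cl$summary), 1L)
  expect_equal(cl$summary$size, 20L)
  # two 50-cliques bridged by one edge: modularity of the 2-cut is
  # ~0.5 - eps > 0.3, so refinement separates them
  h2 <- rbind(clique_edges(ids[1:50]), clique_edges(ids[51:100]),
              make_hits(ids[50], ids[51]))
  cl_off <- cluster_reads(rs, h2, refine = FALSE)
  expect_equal(nrow(cl_off$summary), 1L)
  cl_on <- cluster_reads(rs, h2, refine = TRUE)
  expect_equal(cl_on$summary$size, c(50L, 50L))
})

test_that("isolated reads yield no clusters above any positive threshold", {
  set.seed(54)
  rs <- toy_reads(5)
  cl <- cluster_reads(rs, make_hits("r001", "r002")[0, ])
  expect_equal(nrow(cl$summary), 0L)
  expect_true(all(is.na(cl$membership$cluster_id)))
})

test_that("composition sums to cluster size and drives specificity calls", {
  set.seed(55)
  rs <- toy_reads(6, species = c("A", "A", "A", "B", "B", "C"))
  h <- make_hits(c("r001", "r002", "r004", "r001"),
                 c("r002", "r003", "r005", "r004"))
  cl <- cluster_reads(rs, h)
  comp <- per_species_composition(cl, "CL1")
  expect_equal(sum(comp), cl$summary$size[1])
  expect_error(per_species_composition(cl, "CL99"), "unknown cluster")
  # direct rule checks
  expect_equal(specificity_call(c(A = 100, B = 0, C = 0)),
               "species-specific:A")
  expect_equal(specificity_call(c(A = 10, B = 10, C = 10, D = 10,
                                  E = 10, F = 10)), "shared-all")
  expect_equal(specificity_call(c(A = 45, B = 55, C = 4)),
               "group-specific:A+B")
})

test_that("clustering is deterministic on identical input", {
  run <- small_run()
  cl2 <- cluster_reads(run$ds$reads, run$hits)
  expect_identical(run$clusters$membership, cl2$membership)
  expect_identical(run$clusters$summary, cl2$summary)
})

test_that("planted families form single near-pure clusters in the small
           simulation", {
  run <- small_run()
  memb <- run$clusters$membership
  tr <- run$ds$truth
  for (f in c("F1", "F2", "F3")) {
    ids <- tr$read_id[tr$family == f]
    cls <- memb$cluster_id[match(ids, memb$read_id)]
    main <- names(sort(table(cls), decreasing = TRUE))[1]
    expect_gt(mean(cls == main, na.rm = TRUE), 0.95)
    # purity: non-junction members of the main cluster come from f
    members <- memb$read_id[!is.na(memb$cluster_id) &
                              memb$cluster_id == main]
    fam_of <- tr$family[match(members, tr$read_id)]
    non_j <- fam_of[fam_of != "junction"]
    expect_gt(mean(non_j == f), 0.95)
  }
})

test_that("a family present in only two species gets the right group call", {
  run <- small_run()
  summ <- cluster_specificity(run$clusters)
  tr <- run$ds$truth
  memb <- run$clusters$membership
  ids <- tr$read_id[tr$family == "F2"] # planted in A and B only
  main <- names(sort(table(memb$cluster_id[match(ids, memb$read_id)]),
                     decreasing = TRUE))[1]
  expect_equal(summ$specificity[summ$cluster_id == main],
               "group-specific:A+B")
  ids3 <- tr$read_id[tr$family == "F3"] # C only
  main3 <- names(sort(table(memb$cluster_id[match(ids3, memb$read_id)]),
                      decreasing = TRUE))[1]
  expect_equal(summ$specificity[summ$cluster_id == main3],
               "species-specific:C")
})
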