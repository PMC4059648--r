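# Shared fixtures: generated in code, deterministic under fixed seeds.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_reads <- function(n, len = 200L, seed = 1L, species = "S1") {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) rand_dna(len), character(1))
  names(seqs) <- paste0(species, "_", seq_len(n))
  read_set(seqs, rep(species, n))
}

mutate_test_seq <- function(seq, p) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(x)) < p)
  bases <- c("A", "C", "G", "T")
  if (length(idx)) {
    cur <- match(x[idx], bases)
    x[idx] <- bases[((cur - 1L + sample.int(3L, length(idx),
                                            replace = TRUE)) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# small three-species simulation used by several unit tests
small_sim_config <- function(seed = 7L, n_reads = 1200L) {
  sim_config(
    tree = "((A:0.01,B:0.01):0.01,C:0.03);",
    background_bp = c(A = 150000, B = 150000, C = 150000),
    families = list(
      family_spec("F1", "dispersed_element", 600,
                  c(A = 40, B = 40, C = 20), 0.01,
                  "Ty1/copia:Angela", ltr_len = 100),
      family_spec("F2", "tandem_satellite", 45, c(A = 250, B = 250),
                  0.02, "satellite:S1"),
      family_spec("F3", "dispersed_element", 500, c(C = 30), 0.01,
                  "LINE")),
    n_reads = n_reads, seed = seed)
}

# memoised pipeline run on the small simulation, shared across test files
.small_run_cache <- new.env(parent = emptyenv())
small_run <- function() {
  if (is.null(.small_run_cache$run)) {
    ds <- simulate_dataset(small_sim_config())
    hits <- find_hits(ds$reads)
    clusters <- cluster_reads(ds$reads, hits)
    .small_run_cache$run <- list(ds = ds, hits = hits, clusters = clusters)
  }
  .small_run_cache$run
}

# memoised full-scale default simulation for the acceptance tests
.default_run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.default_run_cache$run)) {
    ds <- simulate_dataset(default_sim_config(seed = 20260925L))
    hits <- find_hits(ds$reads)
    clusters <- cluster_reads(ds$reads, hits)
    .default_run_cache$run <- list(ds = ds, hits = hits,
                                   clusters = clusters)
  }
  .default_run_cache$run
}
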