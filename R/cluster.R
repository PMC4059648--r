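# Read-graph construction and partition into repeat clusters.

#' Build the read similarity graph
#'
#' Nodes are reads, edges are similarity hits weighted by alignment
#' score.
#'
#' @param reads A [read_set()].
#' @param hits Hit table from [find_hits()]; referencing a read id absent
#'   from `reads` is an error.
#' @return An [igraph::igraph] with vertex attribute `species`.
#' @export
build_read_graph <- function(reads, hits) {
  stopifnot(inherits(reads, "read_set"))
  ids <- names(reads$seqs)
  if (nrow(hits)) {
    bad <- setdiff(unique(c(hits$read_a, hits$read_b)), ids)
    if (length(bad)) {
      stop("hit table references unknown read ids, e.g. ", bad[1L])
    }
  }
  igraph::graph_from_data_frame(
    data.frame(from = hits$read_a, to = hits$read_b, weight = hits$score),
    directed = FALSE,
    vertices = data.frame(name = ids, species = reads$species))
}

# recursively split a component when its best greedy 2-way split gains
# more modularity than the gate
split_component <- function(g, gate) {
  n <- igraph::vcount(g)
  if (n < 4L || igraph::ecount(g) == 0L) {
    return(list(igraph::V(g)$name))
  }
  fg <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  if (length(unique(igraph::membership(fg))) < 2L) {
    return(list(igraph::V(g)$name))
  }
  memb2 <- igraph::cut_at(fg, no = 2L)
  q <- igraph::modularity(g, memb2, weights = igraph::E(g)$weight)
  if (q <= gate) return(list(igraph::V(g)$name))
  out <- list()
  for (part in unique(memb2)) {
    sub <- igraph::induced_subgraph(g, which(memb2 == part))
    out <- c(out, split_component(sub, gate))
  }
  out
}

#' Partition the read graph into repeat clusters
#'
#' The base partition is the connected components of the hit graph — the
#' reference clustering mode. With `refine = TRUE`, any component whose
#' best greedy-agglomerative two-way split has modularity above
#' `modularity_gate` is split recursively, which can separate distinct
#' families bridged by a few chimeric edges. Clusters (components with
#' at least two reads) are numbered `CL1, CL2, ...` by decreasing size,
#' ties broken by the lexicographically smallest member read id;
#' remaining reads are singletons.
#'
#' @param reads A [read_set()].
#' @param hits Hit table from [find_hits()].
#' @param refine Apply modularity-gated splitting (default off).
#' @param modularity_gate Minimum modularity of a two-way split for it to
#'   be applied.
#' @param size_threshold Fraction of all analyzed reads a cluster must
#'   reach to count as a "top" cluster (default 0.03%).
#' @return A `cluster_set`: list with `membership` (data frame `read_id`,
#'   `cluster_id`; singletons have `cluster_id` `NA`), `summary` (data
#'   frame per cluster: `cluster_id`, `size`, `size_frac`, `top`, one
#'   `n_<code>` column per species), `total_reads`, `size_threshold`.
#' @export
cluster_reads <- function(reads, hits, refine = FALSE,
                          modularity_gate = 0.3, size_threshold = 3e-4) {
  g <- build_read_graph(reads, hits)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  if (refine) {
    out <- list()
    for (grp in groups) {
      if (length(grp) < 4L) { out <- c(out, list(grp)); next }
      sub <- igraph::induced_subgraph(g, grp)
      out <- c(out, split_component(sub, modularity_gate))
    }
    groups <- out
  }
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups)) {
    sizes <- vapply(groups, length, integer(1))
    firsts <- vapply(groups, function(x) min(x), character(1))
    ord <- order(-sizes, firsts)
    groups <- groups[ord]
  }
  n_total <- length(reads$seqs)
  sp_of <- setNames(reads$species, names(reads$seqs))
  codes <- sort(unique(reads$species))

  memb <- data.frame(read_id = names(reads$seqs),
                     cluster_id = NA_character_,
                     stringsAsFactors = FALSE)
  rownames(memb) <- memb$read_id
  summ <- data.frame(cluster_id = character(), size = integer(),
                     size_frac = numeric(), top = logical(),
                     stringsAsFactors = FALSE)
  for (cd in codes) summ[[paste0("n_", cd)]] <- integer()
  if (length(groups)) {
    cl_ids <- paste0("CL", seq_along(groups))
    for (i in seq_along(groups)) {
      memb[groups[[i]], "cluster_id"] <- cl_ids[i]
    }
    sizes <- vapply(groups, length, integer(1))
    summ <- data.frame(cluster_id = cl_ids, size = sizes,
                       size_frac = sizes / n_total,
                       top = sizes / n_total >= size_threshold,
                       stringsAsFactors = FALSE)
    for (cd in codes) {
      summ[[paste0("n_", cd)]] <- vapply(
        groups, function(x) sum(sp_of[x] == cd), integer(1))
    }
  }
  rownames(memb) <- NULL
  structure(list(membership = memb, summary = summ,
                 total_reads = n_total, size_threshold = size_threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$summary), "clusters over", x$total_reads,
      "reads;", sum(x$summary$top), "top clusters (size >=",
      format(100 * x$size_threshold), "% of reads)\n")
  print(head(x$summary, 10))
  invisible(x)
}

#' Per-species read composition of one cluster
#'
#' @param clusters A `cluster_set` from [cluster_reads()].
#' @param cluster_id Cluster identifier, e.g. `"CL1"`.
#' @return Named integer vector of read counts per species code; sums to
#'   the cluster size.
#' @export
per_species_composition <- function(clusters, cluster_id) {
  stopifnot(inherits(clusters, "cluster_set"))
  row <- clusters$summary[clusters$summary$cluster_id == cluster_id, ,
                          drop = FALSE]
  if (!nrow(row)) stop("unknown cluster id: ", cluster_id)
  cols <- grep("^n_", names(row), value = TRUE)
  setNames(as.integer(row[1, cols]), sub("^n_", "", cols))
}

#' Call species specificity of a cluster composition
#'
#' A cluster is `species-specific:<code>` when one species holds at least
#' `min_frac_specific` of its reads; `group-specific:<codes>` when the
#' species each holding at least `1 - min_frac_specific` form a proper
#' subset that jointly holds at least `min_frac_specific`; otherwise
#' `shared-all`.
#'
#' @param counts Named vector of per-species read counts (e.g. from
#'   [per_species_composition()]), covering all analyzed species (zeros
#'   included).
#' @param min_frac_specific Specificity threshold (default 0.9).
#' @return A single label string.
#' @export
specificity_call <- function(counts, min_frac_specific = 0.9) {
  tot <- sum(counts)
  if (tot == 0) stop("empty composition")
  shares <- counts / tot
  if (max(shares) >= min_frac_specific) {
    return(paste0("species-specific:", names(which.max(shares))))
  }
  cand <- names(shares)[shares >= (1 - min_frac_specific)]
  if (length(cand) < length(shares) && sum(shares[cand]) >=
      min_frac_specific) {
    return(paste0("group-specific:", paste(sort(cand), collapse = "+")))
  }
  "shared-all"
}

#' Cluster summary with specificity calls
#'
#' Convenience wrapper adding a `specificity` column to the cluster
#' summary table.
#'
#' @param clusters A `cluster_set`.
#' @param min_frac_specific Passed to [specificity_call()].
#' @return The summary data frame with an extra `specificity` column.
#' @export
cluster_specificity <- function(clusters, min_frac_specific = 0.9) {
  summ <- clusters$summary
  cols <- grep("^n_", names(summ), value = TRUE)
  summ$specificity <- vapply(seq_len(nrow(summ)), function(i) {
    specificity_call(setNames(as.integer(summ[i, cols]),
                              sub("^n_", "", cols)),
                     min_frac_specific)
  }, character(1))
  summ
}
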