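# Distance-based phylogenetics: p-distances, Jukes-Cantor correction,
# NJ/BioNJ trees and consensus-anchored read alignment.

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence has a gap (`-`) or `N` are excluded.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return p in \[0, 1\]; error when no site is comparable.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(x) != length(y)) stop("aligned sequences differ in length")
  ok <- !(x %in% c("-", "N")) & !(y %in% c("-", "N"))
  if (!any(ok)) stop("no comparable sites between the sequences")
  mean(x[ok] != y[ok])
}

#' Jukes-Cantor distance from a p-distance
#'
#' `d = -(3/4) log(1 - 4p/3)`; saturated inputs (p >= 0.75) are an
#' error rather than silently capped.
#'
#' @param p Proportion(s) of differing sites.
#' @return Corrected distance(s), `d >= p`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) {
    stop("p >= 0.75: Jukes-Cantor distance saturated (undefined)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix of aligned sequences
#'
#' @param aln Named character vector of aligned sequences (equal length).
#' @return Symmetric distance matrix.
#' @export
jc_distance_matrix <- function(aln) {
  n <- length(aln)
  stopifnot(n >= 2L, !is.null(names(aln)))
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- jc_distance(p_distance(aln[[i]], aln[[j]]))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ or the variance-weighted BioNJ variant. Negative branch
#' lengths produced by the agglomeration are clamped to zero with the
#' deficit moved to the sister branch, preserving path lengths through
#' the parent node.
#'
#' @param d Symmetric distance matrix (or [stats::dist]) over at least
#'   three taxa.
#' @param variant `"nj"` or `"bionj"`.
#' @param clamp_negative Apply the negative-branch correction.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d, variant = c("nj", "bionj"), clamp_negative = TRUE) {
  variant <- match.arg(variant)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tree <- if (variant == "nj") ape::nj(as.dist(d)) else
    ape::bionj(as.dist(d))
  if (clamp_negative && any(tree$edge.length < 0)) {
    for (e in which(tree$edge.length < 0)) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      sib <- which(tree$edge[, 1] == tree$edge[e, 1])
      sib <- setdiff(sib, e)
      if (length(sib)) {
        tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
      }
    }
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' @param t1,t2 [ape::phylo] trees over the same taxa.
#' @return Number of differing bipartitions; 0 means identical
#'   unrooted topology.
#' @export
rf_distance <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}

#' Align reads onto a consensus coordinate system
#'
#' Each read is locally aligned to the consensus (both strands, best
#' kept) and written into a fixed-width row of consensus length;
#' insertions relative to the consensus are dropped, uncovered positions
#' are gaps. Reads with alignment identity below `min_identity` are
#' excluded with a warning. Substitutes a full multiple alignment at
#' read scale.
#'
#' @param reads A [read_set()], `DNAStringSet` or named character vector.
#' @param consensus Consensus sequence (character string).
#' @param min_identity Minimum fraction of a read's bases matching the
#'   consensus in its best local alignment; reads matching over less of
#'   their length (including reads that only graze the consensus) are
#'   excluded.
#' @return Character matrix: one row per kept read (rownames = read
#'   ids), `nchar(consensus)` columns of `A/C/G/T/N/-`.
#' @export
align_to_consensus <- function(reads, consensus, min_identity = 0.5) {
  seqs <- if (inherits(reads, "read_set")) reads$seqs else
    Biostrings::DNAStringSet(reads)
  if (!length(seqs)) return(matrix(character(0), 0, nchar(consensus)))
  cons <- Biostrings::DNAString(consensus)
  clen <- length(cons)

  score_both <- function(x) {
    fw <- Biostrings::pairwiseAlignment(
      x, cons, type = "local", gapOpening = 10, gapExtension = 4,
      scoreOnly = TRUE)
    rv <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(x), cons, type = "local",
      gapOpening = 10, gapExtension = 4, scoreOnly = TRUE)
    rv > fw
  }
  use_rc <- score_both(seqs)
  oriented <- seqs
  if (any(use_rc)) {
    oriented[use_rc] <- Biostrings::reverseComplement(seqs[use_rc])
  }
  pa <- Biostrings::pairwiseAlignment(
    oriented, cons, type = "local", gapOpening = 10, gapExtension = 4)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  sstart <- Biostrings::start(Biostrings::subject(pa))
  pid <- Biostrings::nmatch(pa) / Biostrings::width(oriented)

  keep <- pid >= min_identity
  if (any(!keep)) {
    warning(sum(!keep), " read(s) below ", min_identity,
            " identity to the consensus were excluded")
  }
  out <- matrix("-", nrow = sum(keep), ncol = clen,
                dimnames = list(names(seqs)[keep], NULL))
  ki <- which(keep)
  for (r in seq_along(ki)) {
    i <- ki[r]
    pch <- strsplit(ap[i], "", fixed = TRUE)[[1L]]
    sch <- strsplit(as_[i], "", fixed = TRUE)[[1L]]
    scons <- sch != "-"          # columns that are consensus positions
    cols <- sstart[i] + cumsum(scons) - 1L
    out[r, cols[scons]] <- pch[scons]
  }
  out
}

#' Majority consensus of an alignment matrix
#'
#' @param aln Character matrix from [align_to_consensus()].
#' @param min_cov Minimum non-gap rows for a column call; below it the
#'   column is `N`.
#' @return Consensus string of `ncol(aln)` characters.
#' @export
consensus_sequence <- function(aln, min_cov = 1L) {
  if (!nrow(aln)) stop("empty alignment")
  calls <- apply(aln, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) < min_cov) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  })
  paste(calls, collapse = "")
}

#' Per-species consensus tree of a repeat family from its reads
#'
#' Aligns family reads to a family consensus, builds one majority
#' consensus per species, and estimates an NJ/BioNJ tree from
#' Jukes-Cantor distances of those consensuses. This is the read-level
#' route to a repeat-family phylogeny concordant (or not) with the
#' species tree.
#'
#' @param reads A [read_set()] restricted to the family's reads.
#' @param consensus Family consensus sequence (string).
#' @param variant NJ variant, see [nj_tree()].
#' @param min_sites Minimum comparable consensus columns required per
#'   species pair.
#' @return List with `tree` ([ape::phylo]), `alignment` (per-species
#'   consensus strings), `distances` (JC matrix).
#' @export
family_species_tree <- function(reads, consensus, variant = "bionj",
                                min_sites = 100L) {
  stopifnot(inherits(reads, "read_set"))
  codes <- sort(unique(reads$species))
  if (length(codes) < 3L) stop("need reads from at least 3 species")
  cons_by_sp <- vapply(codes, function(sp) {
    sub <- reads$seqs[reads$species == sp]
    # element-edge reads matching over less than half their length are
    # dropped by design; no need to surface the per-species warning here
    aln <- suppressWarnings(align_to_consensus(sub, consensus))
    consensus_sequence(aln, min_cov = 2L)
  }, character(1))
  ok <- nchar(gsub("[N-]", "", cons_by_sp)) >= min_sites
  if (sum(ok) < 3L) stop("fewer than 3 species with enough covered sites")
  d <- jc_distance_matrix(cons_by_sp[ok])
  list(tree = nj_tree(d, variant), alignment = cons_by_sp[ok],
       distances = d)
}
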