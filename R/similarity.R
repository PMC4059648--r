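# All-to-all read comparison: the similarity hits that define
# repetitiveness and the edges of the read graph.

#' Similarity search parameters
#'
#' The defaults encode the repeat-detection rule used throughout: a read
#' pair is a hit when its best local alignment (either orientation)
#' reaches at least `min_identity` over at least `min_overlap_frac` of
#' the read length — 90% identity over 55% of the read, i.e. 110 nt for
#' 200 nt reads. Identity is matches / alignment columns (gap columns
#' count). Scoring is mgblast-like: +1 match, -2 mismatch, gaps cost 3
#' for the first base and 1 for each additional base.
#'
#' @param min_identity Minimum identity of an accepted hit.
#' @param min_overlap_frac Minimum alignment span as a fraction of the
#'   read length; the nt threshold is `ceiling(frac * read_len)`.
#' @param seed_kmer_len Length of the exact k-mer shared by candidate
#'   pairs in the seeded search (canonical, so both orientations are
#'   covered).
#' @param match,mismatch,gap_open,gap_ext Alignment scores (all positive;
#'   mismatch/gap values are penalties).
#' @return A `similarity_params` object.
#' @export
similarity_params <- function(min_identity = 0.90, min_overlap_frac = 0.55,
                              seed_kmer_len = 16L, match = 1L, mismatch = 2L,
                              gap_open = 3L, gap_ext = 1L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_overlap_frac > 0, min_overlap_frac <= 1,
            seed_kmer_len >= 4L, seed_kmer_len <= 16L)
  structure(list(min_identity = min_identity,
                 min_overlap_frac = min_overlap_frac,
                 seed_kmer_len = as.integer(seed_kmer_len),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext)),
            class = "similarity_params")
}

#' Overlap threshold in nucleotides for a given read length
#' @param params A [similarity_params()].
#' @param read_len Read length in nt.
#' @return Integer number of alignment columns required.
#' @export
min_overlap_nt <- function(params, read_len) {
  # epsilon guards against 0.55 * 200 = 110.0000000000000142
  as.integer(ceiling(params$min_overlap_frac * read_len - 1e-9))
}

#' All-to-all similarity search over a read set
#'
#' Finds every unordered read pair whose best local alignment (forward or
#' reverse-complement) passes the identity and overlap thresholds. The
#' default seeded search considers only pairs sharing at least one exact
#' canonical k-mer; `method = "exhaustive"` aligns all pairs and is the
#' reference the seeded search must reproduce.
#'
#' @param reads A [read_set()] of uniform-length reads.
#' @param params A [similarity_params()].
#' @param method `"seeded"` (k-mer prefilter) or `"exhaustive"`.
#' @return Data frame with one row per hit: `read_a`, `read_b`
#'   (lexicographically ordered ids), `identity`, `overlap` (alignment
#'   columns), `orientation` (`"forward"`/`"reverse"`), `score`.
#' @export
find_hits <- function(reads, params = similarity_params(),
                      method = c("seeded", "exhaustive")) {
  method <- match.arg(method)
  if (!inherits(reads, "read_set")) {
    stop("'reads' must be a read_set; run prepare_reads() on raw reads")
  }
  ids <- names(reads$seqs)
  min_ov <- min_overlap_nt(params, reads$read_len)
  df <- .sw_all_hits(as.character(reads$seqs),
                     params$min_identity, min_ov,
                     params$match, params$mismatch,
                     params$gap_open, params$gap_ext,
                     method == "seeded", params$seed_kmer_len)
  a <- ids[df$a]; b <- ids[df$b]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(read_a = a, read_b = b, identity = df$identity,
                    overlap = df$overlap,
                    orientation = ifelse(df$reverse == 1L, "reverse",
                                         "forward"),
                    score = df$score, stringsAsFactors = FALSE)
  out[order(out$read_a, out$read_b), , drop = FALSE]
}

#' Per-read similarity hit counts, overall and per partner species
#'
#' Counts, for every read of the set, its distinct hit partners in total
#' and split by the partner's species; reads without hits get zero
#' counts. The count of hits within a read's own species is what scales
#' with its copy number in that genome.
#'
#' @param hits Hit table from [find_hits()].
#' @param reads The [read_set()] the hits were computed on.
#' @return Data frame: `read_id`, `species`, `total`, then one
#'   `hits_<code>` column per species code.
#' @export
hits_per_read <- function(hits, reads) {
  stopifnot(inherits(reads, "read_set"))
  ids <- names(reads$seqs)
  codes <- sort(unique(reads$species))
  sp_of <- setNames(reads$species, ids)
  m <- matrix(0L, nrow = length(ids), ncol = length(codes),
              dimnames = list(ids, codes))
  if (nrow(hits)) {
    ends <- c(hits$read_a, hits$read_b)
    partner_sp <- c(sp_of[hits$read_b], sp_of[hits$read_a])
    t2 <- table(factor(ends, levels = ids),
                factor(partner_sp, levels = codes))
    m <- m + unclass(t2)
  }
  out <- data.frame(read_id = ids, species = unname(sp_of[ids]),
                    total = as.integer(rowSums(m)),
                    stringsAsFactors = FALSE)
  for (cd in codes) out[[paste0("hits_", cd)]] <- as.integer(m[, cd])
  out
}

#' Within- and between-species similarity hit totals
#'
#' @param hits Hit table from [find_hits()].
#' @param reads The [read_set()] the hits were computed on.
#' @return Symmetric matrix of hit counts; the diagonal holds
#'   within-species totals.
#' @export
species_pair_summary <- function(hits, reads) {
  stopifnot(inherits(reads, "read_set"))
  codes <- sort(unique(reads$species))
  sp_of <- setNames(reads$species, names(reads$seqs))
  m <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  if (nrow(hits)) {
    sa <- unname(sp_of[hits$read_a]); sb <- unname(sp_of[hits$read_b])
    lo <- pmin(sa, sb); hi <- pmax(sa, sb)
    tab <- table(factor(lo, codes), factor(hi, codes))
    m <- m + unclass(tab)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}
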