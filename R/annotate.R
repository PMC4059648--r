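# Cluster annotation against a labelled repeat reference, protein-domain
# detection in reads, per-label read databases and tandem/dispersed
# calling.

#' Load a labelled repeat reference collection
#'
#' FASTA headers carry the hierarchical taxonomy label after a pipe:
#' `>entry_id|class/lineage:clade`. Entries without a pipe get label
#' `"unknown"`.
#'
#' @param path FASTA file path, or a named `DNAStringSet` whose names
#'   follow the same convention.
#' @return A `repeat_reference`: list with `seqs` (DNAStringSet named by
#'   entry id) and `label` (character vector parallel to `seqs`).
#' @export
read_repeat_reference <- function(path) {
  x <- if (is.character(path) && length(path) == 1L && file.exists(path)) {
    read_fasta(path)
  } else if (methods::is(path, "DNAStringSet")) {
    path
  } else {
    stop("'path' must be a FASTA path or a DNAStringSet")
  }
  if (!length(x)) stop("empty repeat reference")
  parts <- strsplit(names(x), "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  labels <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[2L] else "unknown"
  }, character(1))
  names(x) <- ids
  structure(list(seqs = x, label = labels), class = "repeat_reference")
}

#' Annotate clusters by similarity vote against a repeat reference
#'
#' Each member read of each top cluster is assigned the label of its
#' best-scoring reference entry (local nucleotide alignment at
#' `min_identity` over at least `min_len` nt, either strand); a cluster
#' takes the majority label when enough reads hit the reference and the
#' majority is strong enough, and is `"unclassified repetitive"`
#' otherwise.
#'
#' @param clusters A `cluster_set` from [cluster_reads()].
#' @param reads The clustered [read_set()].
#' @param reference A `repeat_reference` from [read_repeat_reference()].
#' @param min_identity,min_len Per-read nucleotide hit thresholds
#'   (defaults 70% over 60 nt).
#' @param min_vote Minimum fraction of reference-hit reads supporting
#'   the winning label.
#' @param min_hit_reads Minimum number of reference-hit reads.
#' @param seed_kmer_len Seed k-mer length of the read-to-reference
#'   search (shorter than the read-to-read seed because reference hits
#'   may be considerably diverged).
#' @param top_only Annotate only top clusters (default) or all.
#' @return Data frame: `cluster_id`, `label`, `vote_fraction`,
#'   `n_hit_reads`.
#' @export
classify_clusters <- function(clusters, reads, reference,
                              min_identity = 0.70, min_len = 60L,
                              min_vote = 0.6, min_hit_reads = 5L,
                              seed_kmer_len = 12L, top_only = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(reads, "read_set"),
            inherits(reference, "repeat_reference"))
  if (!length(reference$seqs)) stop("empty repeat reference")
  summ <- clusters$summary
  if (top_only) summ <- summ[summ$top, , drop = FALSE]
  out <- data.frame(cluster_id = character(), label = character(),
                    vote_fraction = numeric(), n_hit_reads = integer(),
                    stringsAsFactors = FALSE)
  if (!nrow(summ)) return(out)

  memb <- clusters$membership
  memb <- memb[!is.na(memb$cluster_id) &
                 memb$cluster_id %in% summ$cluster_id, , drop = FALSE]
  seqs <- reads$seqs[memb$read_id]
  hits <- .sw_map_reads(as.character(seqs),
                        as.character(reference$seqs),
                        min_identity, as.integer(min_len),
                        1L, 2L, 3L, 1L, as.integer(seed_kmer_len))
  # best reference entry per read
  read_label <- rep(NA_character_, length(seqs))
  if (nrow(hits)) {
    ord <- order(hits$read, -hits$score)
    hits <- hits[ord, , drop = FALSE]
    first <- !duplicated(hits$read)
    read_label[hits$read[first]] <- reference$label[hits$subject[first]]
  }
  for (cl in summ$cluster_id) {
    lab <- read_label[memb$cluster_id == cl]
    lab <- lab[!is.na(lab)]
    n_hit <- length(lab)
    if (n_hit >= min_hit_reads) {
      tab <- sort(table(lab), decreasing = TRUE)
      vote <- as.numeric(tab[1L]) / n_hit
      label <- if (vote >= min_vote) names(tab)[1L] else
        "unclassified repetitive"
    } else {
      vote <- if (n_hit) max(table(lab)) / n_hit else 0
      label <- "unclassified repetitive"
    }
    out <- rbind(out, data.frame(cluster_id = cl, label = label,
                                 vote_fraction = vote,
                                 n_hit_reads = n_hit,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Detect protein-domain-bearing reads
#'
#' Translates each read in all six frames and aligns the translations
#' locally against a protein reference (BLOSUM62, affine gaps). A read
#' is a domain read when any frame reaches `min_score`; the best frame,
#' strand and reference entry are reported.
#'
#' @param reads A [read_set()] or `DNAStringSet`.
#' @param protein_reference Named `AAStringSet` (or character vector) of
#'   domain sequences.
#' @param min_score Minimum local alignment score.
#' @return Data frame of domain reads: `read_id`, `entry`, `frame`
#'   (+1..+3, -1..-3), `strand`, `score`.
#' @export
detect_domain_reads <- function(reads, protein_reference, min_score = 80) {
  seqs <- if (inherits(reads, "read_set")) reads$seqs else
    Biostrings::DNAStringSet(reads)
  if (is.character(protein_reference)) {
    protein_reference <- Biostrings::AAStringSet(protein_reference)
  }
  if (!length(protein_reference)) stop("empty protein reference")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())

  ids <- names(seqs)
  n <- length(seqs)
  best <- data.frame(read_id = ids, entry = NA_character_,
                     frame = NA_integer_, score = -Inf,
                     stringsAsFactors = FALSE)
  rc <- Biostrings::reverseComplement(seqs)
  for (fr in 1:3) {
    for (strand in c(1L, -1L)) {
      src <- if (strand == 1L) seqs else rc
      w <- Biostrings::width(src)
      keep_len <- w - ((w - fr + 1L) %% 3L) # trim to codon multiple
      sub <- Biostrings::subseq(src, fr, keep_len)
      aa <- suppressWarnings(Biostrings::translate(
        sub, if.fuzzy.codon = "X"))
      aa <- Biostrings::AAStringSet(chartr("*", "X", as.character(aa)))
      for (e in seq_along(protein_reference)) {
        sc <- Biostrings::pairwiseAlignment(
          aa, protein_reference[[e]], type = "local",
          substitutionMatrix = mat, gapOpening = 10, gapExtension = 2,
          scoreOnly = TRUE)
        upd <- sc > best$score
        best$score[upd] <- sc[upd]
        best$frame[upd] <- strand * fr
        best$entry[upd] <- names(protein_reference)[e]
      }
    }
  }
  best <- best[best$score >= min_score, , drop = FALSE]
  best$strand <- ifelse(best$frame > 0, "+", "-")
  rownames(best) <- NULL
  best[, c("read_id", "entry", "frame", "strand", "score")]
}

#' Merge annotated cluster reads into per-label databases
#'
#' Reads of top clusters sharing an annotation label are pooled into one
#' database usable for hit-density annotation of assemblies; clusters
#' without a label are pooled under `"unclassified"`.
#'
#' @param clusters A `cluster_set`.
#' @param annotations Data frame from [classify_clusters()].
#' @param reads The clustered [read_set()].
#' @return Named list of `DNAStringSet`, one per label.
#' @export
build_read_databases <- function(clusters, annotations, reads) {
  summ <- clusters$summary[clusters$summary$top, , drop = FALSE]
  memb <- clusters$membership
  lab_of <- setNames(annotations$label, annotations$cluster_id)
  out <- list()
  for (cl in summ$cluster_id) {
    lab <- if (cl %in% names(lab_of)) unname(lab_of[cl]) else
      "unclassified repetitive"
    if (lab == "unclassified repetitive") lab <- "unclassified"
    ids <- memb$read_id[!is.na(memb$cluster_id) & memb$cluster_id == cl]
    out[[lab]] <- c(out[[lab]], ids)
  }
  lapply(out, function(ids) reads$seqs[ids])
}

#' Flag a cluster's reads as tandem or dispersed
#'
#' Tandem repeats with a unit shorter than the read length repeat within
#' single reads; the modal spacing of identical k-mers inside a read
#' then reveals the unit length. Each read votes for its best-supported
#' positive k-mer self-offset; the cluster is `tandem` when most sampled
#' reads have such a periodicity, `dispersed` otherwise, `unknown` below
#' `min_reads`.
#'
#' @param reads `DNAStringSet` (or character) of cluster member reads.
#' @param min_reads Minimum cluster size for a call (default 20).
#' @param k K-mer length of the periodicity scan.
#' @param min_support Minimum identical-k-mer pairs at the modal offset
#'   for a read to vote tandem.
#' @param max_sample Reads sampled per cluster for the scan.
#' @return List with `flag` (`"tandem"`, `"dispersed"` or `"unknown"`),
#'   `period` (median modal offset of tandem-voting reads, or `NA`) and
#'   `vote` (fraction of reads voting tandem).
#' @export
tandem_detect <- function(reads, min_reads = 20L, k = 8L,
                          min_support = 5L, max_sample = 100L) {
  seqs <- if (inherits(reads, "read_set")) reads$seqs else
    Biostrings::DNAStringSet(reads)
  if (length(seqs) < min_reads) {
    return(list(flag = "unknown", period = NA_real_, vote = NA_real_))
  }
  idx <- if (length(seqs) > max_sample) {
    sample.int(length(seqs), max_sample)
  } else {
    seq_along(seqs)
  }
  periods <- vapply(as.character(seqs[idx]), function(s) {
    n <- nchar(s)
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    pos <- split(seq_along(kmers), kmers)
    pos <- pos[lengths(pos) > 1L]
    if (!length(pos)) return(NA_real_)
    offs <- unlist(lapply(pos, function(p) diff(sort(p))), use.names = FALSE)
    offs <- offs[offs >= k] # ignore homopolymer-style micro-offsets
    if (!length(offs)) return(NA_real_)
    tab <- table(offs)
    if (max(tab) < min_support) return(NA_real_)
    as.numeric(names(tab)[which.max(tab)])
  }, numeric(1), USE.NAMES = FALSE)
  vote <- mean(!is.na(periods))
  if (vote > 0.5) {
    list(flag = "tandem", period = median(periods, na.rm = TRUE),
         vote = vote)
  } else {
    list(flag = "dispersed", period = NA_real_, vote = vote)
  }
}
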