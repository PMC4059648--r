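# Hit-density annotation of assembled sequences against read databases:
# per-window counts of read similarity hits and derived repeat intervals.

#' Sliding-window hit-density tracks of an assembly
#'
#' Maps every read of every database onto the assembly (k-mer seeded
#' local alignment, both strands) and counts, per window, the reads
#' whose best alignment footprint overlaps the window, one track per
#' database. The similarity rule is the read-to-read rule applied
#' read-length-relatively: at least `min_identity` over
#' `min_overlap_frac` of the read length.
#'
#' @param assembly A single sequence: character string, `DNAString` or
#'   `DNAStringSet` of length 1.
#' @param databases Named list of read databases (`DNAStringSet` or
#'   character vectors), e.g. from [build_read_databases()].
#' @param window Window size in nt (default 100).
#' @param step Window step in nt (default 50); must not exceed `window`,
#'   and `window` must not exceed the assembly length.
#' @param params A [similarity_params()].
#' @return A `density_tracks` object: list with `windows` (data frame
#'   `start`, `end`, 1-based closed), `counts` (matrix windows x
#'   databases), `window`, `step`, `seq_len`, `hits` (per-read best
#'   footprints).
#' @export
density_tracks <- function(assembly, databases, window = 100L, step = 50L,
                           params = similarity_params()) {
  if (methods::is(assembly, "DNAStringSet")) {
    stopifnot(length(assembly) == 1L)
    assembly <- as.character(assembly[[1L]])
  } else if (methods::is(assembly, "DNAString")) {
    assembly <- as.character(assembly)
  }
  L <- nchar(assembly)
  if (window > L) stop("window larger than the assembly sequence")
  if (step > window) stop("step must not exceed window")
  if (is.null(names(databases)) || any(names(databases) == "")) {
    stop("'databases' must be a named list")
  }
  n_win <- (L - window) %/% step + 1L
  wstart <- (seq_len(n_win) - 1L) * step + 1L
  wend <- wstart + window - 1L
  counts <- matrix(0L, n_win, length(databases),
                   dimnames = list(NULL, names(databases)))
  hit_list <- list()
  for (db in names(databases)) {
    rd <- databases[[db]]
    if (is.character(rd)) rd <- Biostrings::DNAStringSet(rd)
    if (!length(rd)) next
    rlen <- Biostrings::width(rd)
    min_ov <- as.integer(ceiling(params$min_overlap_frac * min(rlen) - 1e-9))
    hits <- .sw_map_reads(as.character(rd), assembly,
                          params$min_identity, min_ov,
                          params$match, params$mismatch,
                          params$gap_open, params$gap_ext,
                          params$seed_kmer_len)
    if (nrow(hits)) {
      # windows overlapping footprint [sstart, send]:
      # wstart <= send and wend >= sstart
      i_max <- pmin(n_win, (hits$send - 1L) %/% step + 1L)
      i_min <- pmax(1L, (hits$sstart - window) %/% step + 2L)
      for (h in seq_len(nrow(hits))) {
        if (i_min[h] <= i_max[h]) {
          idx <- i_min[h]:i_max[h]
          counts[idx, db] <- counts[idx, db] + 1L
        }
      }
      hits$database <- db
      hits$read_id <- names(rd)[hits$read]
      hit_list[[db]] <- hits
    }
  }
  structure(list(windows = data.frame(start = wstart, end = wend),
                 counts = counts, window = window, step = step,
                 seq_len = L,
                 hits = if (length(hit_list)) do.call(rbind, hit_list)
                        else NULL),
            class = "density_tracks")
}

#' @export
print.density_tracks <- function(x, ...) {
  cat("density_tracks:", nrow(x$counts), "windows (", x$window, "/",
      x$step, "nt ) x", ncol(x$counts), "databases on a", x$seq_len,
      "nt sequence\n")
  invisible(x)
}

#' Call repeat intervals from density tracks
#'
#' Windows where any track reaches `min_density` form runs; runs are
#' merged across gaps up to `merge_gap` nt, intervals shorter than
#' `min_len` are discarded, and each surviving interval is labelled
#' with the database of highest mean density over it (ties ->
#' `"ambiguous"`).
#'
#' @param tracks A `density_tracks` object.
#' @param min_density Minimum per-window hit count.
#' @param min_len Minimum interval length in nt.
#' @param merge_gap Maximum gap bridged when merging intervals.
#' @param seqid Sequence name used in the output.
#' @return Data frame (1-based closed): `seqid`, `start`, `end`,
#'   `label`, `mean_density`; writable with [write_gff3()]/[write_bed()].
#' @export
call_intervals <- function(tracks, min_density = 2L, min_len = 150L,
                           merge_gap = 200L, seqid = "assembly") {
  stopifnot(inherits(tracks, "density_tracks"))
  empty <- data.frame(seqid = character(), start = integer(),
                      end = integer(), label = character(),
                      mean_density = numeric(), stringsAsFactors = FALSE)
  qual <- apply(tracks$counts >= min_density, 1L, any)
  if (!any(qual)) return(empty)
  w <- tracks$windows
  r <- rle(qual)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- data.frame(start = w$start[starts_i[r$values]],
                     end = w$end[ends_i[r$values]])
  # merge across small gaps
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, ,
                   drop = FALSE]
  if (!nrow(merged)) return(empty)
  lab <- character(nrow(merged))
  md <- numeric(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    in_iv <- w$start <= merged$end[i] & w$end >= merged$start[i]
    means <- colMeans(tracks$counts[in_iv, , drop = FALSE])
    top <- which(means == max(means))
    lab[i] <- if (length(top) > 1L) "ambiguous" else names(means)[top]
    md[i] <- max(means)
  }
  data.frame(seqid = seqid, start = merged$start, end = merged$end,
             label = lab, mean_density = md, stringsAsFactors = FALSE)
}

#' Jaccard overlap of two interval sets
#'
#' Utility for comparing called repeat intervals with truth coordinates:
#' intersection over union of the covered bases.
#'
#' @param a,b Data frames with `start`, `end` (1-based closed).
#' @return Jaccard index in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  ra <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
  rb <- IRanges::reduce(IRanges::IRanges(b$start, b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) return(1)
  inter / uni
}
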