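# Quantitative readouts: genome proportions, repeat fractions,
# copy-number estimates and inter-species abundance scatter tables.
# Genome proportion is measured in read-count space: sampled reads are
# the unit of genome mass, so a cluster holding x% of a species' reads
# is estimated to occupy x% of that genome.

#' Genome proportion of a cluster in one species
#'
#' @param clusters A `cluster_set` from [cluster_reads()].
#' @param cluster_id Cluster identifier.
#' @param species Species code.
#' @param n_reads_species Named vector of analyzed read counts per
#'   species (e.g. [per_species_counts()]).
#' @return Percentage of the species' analyzed reads in the cluster.
#' @export
genome_proportion <- function(clusters, cluster_id, species,
                              n_reads_species) {
  comp <- per_species_composition(clusters, cluster_id)
  if (!species %in% names(n_reads_species)) {
    stop("unknown species: ", species)
  }
  100 * unname(comp[species]) / unname(n_reads_species[species])
}

#' Per-cluster, per-species genome proportion table
#'
#' @param clusters A `cluster_set`.
#' @param reads The [read_set()] that was clustered.
#' @param top_only Restrict to top clusters.
#' @return Data frame: `cluster_id`, `species`, `percent`.
#' @export
proportion_table <- function(clusters, reads, top_only = TRUE) {
  n_sp <- per_species_counts(reads)
  summ <- clusters$summary
  if (top_only) summ <- summ[summ$top, , drop = FALSE]
  cols <- grep("^n_", names(summ), value = TRUE)
  codes <- sub("^n_", "", cols)
  out <- list()
  for (i in seq_len(nrow(summ))) {
    out[[i]] <- data.frame(
      cluster_id = summ$cluster_id[i], species = codes,
      percent = 100 * as.integer(summ[i, cols]) / as.numeric(n_sp[codes]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(), species = character(),
                      percent = numeric()))
  }
  do.call(rbind, out)
}

#' Fraction of reads with at least one similarity hit
#'
#' The basic estimate of the repetitive fraction of a genome: at low
#' coverage, only repeated sequences generate read-to-read hits.
#'
#' @param per_read Per-read counts from [hits_per_read()].
#' @param species Optional species code; default reports every species.
#' @return Named numeric vector of percentages in \[0, 100\].
#' @export
repeat_fraction <- function(per_read, species = NULL) {
  if (is.null(species)) species <- sort(unique(per_read$species))
  vapply(setNames(species, species), function(sp) {
    sub <- per_read[per_read$species == sp, , drop = FALSE]
    if (!nrow(sub)) return(0)
    100 * mean(sub$total >= 1L)
  }, numeric(1))
}

#' Copy-number model from the overlap window
#'
#' Two reads of length `L` overlap by at least `o_min` exactly when their
#' start positions differ by at most `L - o_min`, a window of
#' `2(L - o_min) + 1` positions. A single-copy locus therefore yields
#' `h = N (2(L - o_min) + 1) / G` expected within-species hits per read,
#' and `hits / h` estimates the copy number per haploid genome.
#' Classing bounds are strict: medium above 100 copies/1C, high above
#' 1000 copies/1C.
#'
#' @param read_len Read length `L` (nt).
#' @param min_overlap Overlap threshold `o_min` (nt).
#' @param n_reads Analyzed reads `N` of the species.
#' @param genome_size Haploid genome size `G` (bp).
#' @param medium_above,high_above Class bounds (copies/1C, strict).
#' @return A `copy_number_model` object.
#' @export
copy_number_model <- function(read_len, min_overlap, n_reads, genome_size,
                              medium_above = 100, high_above = 1000) {
  stopifnot(genome_size > 0, n_reads > 0, read_len > min_overlap)
  h <- n_reads * (2 * (read_len - min_overlap) + 1) / genome_size
  structure(list(read_len = read_len, min_overlap = min_overlap,
                 n_reads = n_reads, genome_size = genome_size, h = h,
                 medium_above = medium_above, high_above = high_above),
            class = "copy_number_model")
}

#' Estimate copy number from a read's hit count
#'
#' @param n_hits Number of within-species similarity hits of the read(s);
#'   vectorized.
#' @param model A [copy_number_model()].
#' @return Estimated copies per haploid genome (`n_hits / h`).
#' @export
copy_number_estimate <- function(n_hits, model) {
  stopifnot(inherits(model, "copy_number_model"))
  if (model$h <= 0) stop("model hit rate h must be positive")
  n_hits / model$h
}

#' Class a copy-number estimate as low / medium / high
#'
#' @param k_hat Copy-number estimate(s).
#' @param model A [copy_number_model()] carrying the class bounds.
#' @return Factor with levels `low`, `medium`, `high`; bounds are strict
#'   (exactly 100 or 1000 copies remains in the lower class).
#' @export
classify_copy_number <- function(k_hat, model) {
  cls <- ifelse(k_hat > model$high_above, "high",
                ifelse(k_hat > model$medium_above, "medium", "low"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Pairwise-species hit scatter table
#'
#' One row per analyzed read with its hit counts in two species; reads
#' of equal genomic abundance in both species lie near the diagonal
#' after normalizing by the per-species read counts.
#'
#' @param per_read Per-read counts from [hits_per_read()].
#' @param species_a,species_b Species codes.
#' @return Data frame: `read_id`, `species`, `hits_a`, `hits_b`.
#' @export
scatter_table <- function(per_read, species_a, species_b) {
  ca <- paste0("hits_", species_a); cb <- paste0("hits_", species_b)
  if (!all(c(ca, cb) %in% names(per_read))) {
    stop("unknown species code(s): ", species_a, ", ", species_b)
  }
  data.frame(read_id = per_read$read_id, species = per_read$species,
             hits_a = per_read[[ca]], hits_b = per_read[[cb]],
             stringsAsFactors = FALSE)
}

#' Per-species repeat accounting report
#'
#' Splits each genome into annotated repeats (labelled top clusters),
#' unclassified repeats (reads with hits outside labelled top clusters)
#' and the low-copy remainder (reads without hits); the three close to
#' 100% by construction. Also sums genome proportions per annotation
#' label.
#'
#' @param clusters A `cluster_set`.
#' @param annotations Data frame from [classify_clusters()] (`cluster_id`,
#'   `label`); clusters missing from it count as unclassified.
#' @param reads The clustered [read_set()].
#' @param per_read Per-read counts from [hits_per_read()].
#' @return List of data frames: `by_species` (species, repeat_fraction,
#'   annotated, unclassified, low_copy) and `by_label` (species, label,
#'   percent).
#' @export
abundance_report <- function(clusters, annotations, reads, per_read) {
  n_sp <- per_species_counts(reads)
  codes <- names(n_sp)
  summ <- clusters$summary[clusters$summary$top, , drop = FALSE]
  lab_of <- setNames(annotations$label, annotations$cluster_id)
  rf <- repeat_fraction(per_read)

  by_label <- list()
  annotated <- setNames(numeric(length(codes)), codes)
  if (nrow(summ)) {
    labels <- ifelse(summ$cluster_id %in% names(lab_of),
                     unname(lab_of[summ$cluster_id]),
                     "unclassified repetitive")
    for (cd in codes) {
      pc <- 100 * summ[[paste0("n_", cd)]] / n_sp[cd]
      agg <- tapply(pc, labels, sum)
      by_label[[cd]] <- data.frame(species = cd, label = names(agg),
                                   percent = as.numeric(agg),
                                   stringsAsFactors = FALSE)
      annotated[cd] <- sum(pc[labels != "unclassified repetitive"])
    }
  }
  by_species <- data.frame(
    species = codes,
    repeat_fraction = as.numeric(rf[codes]),
    annotated = as.numeric(annotated),
    unclassified = as.numeric(rf[codes] - annotated),
    low_copy = as.numeric(100 - rf[codes]),
    stringsAsFactors = FALSE)
  list(by_species = by_species,
       by_label = if (length(by_label)) do.call(rbind, by_label) else
         data.frame(species = character(), label = character(),
                    percent = numeric()))
}
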