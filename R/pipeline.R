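# End-to-end orchestration: simulate -> prepare -> all-to-all hits ->
# cluster -> quantify -> annotate -> coverage stats, with every stage
# result written to files so any stage can be re-run in isolation.

#' Build a repeat reference from a simulation's planted families
#'
#' Entry per family: the ancestral consensus, labelled with the family's
#' class label (`<family_id>|<class_label>` header convention).
#'
#' @param sim A `sim_genomes` object.
#' @return A `repeat_reference`.
#' @export
reference_from_sim <- function(sim) {
  stopifnot(inherits(sim, "sim_genomes"))
  seqs <- Biostrings::DNAStringSet(
    vapply(sim$consensus, `[[`, character(1), "ancestral"))
  labs <- vapply(sim$config$families, `[[`, character(1), "class_label")
  names(seqs) <- paste0(names(sim$consensus), "|", labs)
  read_repeat_reference(seqs)
}

#' Serialize / load a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fams <- lapply(config$families, function(f) {
    list(family_id = f$family_id, kind = f$kind, unit_len = f$unit_len,
         copies = as.list(f$copies),
         intra_divergence = f$intra_divergence,
         class_label = f$class_label,
         ltr_len = f$ltr_len, orf = f$orf)
  })
  yaml::write_yaml(list(
    tree = if (is.null(config$tree)) NULL else
      ape::write.tree(config$tree),
    background_bp = as.list(config$background_bp),
    families = fams, read_len = config$read_len,
    n_reads = config$n_reads, error_rate = config$error_rate,
    min_gap = config$min_gap, seed = config$seed), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  fams <- lapply(y$families, function(f) {
    family_spec(f$family_id, f$kind, f$unit_len,
                unlist(f$copies), f$intra_divergence, f$class_label,
                ltr_len = f$ltr_len,
                orf = if (is.null(f$orf)) NULL else as.integer(f$orf))
  })
  sim_config(tree = y$tree, background_bp = unlist(y$background_bp),
             families = fams, read_len = y$read_len, n_reads = y$n_reads,
             error_rate = y$error_rate, min_gap = y$min_gap,
             seed = y$seed)
}

#' Run the full repeat-profiling pipeline on a simulated dataset
#'
#' Stages: genome simulation, read sampling, all-to-all similarity
#' search, graph clustering, quantification, annotation against the
#' planted-family reference, and coverage statistics. All stage outputs
#' are written as FASTA/TSV under `out_dir` together with a manifest
#' (parameters, package version, output checksums). Given the same
#' config (whose seed governs all randomness) the outputs are
#' byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()]; its `seed` fixes all randomness.
#' @param params A [similarity_params()].
#' @param refine,modularity_gate,size_threshold Clustering options, see
#'   [cluster_reads()].
#' @param reference Optional `repeat_reference`; default is the planted
#'   families' own consensuses.
#' @return Invisibly, a list with all in-memory stage results
#'   (`sim`, `reads`, `truth`, `hits`, `per_read`, `clusters`,
#'   `annotations`, `report`, `coverage`, `manifest`).
#' @export
run_pipeline <- function(out_dir, config = default_sim_config(),
                         params = similarity_params(), refine = FALSE,
                         modularity_gate = 0.3, size_threshold = 3e-4,
                         reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ds <- stage("simulate", simulate_dataset(config))
  write_fasta(ds$sim$genomes, file.path(out_dir, "genomes.fasta"))
  write_fasta(ds$reads$seqs, file.path(out_dir, "reads.fasta"))
  write_tsv(ds$truth, file.path(out_dir, "read_truth.tsv"))
  write_tsv(ds$sim$proportions, file.path(out_dir, "truth_proportions.tsv"))
  cp <- ds$sim$copies
  if (nrow(cp)) {
    write_gff3(data.frame(seqid = cp$species, start = cp$start,
                          end = cp$end, label = cp$family,
                          strand = cp$strand),
               file.path(out_dir, "planted_copies.gff3"))
  }

  hits <- stage("allhits", find_hits(ds$reads, params))
  write_tsv(hits, file.path(out_dir, "hits.tsv"))
  per_read <- stage("counts", hits_per_read(hits, ds$reads))
  write_tsv(per_read, file.path(out_dir, "per_read_hits.tsv"))
  pair_sum <- species_pair_summary(hits, ds$reads)
  write_tsv(data.frame(species = rownames(pair_sum), pair_sum),
            file.path(out_dir, "species_pair_hits.tsv"))

  clusters <- stage("cluster", cluster_reads(
    ds$reads, hits, refine = refine, modularity_gate = modularity_gate,
    size_threshold = size_threshold))
  write_tsv(clusters$membership, file.path(out_dir, "cluster_members.tsv"))

  if (is.null(reference)) reference <- reference_from_sim(ds$sim)
  ann <- stage("annotate", classify_clusters(clusters, ds$reads, reference))
  summ <- cluster_specificity(clusters)
  summ$label <- ifelse(summ$cluster_id %in% ann$cluster_id,
                       ann$label[match(summ$cluster_id, ann$cluster_id)],
                       NA_character_)
  write_tsv(summ, file.path(out_dir, "cluster_summary.tsv"))

  report <- stage("quantify", abundance_report(clusters, ann, ds$reads,
                                               per_read))
  write_tsv(report$by_species, file.path(out_dir, "abundance_species.tsv"))
  write_tsv(report$by_label, file.path(out_dir, "abundance_labels.tsv"))

  glen <- Biostrings::width(ds$sim$genomes)
  covtab <- stage("covstats", coverage_table(
    data.frame(code = names(ds$sim$genomes), genome_mb = glen / 1e6),
    n_reads = config$n_reads, read_len = config$read_len))
  write_tsv(covtab, file.path(out_dir, "coverage_stats.tsv"))

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "repeatscape",
    version = as.character(utils::packageVersion("repeatscape")),
    seed = config$seed,
    n_reads = config$n_reads, read_len = config$read_len,
    error_rate = config$error_rate,
    similarity = unclass(params),
    clustering = list(refine = refine, modularity_gate = modularity_gate,
                      size_threshold = size_threshold),
    checksums = as.list(tools::md5sum(sort(outputs))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(sim = ds$sim, reads = ds$reads, truth = ds$truth,
                 hits = hits, per_read = per_read, clusters = clusters,
                 annotations = ann, report = report, coverage = covtab,
                 manifest = manifest))
}
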