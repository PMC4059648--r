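# Synthetic genome / read simulator with full ground truth.
#
# Family consensus sequences evolve along a species tree by symmetric
# (Jukes-Cantor style) substitutions; genomic copies are the species-level
# consensus further mutated at the family's intra-family divergence and
# inserted at uniform non-overlapping positions (dispersed elements) or as
# head-to-tail arrays (tandem satellites, rDNA-like repeats). Reads are
# fixed-length, uniform-start, strand-symmetric, with an optional per-base
# substitution error rate. Substitution-only evolution keeps alignment
# oracles exact.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# stop-free random codons (for planted protein-coding domains)
random_orf <- function(n_codons) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# substitute each base independently with probability p (to a different base)
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(runif(length(x)) < p)
  if (length(idx)) {
    cur <- match(x[idx], BASES)
    x[idx] <- BASES[((cur - 1L + sample.int(3L, length(idx),
                                            replace = TRUE)) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# expected proportion of differing sites after evolving a branch of length
# b (expected substitutions/site) under the Jukes-Cantor model
jc_p_sub <- function(b) 0.75 * (1 - exp(-4 * b / 3))

#' Specify a planted repeat family
#'
#' @param family_id Unique family identifier.
#' @param kind One of `"dispersed_element"`, `"tandem_satellite"`,
#'   `"rdna_like"`.
#' @param unit_len Consensus (monomer) length in nt, at least 50.
#' @param copies Named integer vector: copy count (dispersed) or unit
#'   count (tandem) per species code; species absent or 0 carry no trace
#'   of the family.
#' @param intra_divergence Per-copy substitution probability relative to
#'   the species-level consensus, in \[0, 0.25\].
#' @param class_label Hierarchical repeat taxonomy label, e.g.
#'   `"Ty1/copia:Maximus-SIRE"`.
#' @param ltr_len For dispersed LTR-like elements: length of the terminal
#'   repeat; the consensus then begins and ends with the same `ltr_len`
#'   bases, so every copy is LTR-internal-LTR.
#' @param orf Optional `c(start, n_codons)`: a stop-codon-free reading
#'   frame planted at `start` (1-based) of the consensus, usable as a
#'   protein-domain anchor.
#' @return A `family_spec` object.
#' @export
family_spec <- function(family_id, kind, unit_len, copies,
                        intra_divergence = 0.01, class_label = "unknown",
                        ltr_len = NULL, orf = NULL) {
  kind <- match.arg(kind, c("dispersed_element", "tandem_satellite",
                            "rdna_like"))
  min_unit <- if (kind == "tandem_satellite") 20L else 50L
  if (unit_len < min_unit) {
    stop("unit_len must be >= ", min_unit, " for kind ", kind)
  }
  if (intra_divergence < 0 || intra_divergence > 0.25) {
    stop("intra_divergence must be in [0, 0.25]")
  }
  if (is.null(names(copies)) || any(names(copies) == "")) {
    stop("'copies' must be named by species code")
  }
  if (!is.null(ltr_len) && 2 * ltr_len >= unit_len) {
    stop("2 * ltr_len must be < unit_len")
  }
  if (!is.null(orf) && (orf[1] + 3 * orf[2] - 1 > unit_len)) {
    stop("orf does not fit in the consensus")
  }
  structure(list(family_id = family_id, kind = kind,
                 unit_len = as.integer(unit_len),
                 copies = copies, intra_divergence = intra_divergence,
                 class_label = class_label, ltr_len = ltr_len, orf = orf),
            class = "family_spec")
}

#' Simulation configuration
#'
#' @param tree A species tree: `ape::phylo` object or newick string with
#'   branch lengths in expected substitutions/site; `NULL` for a single
#'   undiverged set of species (family consensuses used as-is).
#' @param background_bp Named integer vector: background (non-repeat)
#'   length per species; genome length is background plus planted copies.
#' @param families List of [family_spec()] objects.
#' @param read_len Read length in nt.
#' @param n_reads Reads sampled per species.
#' @param error_rate Per-base substitution error probability in reads.
#' @param min_gap Minimum background gap between consecutive planted
#'   insertions; the default (one read length) guarantees no read can
#'   bridge two distinct families.
#' @param seed Integer seed fixing all randomness of the simulation.
#' @return A `sim_config` object.
#' @export
sim_config <- function(tree, background_bp, families, read_len = 200L,
                       n_reads = 5000L, error_rate = 0.005,
                       min_gap = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  species <- if (is.null(tree)) names(background_bp) else tree$tip.label
  if (is.null(names(background_bp))) {
    background_bp <- setNames(rep(background_bp[1L], length(species)),
                              species)
  }
  if (!setequal(names(background_bp), species)) {
    stop("background_bp names must match the tree's species codes")
  }
  for (f in families) {
    bad <- setdiff(names(f$copies), species)
    if (length(bad)) {
      stop("family ", f$family_id, " names unknown species: ",
           paste(bad, collapse = ", "))
    }
  }
  ids <- vapply(families, function(f) f$family_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate family ids")
  if (is.null(min_gap)) min_gap <- read_len
  structure(list(tree = tree, species = species,
                 background_bp = background_bp[species],
                 families = families, read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "sim_config")
}

# per-species consensus of one family: ancestral sequence evolved along
# the tree (parent-before-child edge walk); NULL tree = no divergence
evolve_family_consensus <- function(anc, tree, species) {
  if (is.null(tree)) {
    return(setNames(rep(anc, length(species)), species))
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- max(tree$edge)
  seqs <- vector("character", nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1L]
  seqs[root] <- anc
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    seqs[chd] <- mutate_seq(seqs[par], jc_p_sub(tree$edge.length[e]))
  }
  setNames(seqs[seq_along(tree$tip.label)], tree$tip.label)[species]
}

# split k tandem units into 1-3 arrays
tandem_array_sizes <- function(k) {
  n_arr <- min(3L, max(1L, ceiling(k / 600)))
  sizes <- rep(k %/% n_arr, n_arr)
  if (k %% n_arr) sizes[seq_len(k %% n_arr)] <- sizes[seq_len(k %% n_arr)] + 1L
  sizes
}

#' Build simulated genomes with planted repeat families
#'
#' Evolves each family's ancestral consensus along the species tree,
#' mutates every genomic copy at the family's intra-family divergence
#' (half of all insertions on the reverse strand), and places insertions
#' at uniform positions in the species background with a minimum
#' inter-insertion gap. Returns genomes, the planted-copy coordinate
#' table, per-family truth proportions and the ancestral/species
#' consensuses.
#'
#' @param config A [sim_config()].
#' @return A `sim_genomes` object: list with `genomes` (named
#'   `DNAStringSet`), `copies` (data frame: species, family, start, end,
#'   strand, kind, class_label; 1-based closed), `proportions` (data
#'   frame: species, family, percent, including a `background` row per
#'   species), `consensus` (list per family: `ancestral`, per-species
#'   character vector), `config`.
#' @export
evolve_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  species <- config$species

  # ancestral + species-level consensuses
  consensus <- list()
  for (f in config$families) {
    anc <- random_dna(f$unit_len)
    if (!is.null(f$orf)) {
      orf <- random_orf(f$orf[2])
      substr(anc, f$orf[1], f$orf[1] + 3 * f$orf[2] - 1) <- orf
    }
    if (!is.null(f$ltr_len)) {
      substr(anc, f$unit_len - f$ltr_len + 1L, f$unit_len) <-
        substr(anc, 1L, f$ltr_len)
    }
    consensus[[f$family_id]] <-
      list(ancestral = anc,
           species = evolve_family_consensus(anc, config$tree, species))
  }

  genomes <- setNames(vector("list", length(species)), species)
  copies_tab <- list()
  prop_tab <- list()

  for (sp in species) {
    inserts <- list()
    for (f in config$families) {
      k <- f$copies[sp]
      if (is.na(k) || k == 0L) next
      cons <- consensus[[f$family_id]]$species[[sp]]
      if (f$kind == "dispersed_element") {
        for (i in seq_len(k)) {
          s <- mutate_seq(cons, f$intra_divergence)
          rev <- runif(1) < 0.5
          inserts[[length(inserts) + 1L]] <-
            list(fam = f$family_id, kind = f$kind,
                 class_label = f$class_label,
                 seq = if (rev) revcomp_chr(s) else s,
                 strand = if (rev) "-" else "+")
        }
      } else { # tandem array(s)
        for (asz in tandem_array_sizes(k)) {
          units <- vapply(seq_len(asz),
                          function(i) mutate_seq(cons, f$intra_divergence),
                          character(1))
          arr <- paste(units, collapse = "")
          rev <- runif(1) < 0.5
          inserts[[length(inserts) + 1L]] <-
            list(fam = f$family_id, kind = f$kind,
                 class_label = f$class_label,
                 seq = if (rev) revcomp_chr(arr) else arr,
                 strand = if (rev) "-" else "+")
        }
      }
    }
    bg_len <- config$background_bp[sp]
    n_ins <- length(inserts)
    if (n_ins) inserts <- inserts[sample.int(n_ins)]
    free <- bg_len - (n_ins - 1L) * config$min_gap
    if (n_ins > 0L && free <= n_ins) {
      stop("insufficient background space in species ", sp,
           " for ", n_ins, " insertions with min_gap ", config$min_gap)
    }
    bg <- random_dna(bg_len)
    if (n_ins == 0L) {
      genomes[[sp]] <- bg
      prop_tab[[length(prop_tab) + 1L]] <-
        data.frame(species = sp, family = "background", percent = 100)
      next
    }
    pos <- floor(sort(runif(n_ins, 0, free))) +
      (seq_len(n_ins) - 1L) * config$min_gap  # insertion points in bg coords
    lens <- vapply(inserts, function(i) nchar(i$seq), integer(1))
    offset <- c(0L, cumsum(lens))[seq_len(n_ins)]
    starts <- pos + offset + 1L   # 1-based in final genome
    ends <- starts + lens - 1L
    pieces <- character(2L * n_ins + 1L)
    prev <- 0L
    for (i in seq_len(n_ins)) {
      pieces[2L * i - 1L] <- substr(bg, prev + 1L, pos[i])
      pieces[2L * i] <- inserts[[i]]$seq
      prev <- pos[i]
    }
    pieces[2L * n_ins + 1L] <- substr(bg, prev + 1L, bg_len)
    genomes[[sp]] <- paste(pieces, collapse = "")
    g_len <- bg_len + sum(lens)
    stopifnot(nchar(genomes[[sp]]) == g_len)
    copies_tab[[length(copies_tab) + 1L]] <- data.frame(
      species = sp,
      family = vapply(inserts, `[[`, character(1), "fam"),
      start = starts, end = ends,
      strand = vapply(inserts, `[[`, character(1), "strand"),
      kind = vapply(inserts, `[[`, character(1), "kind"),
      class_label = vapply(inserts, `[[`, character(1), "class_label"),
      stringsAsFactors = FALSE)
    fam_len <- tapply(lens, vapply(inserts, `[[`, character(1), "fam"), sum)
    prop_tab[[length(prop_tab) + 1L]] <- rbind(
      data.frame(species = sp, family = names(fam_len),
                 percent = 100 * as.numeric(fam_len) / g_len),
      data.frame(species = sp, family = "background",
                 percent = 100 * bg_len / g_len))
  }

  structure(list(
    genomes = Biostrings::DNAStringSet(unlist(genomes)),
    copies = if (length(copies_tab)) do.call(rbind, copies_tab) else
      data.frame(),
    proportions = do.call(rbind, prop_tab),
    consensus = consensus,
    config = config), class = "sim_genomes")
}

#' @export
print.sim_genomes <- function(x, ...) {
  cat("sim_genomes:", length(x$genomes), "species, genome sizes",
      paste(Biostrings::width(x$genomes), collapse = "/"), "bp,",
      length(x$consensus), "planted families\n")
  invisible(x)
}

#' Sample shotgun reads from simulated genomes
#'
#' Start positions are i.i.d. uniform, strands equiprobable, substitution
#' errors i.i.d. per base. Each read's truth label is the planted family
#' covering at least half of its span; reads touching a family for less
#' than half their span are labelled `"junction"`, all others
#' `"background"`.
#'
#' @param sim A `sim_genomes` object.
#' @param n_reads Reads per species (default from the config).
#' @param read_len Read length (default from the config).
#' @param error_rate Per-base substitution probability (default from the
#'   config).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return List with `reads` (a [read_set()]) and `truth` (data frame:
#'   read_id, species, start, strand, family, class_label).
#' @export
sample_reads <- function(sim, n_reads = NULL, read_len = NULL,
                         error_rate = NULL, seed = NULL) {
  stopifnot(inherits(sim, "sim_genomes"))
  cfg <- sim$config
  if (is.null(n_reads)) n_reads <- cfg$n_reads
  if (is.null(read_len)) read_len <- cfg$read_len
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  if (n_reads <= 0L) stop("n_reads must be positive")
  if (!is.null(seed)) set.seed(seed)

  class_of <- setNames(
    vapply(cfg$families, function(f) f$class_label, character(1)),
    vapply(cfg$families, function(f) f$family_id, character(1)))

  all_seqs <- character(0)
  truth <- list()
  for (sp in names(sim$genomes)) {
    g <- as.character(sim$genomes[[sp]])
    G <- nchar(g)
    if (G < read_len) stop("genome of ", sp, " shorter than read_len")
    starts <- sample.int(G - read_len + 1L, n_reads, replace = TRUE)
    rev <- runif(n_reads) < 0.5
    seqs <- substring(g, starts, starts + read_len - 1L)
    if (any(rev)) {
      seqs[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev])))
    }
    if (error_rate > 0) {
      flat <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
      idx <- which(runif(length(flat)) < error_rate)
      if (length(idx)) {
        cur <- match(flat[idx], BASES)
        flat[idx] <- BASES[((cur - 1L + sample.int(3L, length(idx),
                                                   replace = TRUE)) %% 4L) + 1L]
        big <- paste(flat, collapse = "")
        seqs <- substring(big, (seq_len(n_reads) - 1L) * read_len + 1L,
                          seq_len(n_reads) * read_len)
      }
    }
    # truth labels from planted-copy overlap
    fam <- rep("background", n_reads)
    ctab <- sim$copies
    ctab <- ctab[ctab$species == sp, , drop = FALSE]
    if (nrow(ctab)) {
      q <- IRanges::IRanges(starts, width = read_len)
      s <- IRanges::IRanges(ctab$start, ctab$end)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]))
        best <- tapply(seq_along(w), S4Vectors::queryHits(ov),
                       function(i) i[which.max(w[i])])
        bi <- unlist(best)
        qh <- S4Vectors::queryHits(ov)[bi]
        fam[qh] <- ifelse(w[bi] >= read_len / 2,
                          ctab$family[S4Vectors::subjectHits(ov)[bi]],
                          "junction")
      }
    }
    ids <- paste0(sp, "_r", seq_len(n_reads))
    names(seqs) <- ids
    all_seqs <- c(all_seqs, seqs)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = ids, species = sp, start = starts,
      strand = ifelse(rev, "-", "+"), family = fam,
      class_label = ifelse(fam %in% names(class_of),
                           unname(class_of[fam]), fam),
      stringsAsFactors = FALSE)
  }
  rs <- read_set(Biostrings::DNAStringSet(all_seqs),
                 rep(names(sim$genomes), each = n_reads))
  list(reads = rs, truth = do.call(rbind, truth))
}

#' Run a full simulation (genomes + reads) from a config
#'
#' @param config A [sim_config()]; its `seed` fixes all randomness.
#' @return List with `sim` (`sim_genomes`), `reads` (a [read_set()]) and
#'   `truth` (per-read truth table).
#' @export
simulate_dataset <- function(config) {
  sim <- evolve_genomes(config)   # seeds the RNG from config$seed
  rd <- sample_reads(sim)         # continues the seeded stream
  list(sim = sim, reads = rd$reads, truth = rd$truth)
}

#' Default six-species simulation configuration
#'
#' Desk-scale surrogate for a six-genome comparative repeat survey:
#' two sister-species pairs, a third close relative and a divergent
#' outgroup; twelve planted families spanning dispersed LTR-element-like
#' repeats, tandem satellites and an rDNA-like tandem (amplified in one
#' species), with shared, group-specific and species-specific
#' distributions. Genome sizes land at 1.2-1.5 Mbp; 5,000 reads of
#' 200 nt per species at a 0.5% substitution error rate.
#'
#' @param n_reads Reads per species.
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n_reads = 5000L, seed = 1L) {
  tree <- paste0("(((MACU:0.008,MORN:0.008):0.005,MBAL:0.012):0.006,",
                 "(MBEC:0.010,MTEX:0.010):0.008,EGIL:0.020);")
  cp <- function(MACU = 0, MORN = 0, MBAL = 0, MBEC = 0, MTEX = 0, EGIL = 0) {
    c(MACU = MACU, MORN = MORN, MBAL = MBAL, MBEC = MBEC, MTEX = MTEX,
      EGIL = EGIL)
  }
  fams <- list(
    family_spec("MAXIMUS", "dispersed_element", 1200,
                cp(60, 60, 55, 44, 44, 30), 0.01,
                "Ty1/copia:Maximus-SIRE", ltr_len = 150),
    family_spec("ANGELA", "dispersed_element", 900,
                cp(45, 45, 36, 32, 32, 24), 0.01,
                "Ty1/copia:Angela", ltr_len = 120),
    family_spec("REINA", "dispersed_element", 700,
                cp(40, 40, 32, 32, 32, 20), 0.01,
                "Ty3/gypsy:chromovirus:Reina", ltr_len = 100),
    family_spec("CRM", "dispersed_element", 1000,
                cp(40, 40, 35, 32, 32, 22), 0.01,
                "Ty3/gypsy:chromovirus:CRM", ltr_len = 120,
                orf = c(301L, 100L)),
    family_spec("RDNA", "rdna_like", 1500,
                cp(20, 20, 20, 60, 15, 20), 0.01, "rDNA:45S"),
    family_spec("SAT_MUSA", "tandem_satellite", 45,
                cp(700, 700, 500, 0, 0, 0), 0.02, "satellite:SatMusa"),
    family_spec("SAT_BECC", "tandem_satellite", 60,
                cp(0, 0, 0, 1200, 0, 0), 0.02, "satellite:SatBecc"),
    family_spec("SAT_BT", "tandem_satellite", 50,
                cp(0, 0, 0, 500, 500, 0), 0.02, "satellite:SatBT"),
    family_spec("EGIL_REINA", "dispersed_element", 700,
                cp(EGIL = 90), 0.01,
                "Ty3/gypsy:chromovirus:Reina", ltr_len = 100),
    family_spec("LINE", "dispersed_element", 900,
                cp(20, 20, 18, 15, 15, 12), 0.01, "LINE"),
    family_spec("AO_LTR", "dispersed_element", 600,
                cp(70, 70, 0, 0, 0, 0), 0.01, "Ty1/copia:Tork"),
    family_spec("DNAT", "dispersed_element", 400,
                cp(25, 25, 20, 20, 20, 15), 0.01, "DNA transposon"))
  sim_config(tree = tree,
             background_bp = setNames(rep(1e6, 6),
                                      c("MACU", "MORN", "MBAL", "MBEC",
                                        "MTEX", "EGIL")),
             families = fams, read_len = 200L, n_reads = n_reads,
             error_rate = 0.005, seed = seed)
}

#' Single-species configuration for copy-number calibration
#'
#' One genome with four dispersed families at 50, 150, 500 and 2,000
#' copies (unit lengths 1,000/800/700/600 nt) in a 3 Mbp genome, sampled
#' at 3,000 reads: the study design for validating hit-count based
#' copy-number estimation and low/medium/high classing.
#'
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
classing_sim_config <- function(seed = 1L) {
  fams <- list(
    family_spec("K50", "dispersed_element", 1000, c(SPEC = 50), 0.01,
                "LINE"),
    family_spec("K150", "dispersed_element", 800, c(SPEC = 150), 0.01,
                "Ty1/copia:Tork"),
    family_spec("K500", "dispersed_element", 700, c(SPEC = 500), 0.01,
                "Ty1/copia:Angela"),
    family_spec("K2000", "dispersed_element", 600, c(SPEC = 2000), 0.01,
                "Ty1/copia:Maximus-SIRE"))
  sim_config(tree = NULL, background_bp = c(SPEC = 1280000),
             families = fams, read_len = 200L, n_reads = 3000L,
             error_rate = 0.005, seed = seed)
}

#' Two-genome configuration for assembly-track validation
#'
#' Mirrors the real use of read databases: reads sampled from one genome
#' annotate a different assembled sequence carrying the same repeat
#' families. The read-source genome `SPECA` (~150 kbp) holds many copies
#' of two dispersed elements (2 kbp and 1.8 kbp units), so its 4,000
#' reads give deep per-family databases; the assembly genome `SPECB`
#' (~65 kbp, undiverged) carries a single copy of each — every family
#' appears once, so its whole read database converges on that one
#' region and coverage is dense and uniform; `SPECB`'s planted
#' coordinates are the truth. Because the two backgrounds are
#' independent, read footprints cannot extend past family boundaries;
#' insertions are spaced at least 1 kbp apart so distinct planted
#' features stay resolvable by the interval caller's merge rule.
#'
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
tracks_sim_config <- function(seed = 1L) {
  fams <- list(
    family_spec("TRK_A", "dispersed_element", 2000,
                c(SPECA = 8, SPECB = 1), 0.01,
                "Ty1/copia:Angela", ltr_len = 150),
    family_spec("TRK_B", "dispersed_element", 1800,
                c(SPECA = 9, SPECB = 1), 0.01,
                "Ty3/gypsy:chromovirus:Reina", ltr_len = 120))
  sim_config(tree = "(SPECA:0.0,SPECB:0.0);",
             background_bp = c(SPECA = 120000, SPECB = 60000),
             families = fams, read_len = 200L, n_reads = 4000L,
             error_rate = 0.005, min_gap = 1000L, seed = seed)
}
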