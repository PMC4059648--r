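#' Read a FASTA file of DNA sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that validates
#' records: empty sequences and duplicate identifiers are parse errors
#' (reported with the record index). Headers are truncated at the first
#' whitespace. An empty file yields an empty `DNAStringSet`.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (length(x)) {
    empt <- which(Biostrings::width(x) == 0L)
    if (length(empt)) {
      stop("empty sequence at record ", empt[1L], " ('", names(x)[empt[1L]],
           "') in ", path)
    }
    dup <- which(duplicated(names(x)))
    if (length(dup)) {
      stop("duplicate sequence id at record ", dup[1L], " ('",
           names(x)[dup[1L]], "') in ", path)
    }
  }
  x
}

#' Write DNA sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("all sequences must be named to be written as FASTA")
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' Plain TSV with a header line, no quoting, no row names; the on-disk
#' format used for hit tables, cluster tables and reports.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write genomic intervals as GFF3 or BED
#'
#' Intervals are held internally as 1-based closed coordinates (the
#' IRanges convention). `write_gff3()` emits them unchanged (GFF3 is
#' 1-based inclusive); `write_bed()` converts to BED's 0-based half-open
#' convention, so an interval covering the first ten bases is
#' `start=1,end=10` in GFF3 and `0,10` in BED.
#'
#' @param x A data frame with columns `seqid`, `start`, `end` (1-based
#'   closed) and optionally `label` (feature type / name), `score`,
#'   `strand`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path, source = "repeatscape") {
  stopifnot(all(c("seqid", "start", "end") %in% names(x)))
  n <- nrow(x)
  lab <- if ("label" %in% names(x)) x$label else rep("region", n)
  sc <- if ("score" %in% names(x)) x$score else rep(".", n)
  st <- if ("strand" %in% names(x)) x$strand else rep(".", n)
  lines <- c("##gff-version 3",
             if (n) paste(x$seqid, source, lab, x$start, x$end, sc, st, ".",
                          paste0("ID=", seq_len(n), ";Name=", lab),
                          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("seqid", "start", "end") %in% names(x)))
  n <- nrow(x)
  lab <- if ("label" %in% names(x)) x$label else rep(".", n)
  sc <- if ("score" %in% names(x)) x$score else rep(0, n)
  st <- if ("strand" %in% names(x)) x$strand else rep(".", n)
  df <- data.frame(x$seqid, x$start - 1L, x$end, lab, sc, st)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GFF3/BED interval files back into the internal convention
#'
#' @param path File path.
#' @return Data frame with `seqid`, `start`, `end` (1-based closed),
#'   `label`, `strand`.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), label = character(),
                      strand = character()))
  }
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  data.frame(seqid = f[, 1], start = as.integer(f[, 4]),
             end = as.integer(f[, 5]), label = f[, 3], strand = f[, 7],
             stringsAsFactors = FALSE)
}

#' @rdname read_gff3
#' @export
read_bed <- function(path) {
  f <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(seqid = f[, 1], start = f[, 2] + 1L, end = f[, 3],
             label = if (ncol(f) >= 4) f[, 4] else ".",
             strand = if (ncol(f) >= 6) f[, 6] else ".",
             stringsAsFactors = FALSE)
}

#' Write/read a phylogenetic tree in newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

# ---- read sets -------------------------------------------------------------

#' Construct a read set
#'
#' A read set is the prepared, species-tagged collection of fixed-length
#' reads on which all downstream comparison and clustering operates.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or character vector) of
#'   reads, all of identical length.
#' @param species Character vector of species codes, one per read.
#' @return An object of class `read_set`: a list with elements `seqs`
#'   (DNAStringSet), `species` (character), `read_len`.
#' @export
read_set <- function(seqs, species) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) != length(species)) {
    stop("'seqs' and 'species' lengths differ")
  }
  w <- unique(Biostrings::width(seqs))
  if (length(w) > 1L) {
    stop("reads have mixed lengths (", paste(w, collapse = ", "),
         "); run prepare_reads() first")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate read ids in read set")
  structure(list(seqs = seqs, species = as.character(species),
                 read_len = if (length(w)) w else 0L),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$seqs), "reads of", x$read_len, "nt\n")
  print(table(x$species))
  invisible(x)
}

#' Per-species read counts of a read set
#' @param rs A `read_set`.
#' @return Named integer vector.
#' @export
per_species_counts <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  tab <- table(rs$species)
  setNames(as.integer(tab), names(tab))
}

#' Prepare raw reads for analysis
#'
#' Trims every read to its first `read_len` bases and draws an equal-sized
#' seeded random sample from each species, so that read and hit counts are
#' directly comparable across species. Reads shorter than `read_len` and
#' reads whose trimmed prefix contains more than `max_n_frac` ambiguous
#' bases are excluded from the sampling pool. Output read ids are
#' `<species_code>_<serial>` in sampled order.
#'
#' @param raw Named list: one element per species (names are species
#'   codes), each a `DNAStringSet` or character vector of raw reads.
#' @param read_len Target read length in nt (default 200).
#' @param n_per_species Reads to sample per species; default is the
#'   largest equal count the pools allow.
#' @param seed Integer seed for the sampling (optional; sampling uses the
#'   current RNG state when `NULL`).
#' @param max_n_frac Maximum tolerated fraction of `N` in a trimmed read.
#' @return A [read_set()].
#' @export
prepare_reads <- function(raw, read_len = 200L, n_per_species = NULL,
                          seed = NULL, max_n_frac = 0.05) {
  if (is.null(names(raw)) || any(names(raw) == "")) {
    stop("'raw' must be a named list: names are species codes")
  }
  pools <- lapply(raw, function(x) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    x <- x[Biostrings::width(x) >= read_len]
    x <- Biostrings::subseq(x, 1L, read_len)
    nfrac <- Biostrings::letterFrequency(x, "N", as.prob = TRUE)[, 1]
    x[nfrac <= max_n_frac]
  })
  avail <- vapply(pools, length, integer(1))
  if (is.null(n_per_species)) n_per_species <- min(avail)
  short <- names(pools)[avail < n_per_species]
  if (length(short)) {
    stop("species ", paste(short, collapse = ", "), " supply only ",
         paste(avail[short], collapse = ", "), " usable reads (",
         n_per_species, " requested)")
  }
  if (n_per_species < 1L) stop("n_per_species must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(pools))
  for (i in seq_along(pools)) {
    idx <- sort(sample.int(avail[i], n_per_species))
    out[[i]] <- pools[[i]][idx]
  }
  seqs <- do.call(c, out)
  species <- rep(names(pools), each = n_per_species)
  names(seqs) <- paste0(species, "_", sequence(rep(n_per_species,
                                                   length(pools))))
  read_set(seqs, species)
}

#' Reference table of the six study genomes
#'
#' Species codes and haploid genome sizes (Mb) of the five *Musa* and one
#' *Ensete* species used as the worked example throughout the package:
#' the inputs of the coverage arithmetic.
#'
#' @return Data frame with columns `species`, `code`, `genome_mb`.
#' @export
musaceae_species <- function() {
  data.frame(
    species = c("M. acuminata", "M. ornata", "M. balbisiana",
                "M. beccarii", "M. textilis", "E. gilletii"),
    code = c("MACU", "MORN", "MBAL", "MBEC", "MTEX", "EGIL"),
    genome_mb = c(599, 635, 567, 763, 701, 591),
    stringsAsFactors = FALSE)
}
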