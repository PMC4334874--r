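# Genome assemblies, composition statistics, and the plain-text formats
# (PHYLIP square distance matrix, partition TSV) shared by all modules.

IUPAC_DNA <- "ACGTNRYSWKMBDHV"

#' Construct a genome record
#'
#' A genome record holds one strain's assembly: an ordered set of replicons
#' (chromosome plus optional plasmids or contigs) as uppercase DNA strings.
#'
#' @param strain_id Label for the strain (unique within a genome set).
#' @param replicons Named character vector of DNA sequences. Lowercase is
#'   uppercased and U is mapped to T; any letter outside the IUPAC nucleotide
#'   alphabet is an error naming the offending replicon.
#' @return An object of class \code{genome_record} with fields
#'   \code{strain_id}, \code{replicons}, \code{total_length} and
#'   \code{gc_fraction} (G+C over unambiguous bases).
#' @export
genome_record <- function(strain_id, replicons) {
  if (length(replicons) < 1) stopf("genome '%s' has no replicons", strain_id)
  if (is.null(names(replicons)))
    names(replicons) <- paste0("replicon_", seq_along(replicons))
  nm <- names(replicons)
  replicons <- setNames(chartr("U", "T", toupper(replicons)), nm)
  bad <- grepl(sprintf("[^%s]", IUPAC_DNA), replicons)
  if (any(bad))
    stopf("replicon '%s' of genome '%s' contains non-nucleotide symbols",
          names(replicons)[which(bad)[1]], strain_id)
  rec <- structure(
    list(strain_id = strain_id, replicons = replicons,
         total_length = sum(nchar(replicons)), gc_fraction = NA_real_),
    class = "genome_record")
  rec$gc_fraction <- gc_fraction(rec)
  rec
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d replicon(s), %s bp, G+C %.1f%%\n",
              x$strain_id, length(x$replicons),
              format(x$total_length, big.mark = ","),
              100 * x$gc_fraction))
  invisible(x)
}

#' Read a genome assembly from a multi-FASTA file
#'
#' @param path Path to a FASTA file with at least one record. Records are
#'   kept in file order; wrapped sequence lines and blank lines are handled;
#'   lowercase (masked) sequence is uppercased.
#' @param strain_id Strain label; defaults to the file name without
#'   extension.
#' @return A \code{\link{genome_record}}.
#' @export
read_genome_fasta <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("not readable as FASTA: %s", path))
  if (length(set) == 0) stopf("FASTA file '%s' contains no records", path)
  if (is.null(strain_id))
    strain_id <- sub("\\.(fa|fna|fasta)$", "", basename(path))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  genome_record(strain_id, seqs)
}

#' Write a genome record to FASTA
#'
#' @param record A \code{\link{genome_record}}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_genome_fasta <- function(record, path, width = 70) {
  set <- Biostrings::DNAStringSet(record$replicons)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' G+C fraction of a genome
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous IUPAC symbols and N are
#' excluded from both numerator and denominator so unknown bases do not bias
#' the composition estimate.
#'
#' @param record A \code{\link{genome_record}}, or a character vector of DNA
#'   sequences.
#' @return Fraction in \code{[0, 1]}.
#' @export
gc_fraction <- function(record) {
  seqs <- if (inherits(record, "genome_record")) record$replicons
          else toupper(record)
  x <- Biostrings::BStringSet(seqs)
  counts <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  num <- sum(counts[, c("C", "G")])
  den <- sum(counts)
  if (den == 0)
    stopf("undefined composition: sequence contains no unambiguous A/C/G/T")
  num / den
}

#' Absolute G+C difference between two genomes, in percentage points
#'
#' @param a,b \code{\link{genome_record}} objects (or sequences accepted by
#'   \code{\link{gc_fraction}}).
#' @return Non-negative difference in percentage points.
#' @export
gc_difference <- function(a, b) {
  abs(gc_fraction(a) - gc_fraction(b)) * 100
}

# ---- distance matrix container ---------------------------------------------

#' Validate and label a square distance matrix
#'
#' @param values Square numeric matrix of intergenomic distances in
#'   \code{[0, 1]}.
#' @param labels Strain labels (defaults to existing dimnames).
#' @return The matrix with dimnames set, after symmetry/diagonal checks.
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("distance matrix must be square")
  if (is.null(labels)) stopf("distance matrix needs strain labels")
  if (anyDuplicated(labels)) stopf("duplicate strain ids in distance matrix")
  dimnames(values) <- list(labels, labels)
  if (any(values < 0 | values > 1)) stopf("distances must lie in [0, 1]")
  if (any(abs(diag(values)) > 1e-12)) stopf("diagonal must be zero")
  if (!isSymmetric(unname(values), tol = 1e-9))
    stopf("distance matrix must be symmetric")
  values
}

#' Read a PHYLIP square distance matrix
#'
#' Relaxed PHYLIP: first line the number of taxa, then one row per taxon of
#' \code{label <TAB> d1 <TAB> d2 ...} (any whitespace accepted on input).
#'
#' @param path Input path.
#' @return A labeled symmetric matrix (see \code{\link{dist_matrix}}).
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1)
    stopf("malformed PHYLIP matrix: %s", path)
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
    if (length(parts) != n + 1)
      stopf("PHYLIP row %d has %d fields, expected %d", i, length(parts), n + 1)
    labs[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  dist_matrix(m, labs)
}

#' Write a PHYLIP square distance matrix
#'
#' @param m Labeled symmetric matrix.
#' @param path Output path.
#' @param digits Significant digits written.
#' @export
write_phylip_dist <- function(m, path, digits = 9) {
  m <- dist_matrix(m)
  labs <- rownames(m)
  if (any(nchar(labs) > 64)) stopf("labels longer than 64 characters")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(labs[i], formatC(m[i, ], digits = digits, format = "g")),
          collapse = "\t"), character(1))
  writeLines(c(sprintf("%d", nrow(m)), rows), path)
  invisible(path)
}

# ---- partitions -------------------------------------------------------------

#' Construct a partition (strain to cluster assignment)
#'
#' @param assignment Named vector (names = strain ids) of cluster labels;
#'   any labels are accepted and recoded to contiguous integer indices
#'   starting at 1, in order of first appearance of the sorted strain ids.
#' @param T,F Optional provenance: the distance threshold and linkage
#'   fraction that produced the partition.
#' @return Named integer vector of class \code{partition} with attribute
#'   \code{params = c(T, F)}.
#' @export
partition <- function(assignment, T = NA_real_, F = NA_real_) {
  if (is.null(names(assignment))) stopf("assignment must be named by strain")
  assignment <- assignment[order(names(assignment))]
  idx <- match(assignment, unique(assignment))
  structure(setNames(as.integer(idx), names(assignment)),
            params = c(T = unname(T), F = unname(F)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d strains in %d clusters (T=%s, F=%s)\n",
              length(x), length(unique(x)),
              format(attr(x, "params")[["T"]]),
              format(attr(x, "params")[["F"]])))
  invisible(x)
}

#' Read a partition from TSV (strain_id <TAB> group)
#' @param path Input path.
#' @return A \code{\link{partition}}.
#' @export
read_partition <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("strain_id", "group"),
                   colClasses = "character")
  partition(setNames(df$group, df$strain_id))
}

#' Write a partition to TSV (strain_id <TAB> group)
#' @param p A \code{\link{partition}}.
#' @param path Output path.
#' @export
write_partition <- function(p, path) {
  df <- data.frame(strain_id = names(p), group = as.integer(p))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
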