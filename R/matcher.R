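# High-scoring segment pairs (HSPs) between two genomes: a deterministic
# k-mer seeded, ungapped, X-drop extended matcher plus the greedy-with-
# trimming overlap resolution that all GBDP distance formulas rely on.
#
# HSPs are ungapped, so trimming is coordinate slicing; each HSP carries its
# mismatch offsets so identities are recounted exactly on any slice.

#' Matcher parameters
#'
#' @param k Seed word size (exact match).
#' @param match,mismatch Per-base alignment scores.
#' @param xdrop Extension stops once the running score falls this far below
#'   the best score seen (ungapped X-drop).
#' @param min_length Minimum HSP (or trimmed slice) length kept, in bases.
#' @param min_identity Minimum fraction of identical positions in a kept HSP.
#' @return A list of class \code{match_params}.
#' @export
match_params <- function(k = 11L, match = 1L, mismatch = -2L, xdrop = 20L,
                         min_length = 100L, min_identity = 0.70) {
  stopifnot(k >= 4, k <= 31, match > 0, mismatch < 0, xdrop > 0,
            min_length >= 1, min_identity >= 0, min_identity <= 1)
  structure(list(k = as.integer(k), match = as.integer(match),
                 mismatch = as.integer(mismatch), xdrop = as.integer(xdrop),
                 min_length = as.integer(min_length),
                 min_identity = min_identity),
            class = "match_params")
}

# Concatenate replicons with a spacer of 2k N's so no seed or extension can
# bridge a replicon join (N scores as a mismatch and is barred from seeds).
concat_genome <- function(record, k) {
  paste(record$replicons, collapse = strrep("N", 2L * k))
}

new_hsp_set <- function(pair, len_a, len_b, concat_len_a, concat_len_b,
                        hsps, mismatch_offsets, params, trimmed = FALSE) {
  structure(list(pair = pair, len_a = len_a, len_b = len_b,
                 concat_len_a = concat_len_a, concat_len_b = concat_len_b,
                 hsps = hsps, mismatch_offsets = mismatch_offsets,
                 params = params, trimmed = trimmed),
            class = "hsp_set")
}

#' @export
print.hsp_set <- function(x, ...) {
  cat(sprintf("<hsp_set> %s vs %s: %d HSPs (%s), %s aligned bases\n",
              x$pair[1], x$pair[2], nrow(x$hsps),
              if (x$trimmed) "trimmed" else "raw",
              format(sum(x$hsps$length), big.mark = ",")))
  invisible(x)
}

sort_hsps <- function(set) {
  h <- set$hsps
  o <- order(-h$score, -h$length, h$a_start, h$b_start)
  set$hsps <- h[o, , drop = FALSE]
  rownames(set$hsps) <- NULL
  set$mismatch_offsets <- set$mismatch_offsets[o]
  set
}

#' Find high-scoring local matches between two genomes
#'
#' Deterministic ungapped matcher: exact k-mer seeds on both strands,
#' per-diagonal seed deduplication, X-drop extension, then filtering by
#' minimum length and identity. Multi-replicon genomes are concatenated with
#' a 2k-base N spacer; coordinates refer to the concatenated sequence, with
#' reverse-strand matches reported in forward coordinates plus a strand flag.
#'
#' @param a,b \code{\link{genome_record}} objects.
#' @param params \code{\link{match_params}}.
#' @return An \code{hsp_set}: pair labels, genome lengths, a data frame of
#'   HSPs (\code{a_start}, \code{a_end}, \code{b_start}, \code{b_end}
#'   0-based half-open, \code{strand}, \code{length}, \code{identities},
#'   \code{score}) sorted by score (ties: longer, then smaller
#'   \code{a_start}, then \code{b_start}), and per-HSP mismatch offsets.
#' @export
find_hsps <- function(a, b, params = match_params()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  ca <- concat_genome(a, params$k)
  cb <- concat_genome(b, params$k)
  if (params$k > min(nchar(a$replicons)) && params$k > min(nchar(b$replicons)))
    warning("seed size k exceeds replicon lengths; no matches possible")
  raw <- .match_pair_cpp(ca, cb, params$k, params$match, params$mismatch,
                         params$xdrop)
  keep <- raw$length >= params$min_length &
    raw$identities >= params$min_identity * raw$length
  hsps <- data.frame(a_start = raw$a_start[keep], a_end = raw$a_end[keep],
                     b_start = raw$b_start[keep], b_end = raw$b_end[keep],
                     strand = raw$strand[keep], length = raw$length[keep],
                     identities = raw$identities[keep],
                     score = raw$score[keep])
  sort_hsps(new_hsp_set(
    pair = c(a$strain_id, b$strain_id),
    len_a = a$total_length, len_b = b$total_length,
    concat_len_a = nchar(ca), concat_len_b = nchar(cb),
    hsps = hsps, mismatch_offsets = raw$mismatch_offsets[keep],
    params = params))
}

# forward-strand B positions of HSP offsets 0..len-1
hsp_b_positions <- function(h, offs) {
  if (h$strand == "+") h$b_start + offs else h$b_end - 1L - offs
}

#' Resolve HSP overlaps by greedy-with-trimming
#'
#' HSPs are visited in decreasing score order (ties: longer first, then
#' smaller \code{a_start}, then smaller \code{b_start}). The first is
#' accepted; each later HSP has every sub-span removed that overlaps the
#' accepted footprint on either genome. Because HSPs are ungapped, trimming
#' is coordinate slicing with identities recounted on the slice (from the
#' stored mismatch offsets). Remaining slices shorter than
#' \code{min_length} are discarded. The accepted set is footprint-disjoint
#' on both genomes.
#'
#' @param set An \code{hsp_set} from \code{\link{find_hsps}} or
#'   \code{\link{read_blast_tab}}.
#' @param min_length Minimum kept slice length; defaults to the matcher
#'   parameter stored in the set.
#' @return A trimmed \code{hsp_set}.
#' @export
greedy_with_trimming <- function(set, min_length = NULL) {
  stopifnot(inherits(set, "hsp_set"))
  min_length <- as.integer(min_length %||% set$params$min_length)
  set <- sort_hsps(set)
  h <- set$hsps
  cov_a <- logical(set$concat_len_a)
  cov_b <- logical(set$concat_len_b)
  out <- vector("list", nrow(h))
  out_mism <- list()
  n_out <- 0L
  for (i in seq_len(nrow(h))) {
    hi <- h[i, ]
    offs <- 0:(hi$length - 1L)
    apos <- hi$a_start + offs
    bpos <- hsp_b_positions(hi, offs)
    keep <- !cov_a[apos + 1L] & !cov_b[bpos + 1L]
    if (!any(keep)) next
    mism <- set$mismatch_offsets[[i]]
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      o1 <- offs[starts[r]]; o2 <- offs[ends[r]]
      sublen <- o2 - o1 + 1L
      if (sublen < min_length) next
      if (is.null(mism)) { # imported HSPs without offsets: proportional
        ident <- as.integer(round(sublen * hi$identities / hi$length))
        sub_mism <- NULL
      } else {
        sub_mism <- mism[mism >= o1 & mism <= o2] - o1
        ident <- sublen - length(sub_mism)
      }
      bpos_run <- hsp_b_positions(hi, c(o1, o2))
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        a_start = hi$a_start + o1, a_end = hi$a_start + o2 + 1L,
        b_start = min(bpos_run), b_end = max(bpos_run) + 1L,
        strand = hi$strand, length = sublen, identities = ident,
        score = ident * set$params$match +
          (sublen - ident) * set$params$mismatch)
      out_mism[n_out] <- if (is.null(mism)) list(NULL)
                         else list(as.integer(sub_mism))
      cov_a[(hi$a_start + o1):(hi$a_start + o2) + 1L] <- TRUE
      cov_b[min(bpos_run):max(bpos_run) + 1L] <- TRUE
    }
  }
  hsps <- if (n_out > 0) do.call(rbind, out[seq_len(n_out)]) else h[0, ]
  set2 <- new_hsp_set(set$pair, set$len_a, set$len_b,
                      set$concat_len_a, set$concat_len_b,
                      hsps, out_mism[seq_len(n_out)], set$params,
                      trimmed = TRUE)
  sort_hsps(set2)
}

#' Import HSPs from BLAST tabular output (outfmt 6)
#'
#' Reads \code{qstart qend sstart send length nident bitscore} columns
#' (1-based inclusive BLAST coordinates are converted to 0-based half-open;
#' subject coordinates with \code{sstart > send} mark the minus strand).
#' Imported HSPs carry no mismatch offsets, so trimming recounts identities
#' proportionally on slices.
#'
#' @param path Tabular BLAST file with columns qstart, qend, sstart, send,
#'   length, nident, bitscore.
#' @param pair Character vector \code{c(query_id, subject_id)}.
#' @param len_a,len_b Genome lengths of query and subject.
#' @param params \code{\link{match_params}} used downstream.
#' @return A raw \code{hsp_set}.
#' @export
read_blast_tab <- function(path, pair, len_a, len_b,
                           params = match_params()) {
  df <- read.table(path, sep = "\t", header = FALSE)
  if (ncol(df) < 7) stopf("expected >= 7 tabular columns in %s", path)
  df <- df[, 1:7]
  names(df) <- c("qstart", "qend", "sstart", "send", "length", "nident",
                 "bitscore")
  minus <- df$sstart > df$send
  hsps <- data.frame(
    a_start = pmin(df$qstart, df$qend) - 1L,
    a_end = pmax(df$qstart, df$qend),
    b_start = pmin(df$sstart, df$send) - 1L,
    b_end = pmax(df$sstart, df$send),
    strand = ifelse(minus, "-", "+"),
    length = df$length, identities = df$nident,
    score = as.integer(round(df$bitscore)))
  sort_hsps(new_hsp_set(pair, len_a, len_b, len_a, len_b, hsps,
                        rep(list(NULL), nrow(hsps)), params))
}

#' Write an HSP set to TSV
#' @param set An \code{hsp_set}.
#' @param path Output path.
#' @export
write_hsps_tsv <- function(set, path) {
  write.table(set$hsps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
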