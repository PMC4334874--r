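# GBDP intergenomic distances: three formulas over a trimmed HSP set, full
# pairwise matrices with cached HSP sets, and pseudo-bootstrap replicate
# matrices obtained by resampling HSPs.

GBDP_FORMULAS <- c("coverage", "f2", "total")

normalize_formula <- function(formula) {
  formula <- switch(formula,
                    identities_per_hsp = "f2",
                    identities_per_total = "total",
                    formula)
  match.arg(formula, GBDP_FORMULAS)
}

#' GBDP distance from a trimmed HSP set
#'
#' With H the summed HSP lengths, I the summed identities and
#' L = len_a + len_b:
#' \describe{
#'   \item{coverage}{d = 1 - 2H/L (how much of the genomes aligns)}
#'   \item{f2 (identities per HSP length)}{d = 1 - I/H, the recommended
#'     formula for incomplete genomes; d = 1 with a warning if H = 0}
#'   \item{total (identities per total length)}{d = 1 - 2I/L}
#' }
#' Results are clamped to \code{[0, 1]}.
#'
#' @param set A trimmed (footprint-disjoint) \code{hsp_set}; untrimmed input
#'   is an error.
#' @param formula One of \code{"coverage"}, \code{"f2"}
#'   (alias \code{"identities_per_hsp"}), \code{"total"}
#'   (alias \code{"identities_per_total"}).
#' @return Distance in \code{[0, 1]}.
#' @export
gbdp_distance <- function(set, formula = "f2") {
  stopifnot(inherits(set, "hsp_set"))
  if (!isTRUE(set$trimmed))
    stopf("gbdp_distance requires a trimmed HSP set (greedy_with_trimming)")
  formula <- normalize_formula(formula)
  H <- sum(set$hsps$length)
  I <- sum(set$hsps$identities)
  L <- set$len_a + set$len_b
  d <- switch(formula,
    coverage = 1 - 2 * H / L,
    f2 = if (H == 0) {
      warning("no HSPs between ", set$pair[1], " and ", set$pair[2],
              "; distance set to 1")
      1
    } else 1 - I / H,
    total = 1 - 2 * I / L)
  min(max(d, 0), 1)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\t")

#' Pairwise GBDP distance matrix for a genome set
#'
#' Computes the trimmed HSP set once per unordered pair and derives the
#' symmetric distance matrix; the per-pair HSP sets are cached in the result
#' for pseudo-bootstrapping.
#'
#' @param genomes List of \code{\link{genome_record}} objects with unique
#'   strain ids.
#' @param formula See \code{\link{gbdp_distance}}.
#' @param params \code{\link{match_params}} for the matcher.
#' @return An object of class \code{gbdp_matrix}: \code{$distances} (labeled
#'   symmetric matrix), \code{$hsps} (cache keyed by unordered pair),
#'   \code{$formula}, \code{$params}.
#' @export
gbdp_pairwise <- function(genomes, formula = "f2", params = match_params()) {
  formula <- normalize_formula(formula)
  ids <- vapply(genomes, function(g) g$strain_id, character(1))
  if (length(ids) < 2) stopf("need at least two genomes")
  if (anyDuplicated(ids)) stopf("duplicate strain ids: %s",
                                ids[duplicated(ids)][1])
  names(genomes) <- ids
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  cache <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      set <- greedy_with_trimming(find_hsps(genomes[[i]], genomes[[j]],
                                            params))
      cache[[pair_key(ids[i], ids[j])]] <- set
      d <- gbdp_distance(set, formula)
      m[i, j] <- m[j, i] <- d
    }
  }
  structure(list(distances = dist_matrix(m), hsps = cache,
                 formula = formula, params = params),
            class = "gbdp_matrix")
}

#' @export
print.gbdp_matrix <- function(x, ...) {
  cat(sprintf("<gbdp_matrix> %d genomes, formula '%s'\n",
              nrow(x$distances), x$formula))
  invisible(x)
}

resample_distance <- function(set, formula) {
  n <- nrow(set$hsps)
  if (n == 0) return(1)
  idx <- sample.int(n, n, replace = TRUE)
  H <- sum(set$hsps$length[idx])
  I <- sum(set$hsps$identities[idx])
  L <- set$len_a + set$len_b
  d <- switch(formula,
              coverage = 1 - 2 * H / L,
              f2 = if (H == 0) 1 else 1 - I / H,
              total = 1 - 2 * I / L)
  min(max(d, 0), 1)
}

#' Pseudo-bootstrap replicate distance matrices
#'
#' For each replicate and each genome pair, resamples n = |HSPs| trimmed
#' HSPs with replacement and recomputes the GBDP distance. Each
#' (replicate, pair) draw uses its own RNG stream derived from
#' \code{(seed, replicate, pair)}, so results are reproducible and
#' independent of pair evaluation order. Pairs with no HSPs get replicate
#' distance 1.
#'
#' @param pw A \code{gbdp_matrix} from \code{\link{gbdp_pairwise}} (its HSP
#'   cache is used).
#' @param replicates Number of replicates (default 100).
#' @param seed Integer seed for the replicate streams.
#' @param formula Distance formula; defaults to the one in \code{pw}.
#' @return List of \code{replicates} labeled symmetric matrices.
#' @export
gbdp_bootstrap <- function(pw, replicates = 100L, seed = 1L,
                           formula = NULL) {
  stopifnot(inherits(pw, "gbdp_matrix"), replicates >= 1)
  formula <- normalize_formula(formula %||% pw$formula)
  ids <- rownames(pw$distances)
  n <- length(ids)
  lapply(seq_len(replicates), function(r) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        key <- pair_key(ids[i], ids[j])
        d <- with_seed(derive_seed(seed, "bootstrap", r, key),
                       resample_distance(pw$hsps[[key]], formula))
        m[i, j] <- m[j, i] <- d
      }
    }
    dist_matrix(m)
  })
}
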