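# Synthetic genome sets with a planted species/subspecies hierarchy.
#
# An ancestor sequence is evolved independently along a fixed hierarchy tree
# by per-branch substitutions (uniform over the three alternative bases, a
# Jukes-Cantor-like model -- the workflow estimates identity fractions, not
# model-based distances), point indels with geometric lengths, and segment
# inversions. Per-branch substitution probabilities are calibrated at run
# time from the configured dDDH model so that the planted divergence bands
# map onto the intended dDDH ranges (within subspecies above 80%, between
# subspecies of one species 72-78%, between species below 60%).

CODE_ACGT <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# per-lineage substitution probability s producing pairwise difference D
# between two leaves: D = 2 s - (4/3) s^2  (uniform model, both lineages)
pairwise_to_lineage <- function(D) (2 - sqrt(4 - (16 / 3) * D)) / (8 / 3)

#' Calibrate a planted hierarchy from dDDH band targets
#'
#' Derives per-branch substitution probabilities so that expected pairwise
#' divergences map (through \code{model}) onto dDDH band centres: between
#' subspecies of one species at \code{ddh_between_subsp} (centre of the
#' 72--78\% band), within subspecies mirror-symmetric in distance about the
#' intended subspecies boundary \code{ddh_boundary} (so the band gap is
#' centred on the boundary, which is where the plateau-midpoint rule of
#' \code{\link{optimize_subspecies_threshold}} places the selected
#' threshold), and between species at \code{ddh_between_species}, well
#' below the 70\% species line.
#'
#' @param model A \code{\link{ddh_model}}.
#' @param n_species,n_subspecies,strains_per_group Hierarchy shape.
#' @param ddh_between_subsp,ddh_between_species,ddh_boundary Band targets
#'   as dDDH fractions.
#' @return List of hierarchy levels, each \code{list(name, groups, subst)};
#'   the last level is the strain level.
#' @export
calibrate_hierarchy <- function(model = ddh_model(), n_species = 3,
                                n_subspecies = 2, strains_per_group = 4,
                                ddh_between_subsp = 0.75,
                                ddh_between_species = 0.40,
                                ddh_boundary = 0.79) {
  d_between <- ddh_to_distance(ddh_between_subsp, model)
  d_within <- 2 * ddh_to_distance(ddh_boundary, model) - d_between
  d_species <- ddh_to_distance(ddh_between_species, model)
  stopifnot(d_within > 0, d_within < d_between, d_between < d_species)
  s_st <- pairwise_to_lineage(d_within)
  s_ss <- pairwise_to_lineage(d_between)   # cumulative to subspecies level
  s_sp <- pairwise_to_lineage(d_species)   # cumulative to species level
  list(
    list(name = "species", groups = n_species,
         subst = 1 - (1 - s_sp) / (1 - s_ss)),
    list(name = "subspecies", groups = n_subspecies,
         subst = 1 - (1 - s_ss) / (1 - s_st)),
    list(name = "strain", groups = strains_per_group, subst = s_st))
}

#' Simulation configuration
#'
#' @param seed Master seed; every branch of the simulation derives its own
#'   stream from it, so output is reproducible and traversal-order
#'   independent.
#' @param ancestor_length Ancestor genome length in bp.
#' @param gc Ancestor G+C fraction (substitutions are composition-neutral
#'   in expectation at gc = 0.5).
#' @param hierarchy List of levels \code{list(name, groups, subst)}, last
#'   level = strains per terminal group; default: calibrated 3 species x 2
#'   subspecies x 4 strains (see \code{\link{calibrate_hierarchy}}).
#' @param indel_rate Per-base probability of an indel event on a branch.
#' @param indel_mean_len Mean of the geometric indel length distribution.
#' @param inversion_rate Expected number of inversions per branch.
#' @param inversion_mean_len Mean inversion segment length.
#' @param model dDDH model used for default hierarchy calibration.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, ancestor_length = 50000L, gc = 0.5,
                       hierarchy = NULL, indel_rate = 1e-4,
                       indel_mean_len = 3, inversion_rate = 0.1,
                       inversion_mean_len = 1000,
                       model = ddh_model()) {
  hierarchy <- hierarchy %||% calibrate_hierarchy(model)
  if (length(hierarchy) < 2 || hierarchy[[1]]$groups < 2)
    stopf("hierarchy needs >= 2 species-level groups and a strain level")
  stopifnot(ancestor_length > 0, gc >= 0, gc <= 1,
            indel_rate >= 0, indel_rate < 1, inversion_rate >= 0)
  structure(list(seed = as.integer(seed),
                 ancestor_length = as.integer(ancestor_length), gc = gc,
                 hierarchy = hierarchy, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 inversion_rate = inversion_rate,
                 inversion_mean_len = inversion_mean_len),
            class = "sim_config")
}

#' Evolve a DNA sequence
#'
#' Applies, in order: per-position substitutions with probability
#' \code{subst_p} (uniform over the three alternative bases), indel point
#' events with geometric lengths (insertions drawn at the configured G+C),
#' then \code{inversions} reverse-complemented random segments. Uses the
#' ambient RNG stream.
#'
#' @param seq DNA string (A/C/G/T).
#' @param subst_p Per-position substitution probability.
#' @param indel_rate Per-base indel event probability.
#' @param indel_mean_len Mean geometric indel length.
#' @param inversions Number of inversion events.
#' @param inversion_mean_len Mean inversion segment length.
#' @param gc G+C fraction for inserted bases.
#' @return Evolved sequence, with attribute \code{events} recording
#'   \code{n_substitutions}, \code{bases_inserted}, \code{bases_deleted},
#'   \code{n_inversions}.
#' @export
evolve_sequence <- function(seq, subst_p, indel_rate = 0,
                            indel_mean_len = 3, inversions = 0,
                            inversion_mean_len = 1000, gc = 0.5) {
  x <- utf8ToInt(seq)
  idx <- match(x, CODE_ACGT) # 1..4, NA for non-ACGT
  n_sub <- 0L
  if (subst_p > 0) {
    hit <- which(!is.na(idx) & runif(length(x)) < subst_p)
    n_sub <- length(hit)
    if (n_sub > 0) {
      shift <- sample.int(3L, n_sub, replace = TRUE)
      x[hit] <- CODE_ACGT[((idx[hit] - 1L + shift) %% 4L) + 1L]
    }
  }
  ins_total <- 0L; del_total <- 0L
  if (indel_rate > 0) {
    n_ev <- rbinom(1, length(x), indel_rate)
    if (n_ev > 0) {
      pos <- sort(sample.int(length(x), n_ev), decreasing = TRUE)
      is_ins <- runif(n_ev) < 0.5
      lens <- rgeom(n_ev, 1 / indel_mean_len) + 1L
      probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      for (e in seq_len(n_ev)) {
        if (is_ins[e]) {
          frag <- sample(CODE_ACGT, lens[e], replace = TRUE, prob = probs)
          x <- append(x, frag, after = pos[e])
          ins_total <- ins_total + lens[e]
        } else {
          to <- min(pos[e] + lens[e] - 1L, length(x))
          del_total <- del_total + (to - pos[e] + 1L)
          x <- x[-(pos[e]:to)]
        }
      }
    }
  }
  if (inversions > 0) {
    comp <- integer(85)
    comp[CODE_ACGT] <- CODE_ACGT[c(4, 3, 2, 1)]
    for (e in seq_len(inversions)) {
      start <- sample.int(length(x), 1)
      len <- min(rgeom(1, 1 / inversion_mean_len) + 1L, length(x) - start + 1L)
      span <- start:(start + len - 1L)
      x[span] <- rev(comp[x[span]])
    }
  }
  structure(intToUtf8(x),
            events = list(n_substitutions = n_sub,
                          bases_inserted = ins_total,
                          bases_deleted = del_total,
                          n_inversions = as.integer(inversions)))
}

# transition matrices of the uniform model have the form a*I + b*J and
# compose in closed form; used for exact expected pairwise divergences
compose_branch <- function(ab, p) {
  a2 <- 1 - 4 * p / 3; b2 <- p / 3
  c(ab[1] * a2, ab[1] * b2 + ab[2] * a2 + 4 * ab[2] * b2)
}

expected_divergence <- function(path_a, path_b) {
  shared <- 0L
  nmin <- min(length(path_a), length(path_b))
  while (shared < nmin &&
         identical(names(path_a)[shared + 1], names(path_b)[shared + 1]))
    shared <- shared + 1L
  ab_a <- c(1, 0); ab_b <- c(1, 0)
  for (p in path_a[seq_along(path_a) > shared]) ab_a <- compose_branch(ab_a, p)
  for (p in path_b[seq_along(path_b) > shared]) ab_b <- compose_branch(ab_b, p)
  1 - ((ab_a[1] + ab_a[2]) * (ab_b[1] + ab_b[2]) + 3 * ab_a[2] * ab_b[2])
}

#' Simulate a genome set with a planted species/subspecies hierarchy
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{taxon_set}: \code{$genomes} (named list of
#'   \code{\link{genome_record}}s), \code{$truth} with \code{tree}
#'   (\code{ape::phylo}, branch lengths = per-branch substitution
#'   probabilities), \code{partitions} (one \code{\link{partition}} per
#'   hierarchy level above the strain level), and
#'   \code{expected_divergence} (exact expected pairwise substitution
#'   fractions), and \code{$config}.
#' @export
simulate_taxon_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  ancestor <- with_seed(derive_seed(config$seed, "ancestor"),
                        intToUtf8(sample(CODE_ACGT, config$ancestor_length,
                                         replace = TRUE, prob = probs)))
  levels <- config$hierarchy
  short <- vapply(levels, function(l) substr(l$name, 1, 2), character(1))

  genomes <- list()
  paths <- list()
  recurse <- function(seq, level, path_names, path_probs) {
    lev <- levels[[level]]
    for (g in seq_len(lev$groups)) {
      tag <- paste0(short[level], g)
      nm <- c(path_names, tag)
      id <- paste(nm, collapse = "_")
      child <- with_seed(
        derive_seed(config$seed, "branch", id),
        evolve_sequence(seq, lev$subst, config$indel_rate,
                        config$indel_mean_len,
                        rpois(1, config$inversion_rate),
                        config$inversion_mean_len, config$gc))
      pp <- c(path_probs, setNames(lev$subst, id))
      if (level == length(levels)) {
        genomes[[id]] <<- genome_record(id, c(chromosome = as.character(child)))
        paths[[id]] <<- pp
      } else {
        recurse(as.character(child), level + 1, nm, pp)
      }
    }
  }
  recurse(ancestor, 1L, character(0), numeric(0))

  ids <- names(genomes)
  n <- length(ids)
  ediv <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ediv[i, j] <- ediv[j, i] <- expected_divergence(paths[[ids[i]]],
                                                    paths[[ids[j]]])

  # truth partitions: one per grouping level (prefix of the id)
  partitions <- list()
  for (lv in seq_len(length(levels) - 1)) {
    grp <- vapply(strsplit(ids, "_"), function(parts)
      paste(parts[seq_len(lv)], collapse = "_"), character(1))
    partitions[[levels[[lv]]$name]] <- partition(setNames(grp, ids))
  }

  newick <- build_truth_newick(levels)
  structure(list(genomes = genomes,
                 truth = list(tree = ape::read.tree(text = newick),
                              partitions = partitions,
                              expected_divergence = ediv),
                 config = config),
            class = "taxon_set")
}

build_truth_newick <- function(levels, level = 1L, prefix = character(0)) {
  short <- substr(levels[[level]]$name, 1, 2)
  subtrees <- vapply(seq_len(levels[[level]]$groups), function(g) {
    nm <- c(prefix, paste0(short, g))
    label <- paste(nm, collapse = "_")
    body <- if (level == length(levels)) label
            else build_truth_newick(levels, level + 1L, nm)
    sprintf("%s:%.8f", body, levels[[level]]$subst)
  }, character(1))
  if (level == 1L) sprintf("(%s);", paste(subtrees, collapse = ","))
  else sprintf("(%s)", paste(subtrees, collapse = ","))
}

#' Write a simulated taxon set to a directory
#'
#' Emits one FASTA per strain, the truth tree (Newick), one truth partition
#' TSV per level, and a manifest JSON.
#'
#' @param sim A \code{taxon_set} from \code{\link{simulate_taxon_set}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_taxon_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- character(0)
  for (g in sim$genomes) {
    f <- file.path(dir, paste0(g$strain_id, ".fasta"))
    write_genome_fasta(g, f)
    fasta <- c(fasta, basename(f))
  }
  ape::write.tree(sim$truth$tree, file.path(dir, "truth_tree.nwk"))
  parts <- character(0)
  for (nm in names(sim$truth$partitions)) {
    f <- file.path(dir, paste0("truth_partition_", nm, ".tsv"))
    write_partition(sim$truth$partitions[[nm]], f)
    parts <- c(parts, basename(f))
  }
  manifest <- list(seed = sim$config$seed,
                   ancestor_length = sim$config$ancestor_length,
                   strains = names(sim$genomes), fasta = fasta,
                   truth_tree = "truth_tree.nwk", truth_partitions = parts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
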