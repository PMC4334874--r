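# End-to-end pipeline: genomes (read or simulated) -> pairwise GBDP
# distances -> dDDH classification vs the type strain -> threshold
# clustering with consistency-optimized subspecies threshold -> distance
# tree with pseudo-bootstrap support -> machine-readable report bundle.

#' Pipeline configuration
#'
#' @param genomes Character vector of FASTA paths, a directory containing
#'   \code{.fasta}/\code{.fa}/\code{.fna} files, or NULL when simulating.
#' @param sim NULL, TRUE (simulate with defaults), or a named list of
#'   \code{\link{sim_config}} arguments.
#' @param formula GBDP distance formula (dDDH stages require \code{"f2"}
#'   unless \code{model_c0}/\code{model_c1} are supplied).
#' @param match Named list overriding \code{\link{match_params}} defaults.
#' @param type_id Type strain label; default: first strain.
#' @param species_thr,subsp_thr,gc_limit Classification thresholds
#'   (\code{0 < species_thr < subsp_thr < 1}).
#' @param model_c0,model_c1 Optional explicit dDDH model coefficients.
#' @param bootstrap_replicates Pseudo-bootstrap replicates (0 disables
#'   branch support).
#' @param outgroup Optional outgroup labels for rooting.
#' @param reference Optional path to a reference partition TSV; triggers
#'   clustering optimization against it.
#' @param seed Top-level seed; all stage streams derive from it.
#' @param out_dir Output directory.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genomes = NULL, sim = NULL, formula = "f2",
                            match = list(), type_id = NULL,
                            species_thr = 0.70, subsp_thr = 0.79,
                            gc_limit = 1.0, model_c0 = NULL,
                            model_c1 = NULL, bootstrap_replicates = 100L,
                            outgroup = NULL, reference = NULL, seed = 1L,
                            out_dir = "gbdtax_out") {
  stopifnot(species_thr > 0, species_thr < subsp_thr, subsp_thr < 1)
  if (is.null(genomes) && is.null(sim))
    stopf("provide input genomes or a simulation request")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Configuration file; keys as in
#'   \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

load_pipeline_genomes <- function(config) {
  if (!is.null(config$sim)) {
    args <- if (isTRUE(config$sim)) list() else config$sim
    if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_taxon_set(do.call(sim_config, args))
    return(list(genomes = sim$genomes, sim = sim))
  }
  paths <- config$genomes
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(fa|fna|fasta)$",
                        full.names = TRUE)
  if (length(paths) < 2) stopf("need at least two genome FASTA files")
  list(genomes = lapply(sort(paths), read_genome_fasta), sim = NULL)
}

#' Run the full genome-based taxonomy pipeline
#'
#' Deterministic given the configuration seed. Writes a report bundle
#' (distance matrix in PHYLIP format, classification TSV, partition TSV,
#' consistency profile TSV, Newick tree with supports, report JSON with a
#' manifest) and returns the report invisibly-visible as a list.
#'
#' @param config A \code{\link{pipeline_config}} (or path to a YAML/JSON
#'   config).
#' @return The report list (also written as \code{report.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  loaded <- load_pipeline_genomes(config)
  genomes <- loaded$genomes
  ids <- vapply(genomes, function(g) g$strain_id, character(1))
  message(sprintf("[genomes] %d strains", length(ids)))

  params <- do.call(match_params, config$match)
  pw <- gbdp_pairwise(genomes, config$formula, params)
  write_phylip_dist(pw$distances, file.path(out, "distances.phylip"))
  message("[distances] pairwise matrix done")

  model <- if (!is.null(config$model_c0))
    ddh_model(config$formula, c0 = config$model_c0, c1 = config$model_c1)
  else ddh_model(config$formula)

  type_id <- config$type_id %||% ids[1]
  gc_tab <- setNames(vapply(genomes, function(g) g$gc_fraction, numeric(1)),
                     ids)
  assignments <- classify_vs_type(pw, type_id, model,
                                  species_thr = config$species_thr,
                                  subsp_thr = config$subsp_thr,
                                  gc = gc_tab, gc_limit = config$gc_limit)
  write.table(assignments, file.path(out, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("[classify] type strain %s", type_id))

  # species groups at the species boundary, then the subspecies threshold
  # from within-species clustering consistency
  d_species <- ddh_to_distance(config$species_thr, model)
  p_species <- threshold_cluster(pw$distances, d_species, 0.5)
  submats <- lapply(split(names(p_species), as.integer(p_species)),
                    function(members) {
                      if (length(members) < 3) return(NULL)
                      pw$distances[members, members]
                    })
  submats <- Filter(Negate(is.null), submats)
  if (length(submats) > 0) {
    opt <- optimize_subspecies_threshold(submats, model)
    write.table(opt$profile, file.path(out, "consistency_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    opt <- list(T_star = NA_real_, ddh_star = NA_real_,
                status = "no_within_species_structure", profile = NULL)
  }
  T_sub <- if (!is.na(opt$T_star)) opt$T_star
           else ddh_to_distance(config$subsp_thr, model)
  p_sub <- threshold_cluster(pw$distances, T_sub, 0.5)
  stats <- cluster_stats(pw$distances, p_sub)
  write_partition(p_sub, file.path(out, "subspecies_partition.tsv"))
  message(sprintf("[cluster] T = %.5f -> %d clusters", T_sub,
                  length(unique(p_sub))))

  ref_opt <- NULL
  if (!is.null(config$reference)) {
    ref <- read_partition(config$reference)
    ref_opt <- optimize_against_reference(pw$distances, ref)
    write_partition(ref_opt$partition,
                    file.path(out, "reference_optimized_partition.tsv"))
  }

  tree <- build_tree(pw$distances)
  if (config$bootstrap_replicates > 0) {
    reps <- gbdp_bootstrap(pw, config$bootstrap_replicates,
                           seed = derive_seed(config$seed, "bootstrap"))
    tree <- annotate_support(tree, reps)
  }
  if (!is.null(config$outgroup))
    tree <- root_with_outgroup(tree, config$outgroup)
  write_tree_newick(tree, file.path(out, "tree.nwk"))
  message("[tree] done")

  files <- c("distances.phylip", "classification.tsv",
             "subspecies_partition.tsv", "tree.nwk")
  if (!is.null(opt$profile)) files <- c(files, "consistency_profile.tsv")
  if (!is.null(ref_opt)) files <- c(files, "reference_optimized_partition.tsv")
  report <- list(
    parameters = list(formula = config$formula, seed = config$seed,
                      type_id = type_id,
                      species_thr = config$species_thr,
                      subsp_thr = config$subsp_thr,
                      gc_limit = config$gc_limit,
                      match = unclass(params),
                      bootstrap_replicates = config$bootstrap_replicates,
                      ddh_model = list(c0 = model$c0, c1 = model$c1)),
    strains = as.list(setNames(
      vapply(genomes, function(g) g$total_length, numeric(1)), ids)),
    gc_fraction = as.list(gc_tab),
    assignments = assignments,
    species_partition = as.list(setNames(as.integer(p_species),
                                         names(p_species))),
    subspecies = list(T = T_sub,
                      ddh = distance_to_ddh(min(max(T_sub, 0), 1), model),
                      status = opt$status,
                      partition = as.list(setNames(as.integer(p_sub),
                                                   names(p_sub))),
                      stats = stats$per_cluster),
    reference_optimization = if (is.null(ref_opt)) NULL else
      ref_opt[c("T", "F", "agreement", "n_clusters")],
    tree = ape::write.tree(tree),
    provenance = list(package = "gbdtax",
                      version = as.character(utils::packageVersion("gbdtax")),
                      seed = config$seed),
    files = as.list(files))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
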