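#' Run the analysis pipeline
#'
#' Single entry point chaining the stages. Subcommands:
#' \describe{
#'   \item{simulate}{generate a synthetic dataset (tree, localities,
#'     specimens, clades) into \code{out}.}
#'   \item{ranges}{localities -> projected convex-hull ranges (vertex and
#'     summary CSVs).}
#'   \item{overlap}{ranges -> pairwise overlap-proportion matrix CSV.}
#'   \item{arc}{tree + overlap matrix -> per-node nested-overlap table.}
#'   \item{morpho}{specimens -> species means, Mahalanobis distances, DFA
#'     scores.}
#'   \item{compare}{overlap matrix + Mahalanobis matrix + clades ->
#'     pooled-t and permutation contrasts.}
#'   \item{aligncheck}{alignment -> summary statistics CSV.}
#'   \item{all}{ranges, overlap, arc, morpho, compare (and aligncheck when
#'     an alignment is given).}
#' }
#' Every run writes a manifest (inputs, parameters, seed, output
#' checksums) to \code{manifest.json} in \code{out}.
#'
#' @param command one of simulate, ranges, overlap, arc, morpho, compare,
#'   aligncheck, all.
#' @param localities,tree,specimens,clades,alignment input file paths (as
#'   required by the subcommand).
#' @param out output directory (created if needed).
#' @param seed integer seed for the stages that draw random numbers
#'   (simulate, compare).
#' @param permutations permutation count for \code{compare}.
#' @param ref_lat projection reference latitude in degrees, or "auto".
#' @param config optional \code{sim_config} for \code{simulate} (its seed
#'   is overridden by \code{seed}).
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(command, localities = NULL, tree = NULL,
                         specimens = NULL, clades = NULL, alignment = NULL,
                         out = ".", seed = 1L, permutations = 9999L,
                         ref_lat = "auto", config = NULL) {
  commands <- c("simulate", "ranges", "overlap", "arc", "morpho", "compare",
                "aligncheck", "all")
  if (!command %in% commands)
    stop("unknown subcommand '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  need <- function(path, what) {
    if (is.null(path)) stop("subcommand '", command, "' requires --", what)
    if (!file.exists(path)) stop(what, " file not found: ", path)
    path
  }

  if (command == "simulate") {
    cfg <- if (is.null(config)) sim_config(seed = seed) else config
    ds <- generate_dataset(cfg)
    outputs <- write_dataset(ds, out)
  }

  if (command %in% c("ranges", "overlap", "arc", "all")) {
    loc <- read_localities(need(localities, "localities"))
    proj <- project_localities(loc, reference_latitude = ref_lat)
    ranges <- species_ranges(proj)
    if (command %in% c("ranges", "all")) {
      write_ranges(ranges, file.path(out, "range_vertices.csv"),
                   file.path(out, "range_summary.csv"))
      outputs <- c(outputs, vertices = file.path(out, "range_vertices.csv"),
                   summary = file.path(out, "range_summary.csv"))
    }
    if (command %in% c("overlap", "arc", "all")) {
      M <- overlap_matrix(ranges)
      write_overlap_matrix(M, file.path(out, "overlap_matrix.csv"))
      outputs <- c(outputs, overlap = file.path(out, "overlap_matrix.csv"))
    }
    if (command %in% c("arc", "all")) {
      tr <- read_dated_tree(need(tree, "tree"))
      tab <- arc_table(tr, M)
      utils::write.csv(tab, file.path(out, "arc_table.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, arc = file.path(out, "arc_table.csv"))
    }
  }

  if (command %in% c("morpho", "all")) {
    sp <- read_specimens(need(specimens, "specimens"))
    summ <- summarize_species(sp)
    D2 <- mahalanobis_matrix(summ)
    proj <- dfa_project(sp, summ)
    write_morpho(summ, D2, proj, file.path(out, "species_means.csv"),
                 file.path(out, "mahalanobis.csv"),
                 file.path(out, "dfa_scores.csv"))
    outputs <- c(outputs, means = file.path(out, "species_means.csv"),
                 mahalanobis = file.path(out, "mahalanobis.csv"),
                 dfa = file.path(out, "dfa_scores.csv"))
  }

  if (command %in% c("compare", "all")) {
    cl <- read_clades(need(clades, "clades"))
    if (command == "compare") {
      loc <- read_localities(need(localities, "localities"))
      proj_pts <- project_localities(loc, reference_latitude = ref_lat)
      M <- overlap_matrix(species_ranges(proj_pts))
      sp <- read_specimens(need(specimens, "specimens"))
      D2 <- mahalanobis_matrix(summarize_species(sp))
    }
    results <- list(
      permutation_test(M, cl, n_permutations = permutations, seed = seed,
                       statistic_name = "within-clade range overlap"),
      permutation_test(D2, cl, n_permutations = permutations, seed = seed,
                       statistic_name = "within-clade Mahalanobis D2"))
    write_comparisons(results, file.path(out, "clade_contrasts.csv"),
                      file.path(out, "clade_contrasts.txt"))
    outputs <- c(outputs, contrasts = file.path(out, "clade_contrasts.csv"),
                 report = file.path(out, "clade_contrasts.txt"))
  }

  if (command == "aligncheck" ||
      (command == "all" && !is.null(alignment))) {
    aln <- read_alignment(need(alignment, "alignment"))
    utils::write.csv(alignment_summary(aln, basename(alignment)),
                     file.path(out, "alignment_summary.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, alignment = file.path(out, "alignment_summary.csv"))
  }

  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("arcmorph")),
    inputs = Filter(Negate(is.null),
                    list(localities = localities, tree = tree,
                         specimens = specimens, clades = clades,
                         alignment = alignment)),
    parameters = list(seed = seed, permutations = permutations,
                      ref_lat = ref_lat),
    outputs = as.list(tools::md5sum(unname(unlist(outputs)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(outputs, manifest = file.path(out, "manifest.json")))
}
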