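# Seeded synthetic-data generator: a two-clade dated Yule tree, ranges
# that fragment (vicariant) or duplicate (sympatric) at speciation,
# map-precision-noised localities, and four correlated positive traits
# evolving by Brownian motion on the log scale with extra divergence at
# sympatric splits. Defaults emulate the study design this pipeline
# targets: clades of 6 and 4 species, Pliocene-scale crown ages, about a
# dozen localities per species with ~5 km precision, and 20 measured
# specimens per species.

#' Simulation configuration
#'
#' All generative parameters for the synthetic harness. Defaults describe
#' a 6-species clade speciating vicariantly and a 4-species clade
#' speciating sympatrically with adaptive trait divergence.
#'
#' @param n_species_per_clade named integer vector, tips per clade.
#' @param birth_rate Yule speciation rate per Ma.
#' @param range_mode named character vector per clade: "vicariant" (range
#'   fragmentation at speciation) or "sympatric" (range duplication).
#' @param root_range width and height (km) of the ancestral rectangular
#'   range.
#' @param split_fraction area fraction taken by one daughter at a
#'   vicariant split, in (0, 1).
#' @param dispersal_sd post-speciation range translation, km per sqrt(Ma).
#' @param localities_per_species sampled point localities per species.
#' @param locality_noise_sd isotropic georeferencing noise, km (emulating
#'   map precision of several km).
#' @param bm_rate Brownian trait variance per Ma on the log scale.
#' @param bm_corr correlation between trait increments.
#' @param sympatric_divergence_boost kappa: magnitude of the opposite mean
#'   shifts (in units of the per-Ma Brownian SD) given to the two
#'   daughters on a random trait axis at each sympatric split. The default
#'   of 5 makes the adaptive clade's mean pairwise squared Mahalanobis
#'   distance roughly an order of magnitude larger than the vicariant
#'   clade's, the contrast scale observed in strongly ecologically
#'   diverged clades.
#' @param specimens_per_species measured specimens per species.
#' @param measurement_cv coefficient of variation of lognormal
#'   within-species measurement noise.
#' @param trait_base species-mean trait values (mm) at the root:
#'   capitulum length/width, leaf length/width.
#' @param origin_lon,origin_lat geographic anchor of the planar frame.
#' @param seed integer seed; all generators are reproducible from
#'   (config, seed).
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_species_per_clade = c(A = 6L, B = 4L),
                       birth_rate = 0.45,
                       range_mode = c(A = "vicariant", B = "sympatric"),
                       root_range = c(width = 300, height = 150),
                       split_fraction = 0.5,
                       dispersal_sd = 10,
                       localities_per_species = 12L,
                       locality_noise_sd = 5,
                       bm_rate = 0.02,
                       bm_corr = 0.5,
                       sympatric_divergence_boost = 5,
                       specimens_per_species = 20L,
                       measurement_cv = 0.1,
                       trait_base = c(cap_len_mm = 8, cap_wid_mm = 5,
                                      leaf_len_mm = 25, leaf_wid_mm = 4),
                       origin_lon = 29.5, origin_lat = -29.5,
                       seed = 42L) {
  cfg <- list(n_species_per_clade = as.integer(n_species_per_clade),
              birth_rate = birth_rate, range_mode = range_mode,
              root_range = root_range, split_fraction = split_fraction,
              dispersal_sd = dispersal_sd,
              localities_per_species = as.integer(localities_per_species),
              locality_noise_sd = locality_noise_sd,
              bm_rate = bm_rate, bm_corr = bm_corr,
              sympatric_divergence_boost = sympatric_divergence_boost,
              specimens_per_species = as.integer(specimens_per_species),
              measurement_cv = measurement_cv, trait_base = trait_base,
              origin_lon = origin_lon, origin_lat = origin_lat,
              seed = as.integer(seed))
  names(cfg$n_species_per_clade) <- names(n_species_per_clade)
  stopifnot(all(cfg$n_species_per_clade >= 2L),
            length(cfg$n_species_per_clade) == 2L,
            birth_rate > 0,
            all(range_mode %in% c("vicariant", "sympatric")),
            identical(sort(names(range_mode)),
                      sort(names(cfg$n_species_per_clade))),
            all(root_range > 0),
            split_fraction > 0, split_fraction < 1,
            dispersal_sd >= 0, locality_noise_sd >= 0,
            localities_per_species >= 1L,
            bm_rate >= 0, bm_corr >= -1 / 3, bm_corr <= 1,
            sympatric_divergence_boost >= 0,
            specimens_per_species >= 1L, measurement_cv >= 0,
            length(trait_base) == 4L, all(trait_base > 0))
  structure(cfg, class = "sim_config")
}

#' Read/write a simulation configuration as YAML
#' @param path YAML file path.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, lapply(vals, unlist))
}

#' @rdname read_sim_config
#' @param config a \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.null(names(x))) x else as.list(x)), path)
  invisible(path)
}

# forward Yule (pure birth) crown tree conditioned on n tips: intervals
# with k lineages are Exp(k * lambda), k = 2..n, plus a final Exp(n*lambda)
# stretch after the last split so terminal branches are positive.
yule_crown_tree <- function(n, lambda, prefix) {
  nodes <- list(list(start = 0, children = NULL),
                list(start = 0, children = NULL))
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1L, k * lambda)
    i <- active[sample.int(k, 1L)]
    id1 <- length(nodes) + 1L; id2 <- id1 + 1L
    nodes[[id1]] <- list(start = t, children = NULL)
    nodes[[id2]] <- list(start = t, children = NULL)
    nodes[[i]]$children <- c(id1, id2)
    nodes[[i]]$end <- t
    active <- c(setdiff(active, i), id1, id2)
  }
  t_end <- t + stats::rexp(1L, n * lambda)
  for (i in active) nodes[[i]]$end <- t_end
  counter <- 0L
  newick <- function(i) {
    len <- nodes[[i]]$end - nodes[[i]]$start
    if (is.null(nodes[[i]]$children)) {
      counter <<- counter + 1L
      sprintf("%s_sp%d:%.10f", prefix, counter, len)
    } else {
      sprintf("(%s,%s):%.10f", newick(nodes[[i]]$children[1L]),
              newick(nodes[[i]]$children[2L]), len)
    }
  }
  list(text = sprintf("(%s,%s)", newick(1L), newick(2L)),
       height = t_end)
}

#' Simulate a two-clade dated Yule tree
#'
#' Each clade is a pure-birth (Yule) crown tree conditioned on its tip
#' count; the two clades are joined at a root whose age is the larger
#' clade height plus one expected speciation waiting time (1 /
#' birth_rate). Tip labels are \code{<clade>_sp<i>}.
#'
#' @param config a \code{sim_config}.
#' @param seed seed, or NULL to use the current RNG state.
#' @return an ultrametric \code{phylo} object.
#' @export
simulate_tree <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  nm <- names(config$n_species_per_clade)
  c1 <- yule_crown_tree(config$n_species_per_clade[1L], config$birth_rate,
                        nm[1L])
  c2 <- yule_crown_tree(config$n_species_per_clade[2L], config$birth_rate,
                        nm[2L])
  root_age <- max(c1$height, c2$height) + 1 / config$birth_rate
  txt <- sprintf("(%s:%.10f,%s:%.10f);", c1$text, root_age - c1$height,
                 c2$text, root_age - c2$height)
  ape::read.tree(text = txt)
}

# clade label of every node: the common tip-label prefix of its
# descendants, NA for the root (whose descendants span both clades)
node_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab_clade <- sub("_.*$", "", tree$tip.label)
  out <- rep(NA_character_, ntip + tree$Nnode)
  out[seq_len(ntip)] <- lab_clade
  po <- rev(seq.int(ntip + 1L, ntip + tree$Nnode))
  for (n in sort(unique(tree$edge[, 1L]), decreasing = TRUE)) {
    kids <- tree$edge[tree$edge[, 1L] == n, 2L]
    cl <- unique(out[kids])
    out[n] <- if (length(cl) == 1L && !anyNA(cl)) cl else NA_character_
  }
  out
}

#' Simulate range polygons along the tree
#'
#' The root range (a rectangle centred on the planar origin) is inherited
#' by both basal clades. At each within-clade speciation event a vicariant
#' clade splits the parent polygon by a random chord into complementary
#' parts (daughter overlap exactly 0 at birth); a sympatric clade copies
#' the parent polygon to both daughters (overlap 1 at birth). After every
#' event each daughter lineage's polygon is translated by an isotropic
#' Gaussian displacement with SD dispersal_sd * sqrt(branch length).
#'
#' @param tree tree from [simulate_tree()].
#' @param config a \code{sim_config}.
#' @param seed seed, or NULL to use the current RNG state.
#' @return named list of counter-clockwise polygon matrices (km), one per
#'   tip species.
#' @export
simulate_ranges <- function(tree, config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  clades <- node_clades(tree)
  w <- config$root_range[1L]; h <- config$root_range[2L]
  root_poly <- rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2),
                     c(w / 2, h / 2), c(-w / 2, h / 2))
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  out <- vector("list", ntip)
  names(out) <- tree$tip.label
  recurse <- function(node, poly) {
    kids <- node_children(tree, node)
    mode <- if (is.na(clades[node])) "sympatric"
      else config$range_mode[[clades[node]]]
    parts <- if (mode == "vicariant") {
      p <- split_by_chord(poly, stats::runif(1L, 0, 2 * pi),
                          config$split_fraction)
      p[sample.int(2L)]
    } else {
      list(poly, poly)
    }
    for (i in 1:2) {
      kid <- kids[i]
      shift <- stats::rnorm(2L, 0, config$dispersal_sd *
                              sqrt(elen[[as.character(kid)]]))
      p <- monotone_chain(sweep(parts[[i]], 2L, -shift))
      if (kid <= ntip) out[[kid]] <<- p else recurse(kid, p)
    }
  }
  recurse(ntip + 1L, root_poly)
  out
}

#' Sample noisy point localities inside a range polygon
#'
#' Uniform points by rejection sampling in the polygon's bounding box,
#' plus isotropic Gaussian georeferencing noise, back-projected to
#' longitude/latitude around the configured planar origin.
#'
#' @param polygon counter-clockwise polygon matrix (km).
#' @param n number of localities.
#' @param noise_sd Gaussian noise SD in km.
#' @param origin_lon,origin_lat geographic anchor of the planar frame.
#' @param seed seed, or NULL to use the current RNG state.
#' @return data.frame with longitude, latitude, x, y (noised planar km).
#' @export
sample_localities <- function(polygon, n, noise_sd = 0,
                              origin_lon = 29.5, origin_lat = -29.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nrow(polygon)) || nrow(polygon) < 3L ||
      polygon_area(polygon) <= 0)
    stop("cannot sample localities from a degenerate polygon")
  if (n < 1L) stop("n must be >= 1")
  xr <- range(polygon[, 1L]); yr <- range(polygon[, 2L])
  pts <- matrix(numeric(0), ncol = 2L)
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 16L)
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]),
                  stats::runif(m, yr[1L], yr[2L]))
    pts <- rbind(pts, cand[points_in_convex(cand, polygon), , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  pts <- pts + matrix(stats::rnorm(2L * n, 0, noise_sd), ncol = 2L)
  geo <- unproject_points(pts, origin_lon, origin_lat)
  data.frame(longitude = geo$longitude, latitude = geo$latitude,
             x = pts[, 1L], y = pts[, 2L])
}

#' Simulate species trait means and specimen measurements
#'
#' Four correlated traits evolve by Brownian motion on the log scale along
#' the tree (rate bm_rate per Ma, increment correlation bm_corr). At each
#' sympatric speciation event the two daughters additionally receive
#' opposite mean shifts of magnitude kappa * sqrt(bm_rate) on one randomly
#' chosen trait axis, modelling character displacement under adaptive
#' divergence. Species means are exponentiated to mm; specimens are drawn
#' with lognormal measurement noise of the configured coefficient of
#' variation.
#'
#' @param tree tree from [simulate_tree()].
#' @param config a \code{sim_config}.
#' @param seed seed, or NULL to use the current RNG state.
#' @return specimen data.frame (columns specimen, species, and the four
#'   trait columns in mm) with the true species means attached as
#'   attribute \code{species_means_mm}.
#' @export
simulate_traits_and_specimens <- function(tree, config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  clades <- node_clades(tree)
  rho <- config$bm_corr
  Sigma <- config$bm_rate * ((1 - rho) * diag(4L) + rho)
  Ch <- if (config$bm_rate > 0)
    chol(Sigma + 1e-12 * config$bm_rate * diag(4L)) else matrix(0, 4L, 4L)
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  logmu <- matrix(NA_real_, ntip + tree$Nnode, 4L)
  logmu[ntip + 1L, ] <- log(config$trait_base)
  recurse <- function(node) {
    kids <- node_children(tree, node)
    mode <- if (is.na(clades[node])) "none"
      else config$range_mode[[clades[node]]]
    shift <- matrix(0, 2L, 4L)
    if (mode == "sympatric" && config$sympatric_divergence_boost > 0) {
      axis <- sample.int(4L, 1L)
      sgn <- sample(c(-1, 1), 1L)
      mag <- config$sympatric_divergence_boost * sqrt(config$bm_rate)
      shift[1L, axis] <- sgn * mag
      shift[2L, axis] <- -sgn * mag
    }
    for (i in 1:2) {
      kid <- kids[i]
      bl <- elen[[as.character(kid)]]
      inc <- drop(stats::rnorm(4L) %*% Ch) * sqrt(bl)
      logmu[kid, ] <<- logmu[node, ] + shift[i, ] + inc
      if (kid > ntip) recurse(kid)
    }
  }
  recurse(ntip + 1L)
  means_mm <- exp(logmu[seq_len(ntip), , drop = FALSE])
  dimnames(means_mm) <- list(tree$tip.label, trait_cols)
  sdlog <- sqrt(log(1 + config$measurement_cv^2))
  nsp <- config$specimens_per_species
  rows <- lapply(tree$tip.label, function(s) {
    noise <- matrix(stats::rnorm(nsp * 4L, 0, sdlog), nsp, 4L)
    vals <- exp(sweep(noise, 2L, log(means_mm[s, ]), `+`))
    colnames(vals) <- trait_cols
    data.frame(specimen = paste0(s, "_", seq_len(nsp)), species = s, vals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "species_means_mm") <- means_mm
  out
}

#' Generate a complete synthetic dataset
#'
#' Composes the tree, range, locality and specimen generators under one
#' seed and returns everything the analysis pipeline consumes.
#'
#' @param config a \code{sim_config}.
#' @return object of class \code{synthetic_dataset}: list with tree,
#'   ranges (true polygons), localities, specimens, clades (named
#'   species-to-clade vector) and provenance (config and seed).
#' @export
generate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config, seed = NULL)
  ranges <- simulate_ranges(tree, config, seed = NULL)
  loc <- do.call(rbind, lapply(names(ranges), function(s) {
    l <- sample_localities(ranges[[s]], config$localities_per_species,
                           config$locality_noise_sd, config$origin_lon,
                           config$origin_lat, seed = NULL)
    data.frame(species = s, longitude = l$longitude, latitude = l$latitude,
               precision_m = 1000 * config$locality_noise_sd,
               source = "simulated")
  }))
  specimens <- simulate_traits_and_specimens(tree, config, seed = NULL)
  clades <- stats::setNames(sub("_.*$", "", tree$tip.label), tree$tip.label)
  structure(list(tree = tree, ranges = ranges, localities = loc,
                 specimens = specimens, clades = clades,
                 provenance = list(config = config, seed = config$seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", ape::Ntip(x$tree), "species in",
      length(unique(x$clades)), "clades;",
      nrow(x$localities), "localities;", nrow(x$specimens), "specimens;",
      "seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits localities.csv, specimens.csv, clades.csv, tree.nwk,
#' true_ranges.csv (vertex table of the generating polygons) and
#' config.yaml into a directory. The files are consumed unchanged by
#' [run_pipeline()].
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(localities = file.path(dir, "localities.csv"),
             specimens = file.path(dir, "specimens.csv"),
             clades = file.path(dir, "clades.csv"),
             tree = file.path(dir, "tree.nwk"),
             ranges = file.path(dir, "true_ranges.csv"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(dataset$localities, paths["localities"], row.names = FALSE)
  utils::write.csv(dataset$specimens, paths["specimens"], row.names = FALSE)
  utils::write.csv(data.frame(species = names(dataset$clades),
                              clade = unname(dataset$clades)),
                   paths["clades"], row.names = FALSE)
  ape::write.tree(dataset$tree, paths["tree"])
  verts <- do.call(rbind, lapply(names(dataset$ranges), function(s) {
    v <- dataset$ranges[[s]]
    data.frame(species = s, vertex_index = seq_len(nrow(v)),
               x_km = v[, 1L], y_km = v[, 2L])
  }))
  utils::write.csv(verts, paths["ranges"], row.names = FALSE)
  write_sim_config(dataset$provenance$config, paths["config"])
  invisible(paths)
}
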