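# Morphometric divergence: species trait means, pooled within-group
# covariance, Mahalanobis distances and canonical-variates (DFA) scores
# from specimen-level measurements of the four floral/vegetative traits
# (capitulum length/width, leaf length/width, in mm).

trait_cols <- c("cap_len_mm", "cap_wid_mm", "leaf_len_mm", "leaf_wid_mm")

#' Read specimen measurements from CSV
#'
#' Expects columns \code{specimen}, \code{species} and the four trait
#' columns \code{cap_len_mm}, \code{cap_wid_mm}, \code{leaf_len_mm},
#' \code{leaf_wid_mm}. Rows with missing or non-positive measurements are
#' rejected with a row-level warning; extra columns are ignored with a
#' message.
#'
#' @param path CSV file path.
#' @return data.frame of validated specimen records.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("specimen file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", trait_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimen CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$specimen)) df$specimen <- paste0("spec", seq_len(nrow(df)))
  extra <- setdiff(names(df), c("specimen", need))
  if (length(extra))
    message("ignoring extra specimen column(s): ", paste(extra, collapse = ", "))
  df <- df[c("specimen", "species", trait_cols)]
  vals <- as.matrix(df[trait_cols])
  bad <- which(!apply(vals, 1L, function(r) all(is.finite(r) & r > 0)))
  if (length(bad)) {
    warning("rejecting ", length(bad), " specimen row(s) with missing or ",
            "non-positive measurements: rows ", paste(bad, collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Per-species trait means and covariances
#'
#' Means over all specimens of each species; sample ((n-1)-denominator)
#' covariance matrices where a species has at least two specimens, else the
#' covariance is flagged undefined (NULL) but the mean is retained.
#'
#' @param specimens specimen data.frame (see [read_specimens()]).
#' @return object of class \code{trait_summary}: list with \code{species},
#'   \code{n} (specimen counts), \code{means} (species x 4 matrix) and
#'   \code{cov} (list of 4 x 4 matrices or NULL).
#' @export
summarize_species <- function(specimens) {
  sp <- unique(specimens$species)
  means <- matrix(NA_real_, length(sp), length(trait_cols),
                  dimnames = list(sp, trait_cols))
  covs <- vector("list", length(sp)); names(covs) <- sp
  n <- integer(length(sp)); names(n) <- sp
  for (s in sp) {
    m <- as.matrix(specimens[specimens$species == s, trait_cols])
    n[s] <- nrow(m)
    means[s, ] <- colMeans(m)
    covs[[s]] <- if (nrow(m) >= 2L) stats::cov(m) else NULL
  }
  structure(list(species = sp, n = n, means = means, cov = covs),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat("Trait summary for", length(x$species), "species;",
      sum(x$n), "specimens\n")
  print(cbind(n = x$n, round(x$means, 2)))
  invisible(x)
}

#' Pooled within-group covariance matrix
#'
#' \eqn{S_W = \sum_i (n_i - 1) S_i / (N - k)} over the k species with at
#' least two specimens (N the total specimens of those species). Species
#' with a single specimen contribute a mean but no covariance.
#'
#' @param summaries a \code{trait_summary}.
#' @return symmetric positive semi-definite 4 x 4 matrix.
#' @export
pooled_within_covariance <- function(summaries) {
  keep <- summaries$species[summaries$n >= 2L]
  if (length(keep) < 2L)
    stop("need at least two species with >= 2 specimens to pool covariance")
  N <- sum(summaries$n[keep])
  k <- length(keep)
  S <- Reduce(`+`, lapply(keep, function(s)
    (summaries$n[s] - 1) * summaries$cov[[s]]))
  S / (N - k)
}

# condition-number guard shared by Mahalanobis and DFA
check_invertible <- function(S, threshold = 1e12) {
  d <- svd(S, nu = 0, nv = 0)$d
  if (min(d) <= 0 || max(d) / min(d) > threshold)
    stop("pooled within-group covariance is singular or near-singular ",
         "(condition number > 1e12); remove a redundant trait or ",
         "regularise before computing distances")
  invisible(TRUE)
}

#' Pairwise squared Mahalanobis distances between species means
#'
#' \eqn{D^2_{ij} = (\mu_i - \mu_j)^T S_W^{-1} (\mu_i - \mu_j)} using the
#' pooled within-group covariance, i.e. squared Euclidean distance after
#' whitening by the within-group scatter. Reported as squared distances;
#' the square root is \code{sqrt()} of the result.
#'
#' @param summaries a \code{trait_summary}.
#' @param pooled pooled covariance (default computed from
#'   \code{summaries}).
#' @return symmetric matrix of squared distances, zero diagonal, species
#'   dimnames.
#' @export
mahalanobis_matrix <- function(summaries,
                               pooled = pooled_within_covariance(summaries)) {
  check_invertible(pooled)
  mu <- summaries$means
  Sinv <- solve(pooled)
  k <- nrow(mu)
  D2 <- matrix(0, k, k, dimnames = list(rownames(mu), rownames(mu)))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    d <- mu[i, ] - mu[j, ]
    D2[i, j] <- D2[j, i] <- drop(t(d) %*% Sinv %*% d)
  }
  D2
}

#' Canonical-variates (discriminant functions) projection
#'
#' Canonical axes are the eigenvectors of \eqn{S_W^{-1} B}, where B is the
#' between-group scatter of the species means (weighted by specimen counts
#' for the specimen-level entry, unweighted for the species-mean entry),
#' scaled so the within-group variance of scores is 1 on every axis. With
#' this normalisation the squared Euclidean distance between two species
#' centroids across the full canonical space equals their Mahalanobis
#' \eqn{D^2}.
#'
#' @param specimens specimen data.frame.
#' @param summaries optional precomputed \code{trait_summary}.
#' @param level "specimen" (default) weights the between-group scatter by
#'   specimen counts and returns per-specimen scores; "species" weights
#'   every species equally (the entry point for analyses run on species
#'   means).
#' @return object of class \code{dfa_projection}: list with \code{axes}
#'   (4 x m matrix of axis coefficients), \code{eigenvalues} (decreasing,
#'   >= 0), \code{species_scores}, \code{specimen_scores} (NULL for the
#'   species-mean entry) and \code{n_axes} (number of non-null axes,
#'   at most min(4, k - 1)).
#' @export
dfa_project <- function(specimens, summaries = summarize_species(specimens),
                        level = c("specimen", "species")) {
  level <- match.arg(level)
  k <- length(summaries$species)
  if (k < 2L) stop("need at least two species")
  W <- pooled_within_covariance(summaries)
  check_invertible(W)
  mu <- summaries$means
  w <- if (level == "specimen") summaries$n else rep(1, k)
  grand <- colSums(mu * w) / sum(w)
  dev <- sweep(mu, 2L, grand)
  B <- crossprod(dev * sqrt(w))          # sum_i w_i (mu_i - grand)(mu_i - grand)^T
  L <- chol(W)                           # W = L^T L
  M <- backsolve(L, t(backsolve(L, t(B), transpose = TRUE)), transpose = TRUE)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  axes <- backsolve(L, eig$vectors)      # a = L^{-1} v  =>  a^T W a = 1
  dimnames(axes) <- list(colnames(mu), paste0("CV", seq_len(ncol(axes))))
  n_axes <- min(ncol(mu), k - 1L)
  species_scores <- dev %*% axes
  specimen_scores <- NULL
  if (level == "specimen") {
    X <- as.matrix(specimens[trait_cols])
    specimen_scores <- sweep(X, 2L, grand) %*% axes
    rownames(specimen_scores) <- specimens$specimen
  }
  structure(list(axes = axes, eigenvalues = vals,
                 species_scores = species_scores,
                 specimen_scores = specimen_scores,
                 n_axes = n_axes, level = level),
            class = "dfa_projection")
}

#' @export
print.dfa_projection <- function(x, ...) {
  cat("Discriminant-functions projection (", x$level, "-level entry)\n",
      "  non-null axes: ", x$n_axes, "\n", sep = "")
  cat("  eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}

#' Write morphometric outputs
#'
#' Species means, the Mahalanobis matrix in long form (species_a,
#' species_b, D2, D) and DFA scores on the first two canonical axes.
#'
#' @param summaries \code{trait_summary}.
#' @param D2 squared-distance matrix from [mahalanobis_matrix()].
#' @param proj \code{dfa_projection}.
#' @param means_path,dist_path,scores_path output CSV paths.
#' @export
write_morpho <- function(summaries, D2, proj, means_path, dist_path,
                         scores_path) {
  means <- data.frame(species = summaries$species, n = summaries$n,
                      summaries$means, check.names = FALSE)
  utils::write.csv(means, means_path, row.names = FALSE)
  ids <- rownames(D2)
  pairs <- which(upper.tri(D2), arr.ind = TRUE)
  dist <- data.frame(species_a = ids[pairs[, 1L]], species_b = ids[pairs[, 2L]],
                     D2 = D2[pairs], D = sqrt(D2[pairs]))
  utils::write.csv(dist, dist_path, row.names = FALSE)
  sc <- proj$species_scores[, seq_len(min(2L, ncol(proj$species_scores))),
                            drop = FALSE]
  scores <- data.frame(species = rownames(sc), sc, check.names = FALSE)
  utils::write.csv(scores, scores_path, row.names = FALSE)
  invisible(NULL)
}
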