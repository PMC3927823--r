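# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the code paths they check.

# Monte-Carlo membership estimate of a polygon's area: sample the bounding
# box, count hits. Returns the estimate and its binomial standard error.
mc_polygon_area <- function(poly, n = 2e5) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  box <- diff(xr) * diff(yr)
  pts <- cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  hit <- point_in_poly_oracle(pts, poly)
  p <- mean(hit)
  list(area = p * box, se = sqrt(p * (1 - p) / n) * box)
}

# Ray-free membership test written independently of the package's
# half-plane form: a point is inside a CCW convex polygon iff it is on the
# left of (or on) every directed edge.
point_in_poly_oracle <- function(pts, poly) {
  n <- nrow(poly)
  ok <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    ok <- ok & ((poly[j, 1] - poly[i, 1]) * (pts[, 2] - poly[i, 2]) -
                (poly[j, 2] - poly[i, 2]) * (pts[, 1] - poly[i, 1]) >= -1e-9)
  }
  ok
}

# Monte-Carlo intersection area of two convex polygons via joint membership.
mc_intersection_area <- function(a, b, n = 2e5) {
  xr <- range(c(a[, 1], b[, 1])); yr <- range(c(a[, 2], b[, 2]))
  box <- diff(xr) * diff(yr)
  pts <- cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  hit <- point_in_poly_oracle(pts, a) & point_in_poly_oracle(pts, b)
  p <- mean(hit)
  list(area = p * box, se = sqrt(p * (1 - p) / n) * box)
}

# random convex polygon: convex hull of m uniform points
random_convex_poly <- function(m = 12, scale = 1) {
  r <- build_hull(matrix(runif(2 * m, -scale, scale), ncol = 2), "tmp")
  r$vertices
}

square_range <- function(x0, y0, side = 1, id = "sq") {
  build_hull(rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                   c(x0, y0 + side)), id)
}

# Closed-form nested-overlap oracle: each tip's weight inside its daughter
# clade is (1/2)^(number of internal nodes on the path from the clade root
# to the tip, counting the clade root when it is internal, excluding the
# tip); the node value is the weighted sum of cross-clade pairwise
# overlaps. Uses ape::nodepath, independent of the package recursion.
nested_overlap_oracle <- function(tree, node, M) {
  ntip <- ape::Ntip(tree)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  clade_weights <- function(root) {
    if (root <= ntip)
      return(setNames(1, tree$tip.label[root]))
    tips <- ape::extract.clade(tree, root)$tip.label
    w <- vapply(tips, function(tp) {
      path <- ape::nodepath(tree, root, which(tree$tip.label == tp))
      0.5^sum(path > ntip)
    }, numeric(1))
    w
  }
  wL <- clade_weights(kids[1]); wR <- clade_weights(kids[2])
  sum(outer(wL, wR) * M[names(wL), names(wR), drop = FALSE])
}

# brute-force parsimony-informative column counter on a character matrix
pis_oracle <- function(m) {
  m[m == "U"] <- "T"
  sum(apply(m, 2, function(col) {
    counts <- sapply(c("A", "C", "G", "T"), function(s) sum(col == s))
    sum(counts >= 2) >= 2
  }))
}

# random symmetric overlap-like matrix with unit diagonal
random_overlap_matrix <- function(ids) {
  n <- length(ids)
  M <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

# small specimen table drawn from given species means / covariance
make_specimens <- function(means, n_per, Sigma = diag(4)) {
  ch <- chol(Sigma)
  do.call(rbind, lapply(rownames(means), function(s) {
    vals <- matrix(rnorm(n_per * 4), n_per, 4) %*% ch
    vals <- sweep(vals, 2, as.numeric(means[s, ]), `+`)
    colnames(vals) <- c("cap_len_mm", "cap_wid_mm", "leaf_len_mm",
                        "leaf_wid_mm")
    data.frame(specimen = paste0(s, seq_len(n_per)), species = s, vals)
  }))
}
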