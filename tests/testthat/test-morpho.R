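test_that("specimen CSV reading validates rows and columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(3)
  df <- make_specimens(matrix(10, 1, 4, dimnames = list("sp1", NULL)), 20)
  write.csv(df, f, row.names = FALSE)
  expect_equal(nrow(read_specimens(f)), 20)

  df$leaf_len_mm[3] <- 0
  df$cap_wid_mm[7] <- NA
  write.csv(df, f, row.names = FALSE)
  expect_warning(kept <- read_specimens(f), "rejecting 2")
  expect_equal(nrow(kept), 18)

  df$habitat <- "scarp"
  df$leaf_len_mm[3] <- 1; df$cap_wid_mm[7] <- 1
  write.csv(df, f, row.names = FALSE)
  expect_message(read_specimens(f), "extra specimen column")

  write.csv(df[, -3], f, row.names = FALSE)
  expect_error(read_specimens(f), "missing required column")
})

test_that("species summaries give means and (n-1)-covariances", {
  one <- data.frame(specimen = "s1", species = "solo", cap_len_mm = 4,
                    cap_wid_mm = 3, leaf_len_mm = 20, leaf_wid_mm = 2)
  s <- summarize_species(one)
  expect_equal(unname(s$means["solo", ]), c(4, 3, 20, 2))
  expect_null(s$cov[["solo"]])

  two <- rbind(one, one)
  two$specimen <- c("s1", "s2")
  s2 <- summarize_species(two)
  expect_equal(unname(s2$cov[["solo"]]), matrix(0, 4, 4))

  set.seed(13)
  mu <- c(8, 5, 25, 4)
  Sigma <- 0.5 * diag(4) + 0.5
  sp <- make_specimens(matrix(mu, 1, dimnames = list("x", NULL)), 20, Sigma)
  s3 <- summarize_species(sp)
  se <- sqrt(diag(Sigma) / 20)
  expect_true(all(abs(s3$means["x", ] - mu) < 4 * se))
  expect_equal(unname(s3$cov[["x"]]),
               unname(cov(as.matrix(sp[, 3:6]))))
})

test_that("pooled covariance follows the (N - k) rule and exclusions", {
  means <- matrix(c(1, 1, 1, 1, 5, 5, 5, 5), 2, 4, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  set.seed(17)
  sp <- make_specimens(means, 30, diag(4))
  s <- summarize_species(sp)
  W <- pooled_within_covariance(s)
  expect_equal(W, t(W))
  expect_true(all(eigen(W, symmetric = TRUE, only.values = TRUE)$values > 0))
  # equal n: pooled = average of the two sample covariances
  expect_equal(W, (s$cov[["a"]] + s$cov[["b"]]) / 2, tolerance = 1e-12)

  # residual-scatter oracle on unbalanced groups, singleton excluded
  sp2 <- rbind(make_specimens(means["a", , drop = FALSE], 9),
               make_specimens(means["b", , drop = FALSE], 4))
  solo <- make_specimens(matrix(3, 1, 4, dimnames = list("c", NULL)), 1)
  s2 <- summarize_species(rbind(sp2, solo))
  W2 <- pooled_within_covariance(s2)
  resid <- do.call(rbind, lapply(c("a", "b"), function(g) {
    m <- as.matrix(sp2[sp2$species == g, 3:6])
    sweep(m, 2, colMeans(m))
  }))
  expect_equal(unname(W2), unname(crossprod(resid) / (13 - 2)),
               tolerance = 1e-12)
  expect_true("c" %in% s2$species)       # singleton keeps its mean

  expect_error(pooled_within_covariance(summarize_species(solo)),
               "at least two species")
})

test_that("Mahalanobis matrix matches analytic and whitening oracles", {
  means <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  summ <- list(species = c("a", "b"), n = c(a = 5, b = 5),
               means = means, cov = NULL)
  class(summ) <- "trait_summary"
  D2 <- mahalanobis_matrix(summ, pooled = diag(4))
  expect_equal(unname(D2["a", "b"]), 1)             # Euclidean reduction
  D2b <- mahalanobis_matrix(summ, pooled = diag(c(4, 1, 1, 1)))
  expect_equal(unname(D2b["a", "b"]), 0.25)

  set.seed(19)
  k <- 5
  mu <- matrix(rnorm(4 * k), k, 4,
               dimnames = list(paste0("s", 1:k), NULL))
  A <- matrix(rnorm(16), 4, 4)
  S <- crossprod(A) + diag(4)
  summ2 <- list(species = rownames(mu), n = setNames(rep(5, k), rownames(mu)),
                means = mu, cov = NULL)
  class(summ2) <- "trait_summary"
  D2r <- mahalanobis_matrix(summ2, pooled = S)
  # whitening oracle: squared Euclidean distance after S^{-1/2} transform
  e <- eigen(S, symmetric = TRUE)
  white <- mu %*% e$vectors %*% diag(1 / sqrt(e$values))
  expect_equal(unname(D2r), unname(as.matrix(dist(white))^2),
               tolerance = 1e-9)
  # cross-check one row against stats::mahalanobis
  expect_equal(unname(D2r[1, ]),
               unname(stats::mahalanobis(mu, mu[1, ], S)), tolerance = 1e-9)
  expect_equal(D2r, t(D2r))
  expect_equal(unname(diag(D2r)), rep(0, k))
  # triangle inequality for D = sqrt(D2)
  D <- sqrt(D2r)
  for (i in 1:k) for (j in 1:k) for (l in 1:k)
    expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-9)

  expect_error(mahalanobis_matrix(summ2, pooled = matrix(1, 4, 4)),
               "singular")
})

test_that("Mahalanobis D2 is invariant under affine transformation", {
  set.seed(23)
  means <- matrix(rnorm(12, 10), 3, 4,
                  dimnames = list(c("a", "b", "c"), NULL))
  sp <- make_specimens(means, 15, crossprod(matrix(rnorm(16), 4)) / 4 +
                         diag(4) * 0.1)
  s1 <- summarize_species(sp)
  D2a <- mahalanobis_matrix(s1)

  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2
  b <- rnorm(4)
  sp2 <- sp
  sp2[, 3:6] <- t(A %*% t(as.matrix(sp[, 3:6])) + b)
  D2b <- mahalanobis_matrix(summarize_species(sp2))
  expect_equal(D2a, D2b, tolerance = 1e-8)
})

test_that("DFA axes have unit within-variance and recover D2 distances", {
  set.seed(29)
  k <- 4
  means <- matrix(rnorm(4 * k, 10, 2), k, 4,
                  dimnames = list(paste0("g", 1:k), NULL))
  sp <- make_specimens(means, 12, crossprod(matrix(rnorm(16), 4)) / 8 +
                         diag(4) * 0.2)
  summ <- summarize_species(sp)
  proj <- dfa_project(sp, summ)
  W <- pooled_within_covariance(summ)

  expect_equal(proj$n_axes, 3)                      # min(4, k-1)
  expect_true(all(diff(proj$eigenvalues) <= 1e-9))
  expect_true(all(proj$eigenvalues >= 0))
  # unit within-group variance of scores on every axis
  expect_equal(unname(diag(t(proj$axes) %*% W %*% proj$axes)), rep(1, 4),
               tolerance = 1e-9)
  # centroid distances in the full canonical space equal Mahalanobis D2
  D2 <- mahalanobis_matrix(summ, W)
  scores <- proj$species_scores
  expect_equal(unname(as.matrix(dist(scores))^2), unname(D2),
               tolerance = 1e-8)

  # two groups: exactly one non-null axis; identical means: null axes
  sp2 <- make_specimens(means[1:2, ], 10)
  p2 <- dfa_project(sp2)
  expect_equal(p2$n_axes, 1)
  expect_lt(p2$eigenvalues[2] / max(p2$eigenvalues[1], 1), 1e-8)

  # exactly identical group means (residuals centred within groups):
  # every eigenvalue collapses to zero
  same <- do.call(rbind, lapply(c("x", "y", "z"), function(g) {
    r <- scale(matrix(rnorm(40), 10, 4), center = TRUE, scale = FALSE)
    vals <- sweep(r, 2, means[1, ], `+`)
    colnames(vals) <- c("cap_len_mm", "cap_wid_mm", "leaf_len_mm",
                        "leaf_wid_mm")
    data.frame(specimen = paste0(g, 1:10), species = g, vals)
  }))
  p3 <- dfa_project(same)
  expect_lt(max(p3$eigenvalues), 1e-9)
})

test_that("DFA agrees with the canonical analysis in MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(31)
  means <- matrix(rnorm(12, 10, 3), 3, 4,
                  dimnames = list(c("a", "b", "c"), NULL))
  sp <- make_specimens(means, 25, diag(4) * 0.5)
  proj <- dfa_project(sp)
  fit <- MASS::lda(as.matrix(sp[, 3:6]), grouping = sp$species)
  got <- abs(proj$axes[, 1:2])
  # MASS normalises by the within SD with its own (N - k) scaling; axes
  # must agree up to sign
  want <- abs(fit$scaling[, 1:2])
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})
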