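# Clade-level contrasts: within-clade pairwise values (range overlaps or
# Mahalanobis distances), pooled-variance t statistics and a species-label
# permutation null. Pair values sharing a species are not independent,
# which is why the permutation shuffles species labels, never pairs.

#' Read a clade assignment CSV
#'
#' @param path CSV with columns species and clade.
#' @return named character vector mapping species to clade label.
#' @export
read_clades <- function(path) {
  if (!file.exists(path)) stop("clade file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$species) || is.null(df$clade))
    stop("clade CSV needs columns species and clade")
  if (anyDuplicated(df$species))
    stop("species assigned to more than one clade: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  stats::setNames(as.character(df$clade), df$species)
}

#' Within-clade pairwise values from a symmetric matrix
#'
#' The C(n, 2) upper-triangle values among the species carrying a clade
#' label, in the deterministic order of the matrix rows.
#'
#' @param M symmetric matrix with species dimnames (overlap proportions or
#'   squared Mahalanobis distances).
#' @param clades named vector mapping species to clade labels.
#' @param label the clade to extract.
#' @return numeric vector of length choose(n, 2).
#' @export
within_clade_pairs <- function(M, clades, label) {
  sp <- intersect(rownames(M), names(clades)[clades == label])
  if (length(sp) < 2L)
    stop("clade '", label, "' has fewer than 2 species in the matrix")
  sub <- M[sp, sp, drop = FALSE]
  sub[upper.tri(sub)]
}

# pooled-variance t statistic; returns NA when the pooled variance is zero
pooled_t_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Pooled-variance two-sample t test on pairwise values
#'
#' Student's t with pooled variance and df = n1 + n2 - 2, two-sided. This
#' is the parametric contrast applied to within-clade overlap or distance
#' values (for two clades of 6 and 4 species the 15 and 6 pairwise values
#' give df = 19).
#'
#' @param a,b numeric vectors of pairwise values for the two clades.
#' @param statistic_name label carried into the result.
#' @return object of class \code{clade_comparison}: list with
#'   statistic_name, group_values, t, df, p_parametric, p_permutation (NA
#'   until [permutation_test()] fills it), n_permutations, seed.
#' @export
two_sample_t <- function(a, b, statistic_name = "pairwise value") {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least two values")
  t_obs <- pooled_t_stat(a, b)
  if (is.na(t_obs))
    stop("pooled variance is zero; the t statistic is undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(statistic_name = statistic_name,
                 group_values = list(a = a, b = b),
                 t = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_parametric = ht$p.value,
                 p_permutation = NA_real_,
                 n_permutations = 0L,
                 seed = NA_integer_),
            class = "clade_comparison")
}

#' @export
print.clade_comparison <- function(x, ...) {
  cat("Clade contrast on ", x$statistic_name, "\n",
      "  n = ", length(x$group_values$a), " vs ", length(x$group_values$b),
      " pairwise values\n",
      sprintf("  t = %.4f, df = %d, parametric P = %.4g\n",
              x$t, as.integer(x$df), x$p_parametric), sep = "")
  if (!is.na(x$p_permutation))
    cat(sprintf("  permutation P = %.4g (%d permutations, seed %d)\n",
                x$p_permutation, x$n_permutations, x$seed))
  invisible(x)
}

#' Species-label permutation test for a clade contrast
#'
#' The observed statistic is the pooled-variance t on the two sets of
#' within-clade pairwise values. The null is built by randomly permuting
#' clade labels across species (clade sizes preserved), recomputing the
#' within-clade pairwise values and the t statistic for each draw;
#' permuting species rather than pairs respects the non-independence of
#' pairs that share a species. Empirical two-sided
#' p = (1 + #\{|t*| >= |t_obs|\}) / (1 + n_permutations). Draws whose
#' permuted statistic is undefined (zero pooled variance) are redrawn, up
#' to 100 * n_permutations attempts.
#'
#' @param M symmetric matrix with species dimnames.
#' @param clades named species-to-clade vector with exactly two labels
#'   among the matrix species.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed integer seed recorded in the result.
#' @param statistic_name label carried into the result.
#' @return a \code{clade_comparison} with the permutation p filled in.
#' @export
permutation_test <- function(M, clades, n_permutations = 9999L, seed = 1L,
                             statistic_name = "pairwise value") {
  if (n_permutations < 99L) stop("use at least 99 permutations")
  clades <- clades[intersect(rownames(M), names(clades))]
  labs <- unique(clades)
  if (length(labs) != 2L)
    stop("permutation_test needs exactly two clade labels, got: ",
         paste(labs, collapse = ", "))
  sp <- names(clades)
  a_obs <- within_clade_pairs(M, clades, labs[1L])
  b_obs <- within_clade_pairs(M, clades, labs[2L])
  res <- two_sample_t(a_obs, b_obs, statistic_name)
  t_obs <- res$t
  set.seed(seed)
  exceed <- 0L
  done <- 0L
  attempts <- 0L
  max_attempts <- 100L * n_permutations
  while (done < n_permutations && attempts < max_attempts) {
    attempts <- attempts + 1L
    perm <- stats::setNames(sample(unname(clades)), sp)
    a <- within_clade_pairs(M, perm, labs[1L])
    b <- within_clade_pairs(M, perm, labs[2L])
    t_star <- pooled_t_stat(a, b)
    if (is.na(t_star)) next
    done <- done + 1L
    if (abs(t_star) >= abs(t_obs) - 1e-12) exceed <- exceed + 1L
  }
  if (done < n_permutations)
    stop("could not complete ", n_permutations, " valid permutations ",
         "(too many zero-variance draws)")
  res$p_permutation <- (1 + exceed) / (1 + n_permutations)
  res$n_permutations <- as.integer(n_permutations)
  res$seed <- as.integer(seed)
  res
}

#' Write clade-contrast results
#'
#' A tidy CSV (one row per contrast) and a short human-readable report.
#'
#' @param results list of \code{clade_comparison} objects.
#' @param csv_path,report_path output paths.
#' @export
write_comparisons <- function(results, csv_path, report_path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(statistic = r$statistic_name,
               n_a = length(r$group_values$a), n_b = length(r$group_values$b),
               mean_a = mean(r$group_values$a), mean_b = mean(r$group_values$b),
               t = r$t, df = r$df, p_parametric = r$p_parametric,
               p_permutation = r$p_permutation,
               n_permutations = r$n_permutations, seed = r$seed)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  con <- file(report_path, "w")
  on.exit(close(con))
  writeLines("Clade contrasts (pooled-variance t, species-label permutation null)", con)
  for (r in results) {
    writeLines(sprintf(
      "%s: mean %s = %.4g vs %.4g; t = %.4f, df = %d, parametric P = %.4g%s",
      r$statistic_name, "A/B", mean(r$group_values$a), mean(r$group_values$b),
      r$t, as.integer(r$df), r$p_parametric,
      if (is.na(r$p_permutation)) "" else
        sprintf(", permutation P = %.4g (B = %d, seed %d)",
                r$p_permutation, r$n_permutations, r$seed)), con)
  }
  invisible(rows)
}
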