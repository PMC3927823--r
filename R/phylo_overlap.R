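#' Read a dated tree from a newick file
#'
#' Parses a newick tree with branch lengths (via \pkg{ape}) and validates
#' it as a dated species tree: unique tip labels, branch lengths present.
#' Node ages are measured from the present as max tip depth minus node
#' depth; non-ultrametric trees are accepted with a warning under that
#' convention. Polytomies are resolved into a caterpillar of zero-length
#' edges (warning), since the nested-overlap recursion is defined for
#' binary nodes.
#'
#' @param path newick file path; alternatively pass the newick string via
#'   \code{text}.
#' @param text optional newick string (overrides \code{path}).
#' @return an \pkg{ape} \code{phylo} object.
#' @export
read_dated_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
  else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse newick tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a dated tree is required")
  if (any(tabulate(tree$edge[, 1L]) > 2L)) {
    warning("tree contains polytomies; resolving into a caterpillar of ",
            "zero-length edges")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(ape::Ntip(tree))]
  if (diff(range(tipd)) > 1e-6 * max(tipd, 1))
    warning("tree is not ultrametric; node ages taken as max tip depth ",
            "minus node depth")
  tree
}

#' Node ages of a dated tree
#'
#' Ages in time units before the present for every node (tips first, then
#' internal nodes, in \pkg{ape} numbering): max root-to-tip path length
#' minus the node's depth.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @return numeric vector of length \code{Ntip + Nnode}.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Trim a tree to a set of species
#'
#' Induced subtree on \code{keep}: other tips are dropped and unary nodes
#' suppressed, preserving node ages (path lengths are additive under
#' pruning). Used to reduce a multi-accession tree to one tip per species.
#'
#' @param tree a \code{phylo} object.
#' @param keep character vector of tip labels to retain.
#' @return the pruned \code{phylo} object.
#' @export
trim_to_species <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least two tips after trimming")
  ape::keep.tip(tree, keep)
}

# children of an internal node (ape numbering)
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

#' Nested average of range overlaps below a node
#'
#' For an internal node with daughter clades L and R the nested overlap is
#' O(L, R), defined recursively on clade pairs: for two tips it is the
#' pairwise overlap M[x, y]; for a clade with daughters X1, X2 it is the
#' plain average (O(X1, .) + O(X2, .)) / 2. Each daughter clade therefore
#' contributes equally at every level, which down-weights a tip by 1/2 per
#' internal node between it and its clade root.
#'
#' @param tree a binary \code{phylo} object.
#' @param node internal node number (ape numbering; the root is
#'   \code{Ntip + 1}).
#' @param M symmetric overlap matrix with species ids as dimnames covering
#'   all descendant tips.
#' @return nested overlap proportion in [0, 1].
#' @export
nested_overlap <- function(tree, node, M) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) stop("nested_overlap is defined for internal nodes only")
  kids <- node_children(tree, node)
  tips_below <- function(n) {
    if (n <= ntip) return(tree$tip.label[n])
    unlist(lapply(node_children(tree, n), tips_below))
  }
  needed <- unique(unlist(lapply(kids, tips_below)))
  miss <- setdiff(needed, rownames(M))
  if (length(miss))
    stop("species missing from overlap matrix: ", paste(miss, collapse = ", "))
  ov <- function(x, y) {
    if (x <= ntip && y <= ntip)
      return(M[tree$tip.label[x], tree$tip.label[y]])
    if (x > ntip) {
      cx <- node_children(tree, x)
      return((ov(cx[1L], y) + ov(cx[2L], y)) / 2)
    }
    cy <- node_children(tree, y)
    (ov(x, cy[1L]) + ov(x, cy[2L])) / 2
  }
  ov(kids[1L], kids[2L])
}

# deterministic node ids: rank of each internal node in a depth-first
# post-order traversal from the root
postorder_ids <- function(tree) {
  ntip <- ape::Ntip(tree)
  order <- integer(0)
  walk <- function(n) {
    if (n > ntip) for (k in node_children(tree, n)) walk(k)
    if (n > ntip) order <<- c(order, n)
  }
  walk(ntip + 1L)
  ids <- setNames(paste0("n", seq_along(order)), order)
  ids
}

#' Age-range-correlation table
#'
#' One record per internal node: node id (post-order index), node age, and
#' the nested average of range overlaps between its two daughter clades,
#' ordered by decreasing age. A descriptive ordinary-least-squares fit of
#' nested overlap on age is attached as attribute \code{ols}
#' (slope, intercept, r.squared).
#'
#' @param tree a binary \code{phylo} object whose tips match the matrix.
#' @param M symmetric overlap matrix with species dimnames.
#' @return data.frame with columns node_id, age_ma, nested_overlap.
#' @export
arc_table <- function(tree, M) {
  extra_tree <- setdiff(tree$tip.label, rownames(M))
  extra_mat <- setdiff(rownames(M), tree$tip.label)
  if (length(extra_tree) || length(extra_mat))
    stop("tree/matrix species mismatch; in tree only: ",
         paste(extra_tree, collapse = ", "), "; in matrix only: ",
         paste(extra_mat, collapse = ", "))
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  internal <- ntip + seq_len(tree$Nnode)
  ids <- postorder_ids(tree)
  out <- data.frame(
    node_id = unname(ids[as.character(internal)]),
    age_ma = ages[internal],
    nested_overlap = vapply(internal, function(n) nested_overlap(tree, n, M),
                            numeric(1))
  )
  out <- out[order(-out$age_ma), ]
  rownames(out) <- NULL
  # degenerate (constant) overlap vectors make the fit exact; that is a
  # legitimate input here, so the perfect-fit warning is suppressed
  fit <- stats::lm(nested_overlap ~ age_ma, data = out)
  attr(out, "ols") <- c(slope = unname(stats::coef(fit)[2L]),
                        intercept = unname(stats::coef(fit)[1L]),
                        r.squared = suppressWarnings(summary(fit)$r.squared))
  out
}
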