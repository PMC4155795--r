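## Morphometric validation surface: per-tree features and robust population
## summaries (median / MAD / IQR), mirroring how generated populations are
## compared against reconstructed archives.
##
## Conventions (frozen; see the methods vignette):
##   - the soma is order 0; stems are order 1; order increments only at
##     branch points passed on the way out;
##   - a multifurcating soma is NOT a branch point (its children are stems);
##   - MAD is unscaled (no normal-consistency factor);
##   - quartiles use linear interpolation of order statistics (R type 7).

tree_nodes <- function(tree) {
  stopifnot(is.data.frame(tree),
            all(c("id", "type", "x", "y", "z", "radius", "parent")
                %in% names(tree)))
  tree
}

tree_root <- function(tree) {
  r <- which(tree$parent == -1L)
  if (length(r) != 1L) stop("structure error: tree must have exactly one root")
  r
}

tree_children <- function(tree) {
  kids <- vector("list", nrow(tree))
  for (i in seq_len(nrow(tree))) {
    p <- tree$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

## Subset a tree to the component whose stem nodes have one of the given
## SWC type codes (3 basal, 4 apical); the soma is kept as root.
subtree_by_type <- function(tree, types) {
  keep <- tree$type %in% c(1L, types)
  sub <- tree[keep, , drop = FALSE]
  old2new <- integer(nrow(tree))
  old2new[which(keep)] <- seq_len(nrow(sub))
  sub$parent <- ifelse(sub$parent > 0L, old2new[pmax(sub$parent, 1L)], -1L)
  if (any(sub$parent == 0L))
    stop("structure error: type-filtered subtree is disconnected")
  sub$id <- seq_len(nrow(sub))
  class(sub) <- class(tree)
  sub
}

#' Number of branch points in a tree
#'
#' Nodes with two or more children, excluding the soma: a multifurcating
#' soma makes stems, not branch points.
#'
#' @param tree an SWC-style node table (`arbor_tree` or data.frame with
#'   columns id, type, x, y, z, radius, parent).
#' @return integer count.
#' @export
branch_points <- function(tree) {
  tree <- tree_nodes(tree)
  root <- tree_root(tree)
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = nrow(tree))
  sum(deg >= 2L & seq_len(nrow(tree)) != root)
}

#' Euclidean soma-to-tip distances
#'
#' Straight-line distance between the soma and every terminal point.
#'
#' @param tree an SWC-style node table.
#' @return numeric vector, um (empty for a bare soma).
#' @export
tip_euclidean_distances <- function(tree) {
  tree <- tree_nodes(tree)
  root <- tree_root(tree)
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = nrow(tree))
  tips <- which(deg == 0L & seq_len(nrow(tree)) != root)
  if (length(tips) == 0L) return(numeric(0))
  sqrt((tree$x[tips] - tree$x[root])^2 + (tree$y[tips] - tree$y[root])^2 +
       (tree$z[tips] - tree$z[root])^2)
}

#' Total dendritic length
#'
#' Sum of parent-child Euclidean segment lengths, soma-to-stem segments
#' included.
#'
#' @param tree an SWC-style node table.
#' @return length in um.
#' @export
total_length <- function(tree) {
  tree <- tree_nodes(tree)
  has_p <- tree$parent > 0L
  p <- tree$parent[has_p]
  sum(sqrt((tree$x[has_p] - tree$x[p])^2 + (tree$y[has_p] - tree$y[p])^2 +
           (tree$z[has_p] - tree$z[p])^2))
}

## Centrifugal order of every node: soma 0, stems 1, +1 below each branch
## point.
node_orders <- function(tree) {
  tree <- tree_nodes(tree)
  root <- tree_root(tree)
  n <- nrow(tree)
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = n)
  ord <- integer(n)
  kids <- tree_children(tree)
  stack <- kids[[root]]
  ord[stack] <- 1L
  while (length(stack)) {
    cur <- stack[1L]; stack <- stack[-1L]
    ch <- kids[[cur]]
    if (length(ch)) {
      ord[ch] <- ord[cur] + (if (deg[cur] >= 2L) 1L else 0L)
      stack <- c(ch, stack)
    }
  }
  ord
}

#' Centrifugal orders of branch points, and the maximum order
#'
#' Orders follow the soma-0 / stems-1 convention, incrementing below each
#' branch point. `max_order` is the maximum over all nodes (tips included).
#'
#' @param tree an SWC-style node table.
#' @return list with `branch_point_orders` and `max_order`.
#' @export
orders <- function(tree) {
  tree <- tree_nodes(tree)
  root <- tree_root(tree)
  n <- nrow(tree)
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = n)
  ord <- node_orders(tree)
  bp <- which(deg >= 2L & seq_len(n) != root)
  list(branch_point_orders = ord[bp],
       max_order = if (n > 1L) max(ord) else 0L)
}

#' Sholl-like branch-point profile
#'
#' Euclidean soma distance of every branch point, plus a histogram of those
#' distances over `[0, max)` with the given bin width. The sample size
#' always equals [branch_points()].
#'
#' @param tree an SWC-style node table.
#' @param bin_width histogram bin width, um.
#' @return list with `distances` and `histogram` (counts named by bin
#'   lower edge).
#' @export
sholl_like <- function(tree, bin_width = 50) {
  if (bin_width <= 0) stop("sholl_like: bin_width must be > 0")
  tree <- tree_nodes(tree)
  root <- tree_root(tree)
  deg <- tabulate(tree$parent[tree$parent > 0L], nbins = nrow(tree))
  bp <- which(deg >= 2L & seq_len(nrow(tree)) != root)
  d <- sqrt((tree$x[bp] - tree$x[root])^2 + (tree$y[bp] - tree$y[root])^2 +
            (tree$z[bp] - tree$z[root])^2)
  if (length(d) == 0L)
    return(list(distances = numeric(0), histogram = integer(0)))
  edges <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  h <- tabulate(findInterval(d, edges), nbins = length(edges) - 1L)
  names(h) <- edges[-length(edges)]
  list(distances = d, histogram = h)
}

#' Robust summary of a morphometric sample
#'
#' Median (M), unscaled median absolute deviation (MAD =
#' `median(|x - M|)`), and interquartile range (IQR, quartiles by linear
#' interpolation of order statistics).
#'
#' @param samples numeric vector, n >= 1.
#' @return list of class `arbor_summary`: `M`, `MAD`, `IQR`, `n`.
#' @export
summarize <- function(samples) {
  if (length(samples) < 1L) stop("summarize: empty sample")
  M <- median(samples)
  q <- quantile(samples, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(M = M, MAD = median(abs(samples - M)),
                 IQR = q[2L] - q[1L], n = length(samples)),
            class = "arbor_summary")
}

#' @export
print.arbor_summary <- function(x, ...) {
  cat(sprintf("M %.4g  MAD %.4g  IQR %.4g  (n = %d)\n",
              x$M, x$MAD, x$IQR, x$n))
  invisible(x)
}

#' Population morphometrics table
#'
#' One M/MAD/IQR row per feature over a population of trees. Count and
#' length features are per-tree samples; "order" and "sholl" pool every
#' branch point of every tree, and "euclidean" pools every tip.
#' With `split_types = TRUE`, basal (type 3) and apical (type 4) trees are
#' summarized separately.
#'
#' @param trees list of SWC-style node tables.
#' @param features character subset of c("branch_points", "euclidean",
#'   "max_order", "order", "sholl", "total_length").
#' @param split_types summarize basal/apical subtrees separately.
#' @return data.frame with columns feature (, compartment), M, MAD, IQR, n.
#' @export
population_summary <- function(trees,
                               features = c("branch_points", "euclidean",
                                            "max_order", "order", "sholl",
                                            "total_length"),
                               split_types = FALSE) {
  if (length(trees) == 0L) stop("population_summary: at least one tree")
  features <- match.arg(features, several.ok = TRUE)
  one_block <- function(trees, label) {
    rows <- lapply(features, function(f) {
      samples <- switch(f,
        branch_points = vapply(trees, branch_points, 0),
        euclidean = unlist(lapply(trees, tip_euclidean_distances)),
        max_order = vapply(trees, function(t) orders(t)$max_order, 0),
        order = unlist(lapply(trees,
                              function(t) orders(t)$branch_point_orders)),
        sholl = unlist(lapply(trees, function(t) sholl_like(t)$distances)),
        total_length = vapply(trees, total_length, 0))
      if (length(samples) == 0L)
        return(data.frame(feature = f, compartment = label, M = NA_real_,
                          MAD = NA_real_, IQR = NA_real_, n = 0L))
      s <- summarize(samples)
      data.frame(feature = f, compartment = label, M = s$M, MAD = s$MAD,
                 IQR = s$IQR, n = s$n)
    })
    do.call(rbind, rows)
  }
  if (!split_types) {
    out <- one_block(trees, "all")
  } else {
    has_types <- vapply(trees, function(t) any(t$type == 3L) ||
                                           any(t$type == 4L), TRUE)
    if (!all(has_types))
      stop("population_summary: trees lack basal/apical type tags")
    out <- rbind(
      one_block(lapply(trees, subtree_by_type, types = 4L), "apical"),
      one_block(lapply(trees, subtree_by_type, types = 3L), "basal"))
  }
  rownames(out) <- NULL
  out
}
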