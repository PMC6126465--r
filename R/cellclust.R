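#' Linear Cell Variation of a set of unit cells
#'
#' The LCV/aLCV pair scores how non-isomorphous a group of crystals is,
#' using only their unit cells. For every cell the three longest face
#' diagonals are computed ([face_diagonals()]); the absolute score aLCV is
#' the largest pairwise difference of matching diagonals over the group (in
#' Angstrom) and LCV expresses the same worst pair as a percentage of the
#' smaller diagonal. Experience places the onset of problematic
#' non-isomorphism around LCV values above 2 %.
#'
#' @param cells List of [unit_cell()]s (or 6-vectors). A single cell returns
#'   `c(lcv = 0, alcv = 0)` by convention.
#' @return Named numeric vector `c(lcv = <percent>, alcv = <Angstrom>)`.
#' @export
cluster_metrics <- function(cells) {
  if (length(cells) < 2) return(c(lcv = 0, alcv = 0))
  D <- t(vapply(cells, function(cl) face_diagonals(as_unit_cell(cl)), numeric(3)))
  lcv <- 0; alcv <- 0
  for (f in 1:3) {
    d <- D[, f]
    dif <- abs(outer(d, d, "-"))
    mn <- outer(d, d, pmin)
    alcv <- max(alcv, max(dif))
    lcv <- max(lcv, max(100 * dif / mn))
  }
  c(lcv = lcv, alcv = alcv)
}

#' Hierarchical clustering of datasets on unit-cell parameters
#'
#' Each dataset is described by its six cell parameters, standardised
#' component-wise to zero mean and unit variance across the input (constant
#' components are left at zero), and clustered agglomeratively with Ward
#' linkage on Euclidean distances. Every internal node is annotated with the
#' LCV/aLCV of its members' raw (unstandardised) cells, so the tree can be
#' read directly as an isomorphism map: low-aLCV nodes are safe to merge.
#'
#' Node ids continue the leaf numbering: leaves carry the dataset serials
#' 1..n and internal nodes are numbered n+1..2n-1 in merge order (so the
#' root is node 2n-1). `merge_level` is the number of datasets in the node
#' minus one: all two-dataset clusters sit at level 1, all three-dataset
#' clusters at level 2, and so on — the layout used by
#' [plot_merging_levels()].
#'
#' @param datasets List of >= 2 [unmerged_dataset()]s with unique serials
#'   (a list of bare [unit_cell()]s is also accepted, serials 1..n implied).
#' @return An object of class `cell_dendrogram`: list with `n_leaves`,
#'   `serials`, `cells`, `hclust` (the underlying [stats::hclust] object)
#'   and `nodes`, a `data.frame` with one row per internal node
#'   (`node_id`, `height`, `lcv`, `alcv`, `merge_level`, `child1`, `child2`,
#'   and list-column `members`).
#' @export
build_dendrogram <- function(datasets) {
  if (length(datasets) < 2) stop("clustering needs at least 2 datasets")
  if (inherits(datasets[[1]], "unmerged_dataset")) {
    cells <- lapply(datasets, `[[`, "cell")
    serials <- vapply(datasets, `[[`, integer(1), "serial")
  } else {
    cells <- lapply(datasets, as_unit_cell)
    serials <- seq_along(cells)
  }
  if (anyNA(serials) || anyDuplicated(serials)) {
    stop("datasets must carry unique, non-missing serials")
  }
  n <- length(cells)
  M <- t(vapply(cells, as.numeric, numeric(6)))
  Z <- apply(M, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  hc <- stats::hclust(stats::dist(Z, method = "euclidean"), method = "ward.D2")
  ord <- order(serials)  # hclust leaves are in input order; relabel to serials
  # members per internal node, following the hclust merge matrix convention:
  # negative entries are leaves (input row index), positive are earlier merges
  members <- vector("list", n - 1)
  child_id <- function(x) if (x < 0) serials[-x] else n + x
  nodes <- data.frame(node_id = integer(n - 1), height = numeric(n - 1),
                      lcv = numeric(n - 1), alcv = numeric(n - 1),
                      merge_level = integer(n - 1),
                      child1 = integer(n - 1), child2 = integer(n - 1))
  for (i in seq_len(n - 1)) {
    take <- function(x) if (x < 0) serials[-x] else members[[x]]
    mem <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
    members[[i]] <- mem
    met <- cluster_metrics(cells[match(mem, serials)])
    ch <- sort(c(child_id(hc$merge[i, 1]), child_id(hc$merge[i, 2])))
    nodes[i, ] <- list(n + i, hc$height[i], met[["lcv"]], met[["alcv"]],
                       length(mem) - 1L, ch[1], ch[2])
  }
  nodes$members <- members
  structure(list(n_leaves = n, serials = serials, cells = cells,
                 hclust = hc, nodes = nodes),
            class = "cell_dendrogram")
}

#' @export
print.cell_dendrogram <- function(x, ...) {
  root <- x$nodes[nrow(x$nodes), ]
  cat(sprintf("cell dendrogram: %d datasets, %d nodes; root height %.3f, LCV %.2f %%, aLCV %.2f A\n",
              x$n_leaves, nrow(x$nodes), root$height, root$lcv, root$alcv))
  invisible(x)
}

node_members <- function(dendro, node_id) {
  if (node_id <= dendro$n_leaves) {
    if (!node_id %in% dendro$serials) stop("unknown leaf serial: ", node_id)
    return(node_id)
  }
  i <- match(node_id, dendro$nodes$node_id)
  if (is.na(i)) stop("unknown cluster node: ", node_id)
  dendro$nodes$members[[i]]
}

#' Select dendrogram nodes below a threshold
#'
#' In `height` mode every internal node whose merge height is at or below
#' the threshold is returned (a threshold above the root height therefore
#' selects all n-1 nodes); in `alcv` mode the criterion is the node's aLCV
#' in Angstrom, the natural choice when a target resolution suggests how
#' much absolute cell variation is tolerable.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param mode `"height"` or `"alcv"`.
#' @param threshold Positive cut value.
#' @return Subset of `dendro$nodes` (possibly 0 rows), sorted by `node_id`.
#' @export
cut_tree <- function(dendro, mode = c("height", "alcv"), threshold) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), threshold > 0)
  keep <- switch(mode,
                 height = dendro$nodes$height <= threshold,
                 alcv = dendro$nodes$alcv <= threshold)
  out <- dendro$nodes[keep, , drop = FALSE]
  out[order(out$node_id), , drop = FALSE]
}

#' Flag cell-parameter outlier datasets
#'
#' Advisory helper for the common situation where a few mis-indexed or
#' foreign crystals inflate the whole tree's LCV. Offending clusters are
#' peeled greedily, smallest first: while the survivors' LCV exceeds
#' `lcv_threshold`, the tree is rebuilt on the survivors and the root's
#' smaller child branch (on a tie, the one whose removal lowers the LCV
#' more) is flagged whole. Nothing is deleted: the caller is expected to
#' edit the input list and re-run, keeping the human in the loop.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param lcv_threshold Percent; the conventional non-isomorphism alarm
#'   level of 2 % by default.
#' @return Integer vector of flagged serials (possibly empty).
#' @export
flag_outliers <- function(dendro, lcv_threshold = 2) {
  serials <- dendro$serials
  cells <- dendro$cells
  flagged <- integer(0)
  keep <- rep(TRUE, length(serials))
  repeat {
    if (sum(keep) < 2) break
    if (cluster_metrics(cells[keep])[["lcv"]] <= lcv_threshold) break
    sub <- build_dendrogram(cells[keep])  # leaf i of the subtree = i-th kept serial
    kept_serials <- serials[keep]
    nd <- sub$nodes
    root <- nd[nrow(nd), ]
    branch <- function(id) {
      if (id <= sub$n_leaves) id else nd$members[[match(id, nd$node_id)]]
    }
    A <- kept_serials[branch(root$child1)]
    B <- kept_serials[branch(root$child2)]
    drop <- if (length(A) != length(B)) {
      if (length(A) < length(B)) A else B
    } else {
      lcv_wo <- function(set) cluster_metrics(cells[keep & !serials %in% set])[["lcv"]]
      if (lcv_wo(A) <= lcv_wo(B)) A else B
    }
    keep[serials %in% drop] <- FALSE
    flagged <- c(flagged, drop)
  }
  sort(flagged)
}

#' Write the per-node cluster table
#'
#' One row per internal node: node id, merge height, LCV (percent), aLCV
#' (Angstrom) and the member dataset serials in ascending order. This is
#' the file consulted to pick a synthesis threshold (e.g. a height just
#' above the root's merges everything).
#'
#' @param dendro A [build_dendrogram()] result.
#' @param path Output file, conventionally `CLUSTERS.txt`.
#' @return `path`, invisibly.
#' @export
write_clusters_file <- function(dendro, path) {
  nd <- dendro$nodes
  hdr <- sprintf("%-8s %-10s %-9s %-9s %s", "Cluster", "Height", "LCV", "aLCV", "Datasets")
  rows <- vapply(seq_len(nrow(nd)), function(i) {
    sprintf("%-8d %-10.3f %-9.3f %-9.3f %s", nd$node_id[i], nd$height[i],
            nd$lcv[i], nd$alcv[i], paste(nd$members[[i]], collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_clusters_file <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(node_id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
             height = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
             lcv = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
             alcv = vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
             members = I(lapply(parts, function(p) as.integer(p[-(1:4)]))))
}
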