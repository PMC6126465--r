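open_png <- function(path, width = 1200, height = 800) {
  grDevices::png(path, width = width, height = height, res = 120,
                 type = if (capabilities("cairo")) "cairo" else NULL)
}

#' Plot the annotated cell dendrogram
#'
#' Draws the full clustering tree with the top `annotate_top` clusters (by
#' merge height) labelled "LCV (aLCV)" in red, the quickest visual check of
#' how isomorphous the collection is.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param annotate_top Number of highest clusters to annotate (default 5).
#' @param path Output PNG path.
#' @param formats Additional formats: any of `"ps"`, `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
plot_dendrogram <- function(dendro, annotate_top = 5, path = "dendrogram.png",
                            formats = character(0)) {
  draw <- function() {
    hc <- dendro$hclust
    hc$labels <- as.character(dendro$serials)
    graphics::plot(hc, main = "Cell-parameter clustering",
                   xlab = "dataset serial", ylab = "merge height", sub = "")
    nd <- dendro$nodes
    top <- nd[order(-nd$height), ][seq_len(min(annotate_top, nrow(nd))), ]
    # x position of an internal node: mean leaf order position of members
    leaf_x <- stats::setNames(seq_along(hc$order), dendro$serials[hc$order])
    for (i in seq_len(nrow(top))) {
      x <- mean(leaf_x[as.character(top$members[[i]])])
      graphics::text(x, top$height[i],
                     sprintf("%.2f (%.2f)", top$lcv[i], top$alcv[i]),
                     col = "red", pos = 3, cex = 0.9, xpd = NA)
    }
  }
  render_plot(draw, path, formats)
}

render_plot <- function(draw, path, formats) {
  open_png(path)
  draw()
  grDevices::dev.off()
  written <- path
  base <- tools::file_path_sans_ext(path)
  if ("ps" %in% formats) {
    f <- paste0(base, ".ps")
    grDevices::postscript(f, width = 10, height = 7)
    draw(); grDevices::dev.off()
    written <- c(written, f)
  }
  if ("svg" %in% formats && capabilities("cairo")) {
    f <- paste0(base, ".svg")
    grDevices::svg(f, width = 10, height = 7)
    draw(); grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}

#' Plot clusters at their merging level
#'
#' Alternative dendrogram layout in which every node is drawn as a box at
#' its merging level — all two-dataset clusters on the lowest level, all
#' three-dataset clusters on the next, and so on — annotated with the
#' node id and aLCV. Useful when merge heights compress visually.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param path Output PNG path.
#' @param formats Additional formats (`"ps"`, `"svg"`).
#' @return Files written, invisibly.
#' @export
plot_merging_levels <- function(dendro, path = "merging_levels.png",
                                formats = character(0)) {
  draw <- function() {
    hc <- dendro$hclust
    nd <- dendro$nodes
    leaf_x <- stats::setNames(seq_along(hc$order), dendro$serials[hc$order])
    xs <- vapply(nd$members, function(m) mean(leaf_x[as.character(m)]), numeric(1))
    ys <- nd$merge_level
    graphics::plot(NA, xlim = range(c(leaf_x, xs)) + c(-0.5, 0.5),
                   ylim = c(-0.5, max(ys) + 0.7),
                   xlab = "dataset serial", ylab = "merging level",
                   main = "Clusters by merging level", xaxt = "n")
    graphics::axis(1, at = unname(leaf_x), labels = names(leaf_x), cex.axis = 0.7)
    # connect each node to its children
    pos <- rbind(data.frame(id = dendro$serials, x = unname(leaf_x[as.character(dendro$serials)]), y = 0),
                 data.frame(id = nd$node_id, x = xs, y = ys))
    for (i in seq_len(nrow(nd))) {
      for (ch in c(nd$child1[i], nd$child2[i])) {
        j <- match(ch, pos$id)
        graphics::segments(xs[i], ys[i], pos$x[j], pos$y[j], col = "grey60")
      }
    }
    graphics::rect(xs - 0.45, ys - 0.18, xs + 0.45, ys + 0.18,
                   col = "grey85", border = "grey40")
    graphics::text(xs, ys, sprintf("%d\n%.2f", nd$node_id, nd$alcv), cex = 0.6)
    graphics::points(unname(leaf_x), rep(0, length(leaf_x)), pch = 20)
  }
  render_plot(draw, path, formats)
}

#' Plot an annotated subtree around one cluster
#'
#' Draws the subtree rooted at `node_id`, truncated `levels` merge
#' generations down, each displayed node annotated with any statistics
#' available for it (completeness, R_meas, CC1/2 resolution) from
#' synthesis or combination results. Output goes under a `graphics/`
#' directory as `tree_<node>_<levels>.png`.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param node_id Internal node to focus on (a leaf id is an error).
#' @param levels Number of merge generations to display (>= 1).
#' @param annotations Optional `data.frame` with columns `node_id`,
#'   `completeness`, `r_meas`, `res_cc` (see [annotation_table()]).
#' @param dir Output directory (default `"graphics"`, created if needed).
#' @param formats Additional formats (`"ps"`, `"svg"`).
#' @return Files written, invisibly.
#' @export
plot_subtree <- function(dendro, node_id, levels, annotations = NULL,
                         dir = "graphics", formats = character(0)) {
  nd <- dendro$nodes
  if (!node_id %in% nd$node_id) {
    stop("node ", node_id, " is not an internal cluster of the dendrogram")
  }
  stopifnot(levels >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # collect displayed nodes breadth-first down to `levels` generations
  shown <- list(); frontier <- data.frame(id = node_id, gen = 0)
  while (nrow(frontier)) {
    shown[[length(shown) + 1L]] <- frontier
    nxt <- do.call(rbind, lapply(seq_len(nrow(frontier)), function(i) {
      id <- frontier$id[i]; gen <- frontier$gen[i]
      if (gen >= levels || !id %in% nd$node_id) return(NULL)
      r <- nd[match(id, nd$node_id), ]
      data.frame(id = c(r$child1, r$child2), gen = gen + 1)
    }))
    frontier <- if (is.null(nxt)) frontier[0, ] else nxt
  }
  shown <- unique(do.call(rbind, shown))
  draw <- function() {
    ids <- shown$id
    is_node <- ids %in% nd$node_id
    hc <- dendro$hclust
    leaf_x <- stats::setNames(seq_along(hc$order), dendro$serials[hc$order])
    xx <- vapply(ids, function(id) {
      mean(leaf_x[as.character(node_members(dendro, id))])
    }, numeric(1))
    yy <- max(shown$gen) - shown$gen
    graphics::plot(NA, xlim = range(xx) + c(-1, 1), ylim = c(-0.6, max(yy) + 0.6),
                   xlab = "", ylab = "generations below focus", yaxt = "n", xaxt = "n",
                   main = sprintf("Subtree of cluster %d (%d levels)", node_id, levels))
    for (i in seq_len(nrow(shown))) {
      if (!is_node[i] || shown$gen[i] >= levels) next
      r <- nd[match(ids[i], nd$node_id), ]
      for (ch in c(r$child1, r$child2)) {
        j <- match(ch, ids)
        if (!is.na(j)) graphics::segments(xx[i], yy[i], xx[j], yy[j], col = "grey60")
      }
    }
    lab <- vapply(seq_len(nrow(shown)), function(i) {
      id <- ids[i]
      base <- if (is_node[i]) {
        r <- nd[match(id, nd$node_id), ]
        sprintf("%d\naLCV %.2f", id, r$alcv)
      } else sprintf("ds %d", id)
      if (!is.null(annotations) && id %in% annotations$node_id) {
        a <- annotations[match(id, annotations$node_id), ]
        base <- paste0(base, sprintf("\nC %.1f%% Rm %.3f\nresCC %.2f",
                                     a$completeness, a$r_meas, a$res_cc))
      }
      base
    }, character(1))
    graphics::rect(xx - 0.8, yy - 0.3, xx + 0.8, yy + 0.3,
                   col = ifelse(is_node, "grey85", "white"), border = "grey40")
    graphics::text(xx, yy, lab, cex = 0.55)
  }
  render_plot(draw, file.path(dir, sprintf("tree_%d_%d.png", node_id, levels)),
              formats)
}

#' Build an annotation table from merge results
#'
#' @param results Named list of [merge_group()] results (names = node ids),
#'   e.g. a [mode_synthesis()] return value.
#' @return `data.frame` with `node_id`, `completeness`, `r_meas`, `res_cc`.
#' @export
annotation_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(node_id = suppressWarnings(as.integer(r$label)),
               completeness = r$stats$completeness,
               r_meas = r$stats$r_meas, res_cc = r$stats$res_cc)
  }))
}

#' Plot CC1/2 against resolution
#'
#' One curve per merge result, with the conventional usable-resolution
#' threshold CC1/2 = 0.3 marked.
#'
#' @param results List of [merge_group()] results (named for the legend).
#' @param path Output PNG path.
#' @param formats Additional formats (`"ps"`, `"svg"`).
#' @return Files written, invisibly.
#' @export
plot_cc_half <- function(results, path = "cc_half.png", formats = character(0)) {
  if (inherits(results, "merge_result")) results <- list(results)
  draw <- function() {
    cols <- grDevices::hcl.colors(max(3, length(results)), "Dark 3")
    xr <- range(unlist(lapply(results, function(r) r$stats$per_shell$d_mid)))
    graphics::plot(NA, xlim = rev(xr), ylim = c(-0.1, 1.05),
                   xlab = "resolution d (A)", ylab = "CC1/2",
                   main = "CC1/2 vs resolution")
    graphics::abline(h = 0.3, lty = 2, col = "grey50")
    for (i in seq_along(results)) {
      ps <- results[[i]]$stats$per_shell
      graphics::lines(ps$d_mid, ps$cc_half, col = cols[i], lwd = 2, type = "b", pch = 20)
    }
    nm <- names(results)
    if (is.null(nm)) nm <- vapply(results, `[[`, character(1), "label")
    graphics::legend("bottomleft", legend = nm, col = cols[seq_along(results)],
                     lwd = 2, bty = "n")
  }
  render_plot(draw, path, formats)
}
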