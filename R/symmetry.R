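#' Symmetry operators for reflection mapping
#'
#' Returns the point-group rotation operators (as 3x3 integer matrices
#' acting on Miller indices) for a small library of common space groups,
#' plus the Friedel flag. Only the rotation parts matter for mapping
#' observations to unique reflections; translation parts (screw axes) are
#' irrelevant for that purpose, so e.g. P2 and P21 share an operator set.
#' Arbitrary groups can be supplied as a list of matrices via `ops`.
#'
#' @param spacegroup Hermann-Mauguin symbol. Recognised (spaces ignored,
#'   case-insensitive): P1, P2, P21, P222, P212121, P4, P6.
#' @param friedel Treat (-h,-k,-l) as equivalent (default `TRUE`).
#' @param ops Optional list of user-supplied 3x3 integer matrices; when
#'   given, `spacegroup` is only a label. The identity is added if absent
#'   and the set is closed under composition.
#' @return Object of class `symmetry_ops`: list with `spacegroup`,
#'   `rotations` (list of matrices) and `friedel`.
#' @export
symmetry_ops <- function(spacegroup = "P1", friedel = TRUE, ops = NULL) {
  I3 <- diag(3)
  if (is.null(ops)) {
    sym <- toupper(gsub("[ ()]", "", spacegroup))
    two_b <- diag(c(-1, 1, -1))                      # 2-fold along b
    ortho <- list(I3, diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
    four_c <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # h'=(-k,h,l) row conv.
    six_c <- matrix(c(1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)   # hexagonal 6-fold
    gen <- switch(sym,
                  P1 = list(I3),
                  P2 = , P21 = list(I3, two_b),
                  P222 = , P212121 = ortho,
                  P4 = list(I3, four_c),
                  P6 = list(I3, six_c),
                  stop("no shipped operators for space group '", spacegroup,
                       "'; supply ops= explicitly"))
    ops <- gen
  }
  ops <- lapply(ops, function(m) {
    m <- round(m)
    storage.mode(m) <- "double"
    m
  })
  # close under composition (small groups; fixed-point iteration)
  keys <- function(l) vapply(l, function(m) paste(m, collapse = ","), character(1))
  repeat {
    new <- list()
    have <- keys(ops)
    for (a in ops) for (b in ops) {
      ab <- a %*% b
      if (!paste(ab, collapse = ",") %in% c(have, keys(new))) new <- c(new, list(ab))
    }
    if (!length(new)) break
    ops <- c(ops, new)
  }
  if (!any(keys(ops) == paste(I3, collapse = ","))) ops <- c(list(I3), ops)
  structure(list(spacegroup = spacegroup, rotations = ops,
                 friedel = isTRUE(friedel)),
            class = "symmetry_ops")
}

#' @export
print.symmetry_ops <- function(x, ...) {
  cat(sprintf("symmetry ops: %s, %d rotations, Friedel %s\n",
              x$spacegroup, length(x$rotations), x$friedel))
  invisible(x)
}

#' Map Miller indices to canonical unique keys
#'
#' Each observed (h, k, l) is replaced by the lexicographically greatest
#' triple in its symmetry orbit (rotations, plus Friedel negation when
#' enabled), so symmetry-equivalent observations share a key and can be
#' grouped for scaling, merging and statistics.
#'
#' @param hkl Matrix or data frame with columns h, k, l (one row per
#'   reflection), or a length-3 vector.
#' @param ops A [symmetry_ops()].
#' @return Integer matrix of the same height with columns h, k, l.
#' @export
map_to_unique <- function(hkl, ops) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  H <- as.matrix(hkl[, 1:3, drop = FALSE])
  storage.mode(H) <- "double"
  cand <- lapply(ops$rotations, function(R) H %*% R)
  if (ops$friedel) cand <- c(cand, lapply(cand, function(M) -M))
  L <- max(abs(H), 1) + 1
  base <- 2 * L + 1
  score <- vapply(cand, function(M) (M[, 1] * base + M[, 2]) * base + M[, 3],
                  numeric(nrow(H)))
  if (nrow(H) == 1L) score <- matrix(score, nrow = 1)
  pick <- max.col(score, ties.method = "first")
  out <- t(vapply(seq_len(nrow(H)), function(i) cand[[pick[i]]][i, ], numeric(3)))
  out <- round(out)
  storage.mode(out) <- "integer"
  colnames(out) <- c("h", "k", "l")
  out
}

# Enumerate the theoretical unique reflection count of a cell/symmetry to
# d_min (Angstrom). Direct enumeration over an index box wide enough for
# near-orthogonal cells; (0,0,0) excluded, Friedel and rotations collapsed.
count_unique_reflections <- function(cell, ops, d_min) {
  cell <- as_unit_cell(cell)
  lim <- ceiling(as.numeric(cell[1:3]) / d_min) + 1L
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  s <- resolution_s(grid, cell)
  grid <- grid[s <= 1 / d_min^2 + 1e-12, ]
  key <- map_to_unique(grid, ops)
  length(unique(paste(key[, 1], key[, 2], key[, 3])))
}

# Same enumeration, returning the unique index set itself (matrix h,k,l).
enumerate_unique_reflections <- function(cell, ops, d_min) {
  cell <- as_unit_cell(cell)
  lim <- ceiling(as.numeric(cell[1:3]) / d_min) + 1L
  grid <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  s <- resolution_s(grid, cell)
  grid <- grid[s <= 1 / d_min^2 + 1e-12, ]
  key <- map_to_unique(grid, ops)
  uniq <- !duplicated(paste(key[, 1], key[, 2], key[, 3]))
  key[uniq, , drop = FALSE]
}
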