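#' Construct a unit cell
#'
#' A unit cell is described by its six parameters: edge lengths `a`, `b`, `c`
#' in Angstrom and inter-axial angles `alpha`, `beta`, `gamma` in degrees.
#' The constructor validates that the parameters describe a physically
#' realisable lattice (positive-definite metric tensor).
#'
#' @param a,b,c Edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named numeric vector of length 6.
#' @examples
#' uc <- unit_cell(100, 100, 100, 90, 90, 90)
#' face_diagonals(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit cell parameters must be finite numbers")
  if (any(p[1:3] <= 0)) stop("unit cell edges must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(p, class = "unit_cell")
  G <- cell_metric(cell)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("unit cell angles do not define a valid (positive definite) lattice")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x[["a"]], x[["b"]], x[["c"]], x[["alpha"]], x[["beta"]], x[["gamma"]]))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6) stop("a unit cell needs exactly 6 parameters")
  unit_cell(x[1], x[2], x[3], x[4], x[5], x[6])
}

# Direct-space metric tensor G (Angstrom^2). G* = solve(G) is the reciprocal
# metric; s = 1/d^2 = h' G* h for Miller index column h.
cell_metric <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

#' Resolution coordinate of Miller indices
#'
#' Computes s = 1/d^2 (in 1/Angstrom^2) for each (h, k, l) row, the internal
#' resolution coordinate used throughout the package; `dspacing()` returns
#' d = 1/sqrt(s) in Angstrom.
#'
#' @param hkl Integer matrix (or data frame) with columns h, k, l.
#' @param cell A [unit_cell()].
#' @return Numeric vector of s values (length `nrow(hkl)`).
#' @export
resolution_s <- function(hkl, cell) {
  H <- as.matrix(hkl[, 1:3, drop = FALSE])
  storage.mode(H) <- "double"
  Gstar <- solve(cell_metric(as_unit_cell(cell)))
  rowSums((H %*% Gstar) * H)
}

#' @rdname resolution_s
#' @export
dspacing <- function(hkl, cell) 1 / sqrt(resolution_s(hkl, cell))

#' Longest face diagonals of a unit cell
#'
#' For each of the three cell faces — (a, b, gamma), (b, c, alpha) and
#' (a, c, beta) — returns the longer of the two parallelogram diagonals,
#' max over the sign of sqrt(p^2 + q^2 +/- 2 p q cos(theta)). These three
#' lengths are the descriptors from which the Linear Cell Variation
#' (LCV/aLCV) isomorphism score is computed; at 90 degrees both diagonals
#' coincide.
#'
#' @param cell A [unit_cell()].
#' @return Named numeric vector `c(ab=, bc=, ac=)` of diagonal lengths in
#'   Angstrom.
#' @export
face_diagonals <- function(cell) {
  cell <- as_unit_cell(cell)
  diag1 <- function(p, q, theta) {
    ct <- cos(theta * pi / 180)
    sqrt(max(p^2 + q^2 + 2 * p * q * ct, p^2 + q^2 - 2 * p * q * ct))
  }
  c(ab = diag1(cell[["a"]], cell[["b"]], cell[["gamma"]]),
    bc = diag1(cell[["b"]], cell[["c"]], cell[["alpha"]]),
    ac = diag1(cell[["a"]], cell[["c"]], cell[["beta"]]))
}
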