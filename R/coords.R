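#' Stereotaxic coordinate utilities
#'
#' Conversion between Talairach and MNI spaces uses the Brett piecewise
#' affine (distinct superior, z > 0, and inferior, z <= 0, branches in MNI
#' space). The forward map is MNI -> Talairach; the Talairach -> MNI map is
#' its exact inverse, with the branch chosen by the sign of the resulting MNI
#' z (computed consistently: the superior inverse is used when it lands at
#' z >= 0, otherwise the inferior inverse).
#'
#' @name coords
NULL

.brett_sup <- matrix(c(
  0.9900, 0.0000, 0.0000,
  0.0000, 0.9688, 0.0460,
  0.0000, -0.0485, 0.9189), 3, 3, byrow = TRUE)

.brett_inf <- matrix(c(
  0.9900, 0.0000, 0.0000,
  0.0000, 0.9688, 0.0420,
  0.0000, -0.0485, 0.8390), 3, 3, byrow = TRUE)

.as_xyz <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop("coordinate must have 3 components (x, y, z)")
    x <- matrix(x, 1, 3)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinate matrix must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Convert MNI coordinates to Talairach (Brett transform)
#'
#' @param xyz Numeric length-3 vector or n x 3 matrix of MNI mm coordinates.
#' @return Same shape, Talairach mm.
#' @export
#' @examples
#' tal_from_mni(c(-48.5, -63.7, 15.1))  # ~ (-48, -61, 17)
tal_from_mni <- function(xyz) {
  m <- .as_xyz(xyz)
  out <- m
  for (i in seq_len(nrow(m))) {
    M <- if (m[i, 3] >= 0) .brett_sup else .brett_inf
    out[i, ] <- drop(M %*% m[i, ])
  }
  if (is.null(dim(xyz))) drop(out) else out
}

#' Convert Talairach coordinates to MNI (inverse Brett transform)
#'
#' @param xyz Numeric length-3 vector or n x 3 matrix of Talairach mm
#'   coordinates.
#' @return Same shape, MNI mm.
#' @export
#' @examples
#' round(mni_from_tal(c(-48, -61, 17)), 1)  # (-48.5, -63.7, 15.1)
mni_from_tal <- function(xyz) {
  m <- .as_xyz(xyz)
  inv_sup <- solve(.brett_sup)
  inv_inf <- solve(.brett_inf)
  out <- m
  for (i in seq_len(nrow(m))) {
    cand <- drop(inv_sup %*% m[i, ])
    if (cand[3] < 0) cand <- drop(inv_inf %*% m[i, ])
    out[i, ] <- cand
  }
  if (is.null(dim(xyz))) drop(out) else out
}

#' Average a set of coordinates per axis
#'
#' Missing entries (NA) are skipped per axis, matching literature tables in
#' which some studies report only one space.
#'
#' @param xyz n x 3 matrix (or data.frame) of coordinates in a common space.
#' @param digits If non-NULL, round the result to this many decimals
#'   (reporting convention: 1 decimal place).
#' @return Length-3 named vector.
#' @export
average_coords <- function(xyz, digits = NULL) {
  m <- .as_xyz(xyz)
  if (nrow(m) == 0) stop("empty coordinate list")
  out <- colMeans(m, na.rm = TRUE)
  if (!is.null(digits)) out <- round(out, digits)
  names(out) <- c("x", "y", "z")
  out
}

#' Select the candidate peak nearest to a reference coordinate
#'
#' Euclidean distance; ties broken by list order (first wins).
#'
#' @param candidates n x 3 matrix of candidate peaks.
#' @param reference Length-3 reference coordinate (same space).
#' @return List with `coord` (length-3 vector), `index`, `distance`.
#' @export
nearest_peak <- function(candidates, reference) {
  m <- .as_xyz(candidates)
  if (nrow(m) == 0) stop("empty candidate list")
  ref <- .as_xyz(reference)
  d <- sqrt(rowSums(sweep(m, 2, drop(ref))^2))
  i <- unname(which.min(d))  # which.min returns the first minimum: tie rule
  list(coord = unname(m[i, ]), index = i, distance = unname(d[i]))
}
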