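# Least-squares C-alpha superposition (Kabsch) via bio3d's fitting engine.

#' C-alpha RMSD after optimal rigid-body superposition
#'
#' Pairs the C-alpha atoms of two fragments by rank order within each
#' fragment (author residue numbering is ignored, since de novo models
#' rarely share numbering with crystal structures), finds the least-squares
#' optimal rotation and translation, and returns the root-mean-square
#' C-alpha deviation after the fit.
#'
#' @param model,reference [ProteinStructure] fragments, or n-by-3 matrices
#'   of C-alpha coordinates. Both must yield the same number (>= 3) of
#'   C-alpha atoms.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' s <- makeLoopStructure(structureSpec(nChains = 1, chainLength = 8))
#' superposeCalpha(s, s)
superposeCalpha <- function(model, reference) {
  xm <- calphaCoords(model)
  xr <- calphaCoords(reference)
  if (nrow(xm) != nrow(xr))
    stop(sprintf("C-alpha counts differ: model %d vs reference %d",
                 nrow(xm), nrow(xr)), call. = FALSE)
  if (nrow(xm) < 3L)
    stop("need at least 3 C-alpha atoms to superpose", call. = FALSE)
  fixed <- as.numeric(t(xr))
  mobile <- as.numeric(t(xm))
  idx <- seq_along(fixed)
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = idx,
                           mobile.inds = idx)
  dev <- matrix(fitted - fixed, ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums(dev^2)))
}

calphaCoords <- function(x) {
  if (is(x, "ProteinStructure")) {
    a <- x@atoms
    ca <- a[a$elety == "CA", , drop = FALSE]
    ca <- ca[order(match(ca$chain, unique(ca$chain)), ca$resno), ,
             drop = FALSE]
    as.matrix(ca[, c("x", "y", "z")])
  } else if (is.matrix(x) && ncol(x) == 3L) {
    x
  } else {
    stop("expected a ProteinStructure or an n-by-3 coordinate matrix",
         call. = FALSE)
  }
}

#' Apply a rigid transformation to coordinates
#'
#' Utility for generating rotated/translated copies of a fragment (e.g. to
#' verify that superposition RMSD is invariant under rigid motion).
#'
#' @param xyz n-by-3 coordinate matrix.
#' @param angles Euler angles (radians) about the x, y and z axes.
#' @param translation Length-3 translation vector.
#' @return Transformed n-by-3 matrix.
#' @export
rigidTransform <- function(xyz, angles = c(0, 0, 0),
                           translation = c(0, 0, 0)) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L)
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  t(Rz %*% Ry %*% Rx %*% t(xyz)) +
    matrix(translation, nrow(xyz), 3L, byrow = TRUE)
}
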