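#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' selected atoms of two coordinate sets, via SVD of the cross-covariance.
#'
#' @param ref reference n x 3 coordinate matrix, Angstrom.
#' @param mobile mobile n x 3 coordinate matrix.
#' @param selection integer indices used to fit (default: all rows).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (over the selection, Angstrom) and `coords` (all mobile atoms
#'   transformed onto the reference frame).
#' @export
kabsch_superpose <- function(ref, mobile, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  A <- ref[selection, , drop = FALSE]
  B <- mobile[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selected atom counts differ")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("degenerate (collinear) selection; superposition undefined")
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- sweep(sweep(mobile, 2, cb) %*% R, 2, ca, "+")
  resid <- moved[selection, , drop = FALSE] - A
  list(rotation = R, translation = ca - cb %*% R,
       rmsd = sqrt(mean(rowSums(resid^2))), coords = moved)
}

# Plain positional RMSD (no fitting), Angstrom.
rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Fitted RMSD between two coordinate sets over `selection`.
rmsd_fit <- function(a, b, selection = NULL) {
  kabsch_superpose(a, b, selection)$rmsd
}
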