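# Low-level geometry: minimum-image distances and Kabsch superposition.

# Pairwise distances between coordinate row-sets a (n x 3) and b (m x 3),
# applying the orthorhombic minimum-image convention when box is given.
.pair_dists <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{mobile} onto \code{reference} over the fit atoms, by the closed-form
#' SVD (Kabsch) solution. The transform maps a mobile row \eqn{x} to
#' \eqn{x R + t}.
#'
#' @param mobile n x 3 coordinate matrix (nm).
#' @param reference n x 3 coordinate matrix (nm); same atom count over the
#'   fit set.
#' @param fit_sel optional [select_atoms()] result or integer indices giving
#'   the atoms to fit on (defaults to all rows).
#' @return list of class \code{superposition} with \code{rotation} (3 x 3,
#'   determinant +1), \code{translation} (length-3, nm), \code{rmsd} (nm,
#'   over the fit atoms) and \code{coords} (all mobile rows transformed).
#' @export
superpose <- function(mobile, reference, fit_sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  idx <- .as_indices(fit_sel, nrow(mobile))
  if (length(idx) < 3) stop("degenerate-fit error: need at least 3 fit atoms")
  mf <- mobile[idx, , drop = FALSE]
  rf <- reference[idx, , drop = FALSE]
  if (nrow(mf) != nrow(rf)) stop("fit selections must have equal atom counts")
  mc <- colMeans(mf); rc <- colMeans(rf)
  A <- sweep(mf, 2, mc)
  B <- sweep(rf, 2, rc)
  # collinearity check: centered fit atoms must span at least a plane
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-12) {
    stop("degenerate-fit error: fit atoms are collinear")
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- rc - mc %*% R
  fitted <- sweep(mf %*% R, 2, as.numeric(t_vec), "+")
  rmsd <- sqrt(mean(rowSums((fitted - rf)^2)))
  coords <- sweep(mobile %*% R, 2, as.numeric(t_vec), "+")
  structure(list(rotation = R, translation = as.numeric(t_vec),
                 rmsd = rmsd, coords = coords),
            class = "superposition")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain coordinate RMSD, without fitting. Use [superpose()] first to remove
#' rigid-body motion.
#'
#' @param a,b n x 3 coordinate matrices (nm).
#' @param idx optional atom indices over which to measure.
#' @return RMSD in nm.
#' @export
coord_rmsd <- function(a, b, idx = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  i <- .as_indices(idx, nrow(a))
  sqrt(mean(rowSums((a[i, , drop = FALSE] - b[i, , drop = FALSE])^2)))
}

# Accept atom_selection objects, integer vectors or NULL (= all n rows).
.as_indices <- function(sel, n) {
  if (is.null(sel)) return(seq_len(n))
  if (inherits(sel, "atom_selection")) sel <- sel$indices
  sel <- as.integer(sel)
  if (length(sel) == 0) stop("selection error: empty selection")
  if (any(sel < 1 | sel > n)) stop("selection error: index out of range")
  sel
}
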