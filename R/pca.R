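# Cartesian principal component analysis (essential dynamics) and the
# one-Gaussian essential-space classifier.

# Flatten the selected coordinates of every frame into an n_frames x 3N
# matrix, optionally superposing each frame on a reference first.
.flatten_aligned <- function(traj, sel_idx, fit_reference = NULL, fit_idx = NULL) {
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, 3 * length(sel_idx))
  ref <- if (!is.null(fit_reference)) fit_reference$coords else NULL
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    if (!is.null(ref)) xyz <- superpose(xyz, ref, fit_idx)$coords
    out[f, ] <- as.vector(t(xyz[sel_idx, , drop = FALSE]))  # x1 y1 z1 x2 ...
  }
  out
}

#' Cartesian PCA of positional fluctuations
#'
#' Optionally superposes every frame on a reference structure over
#' \code{fit_sel} (for pump trajectories, the 10-helix transmembrane domain
#' is the customary alignment reference), then eigendecomposes the covariance
#' matrix of the selected atoms' Cartesian coordinates about their mean.
#' Components are ordered by descending eigenvalue and each eigenvector's
#' sign is fixed by making its largest-magnitude entry positive, so results
#' are deterministic. Near-degenerate eigenvalue pairs (relative gap
#' < 1e-6) are flagged; collinearity comparisons should treat those as
#' subspaces rather than individual vectors.
#'
#' @param traj an [md_trajectory()] with at least 2 frames.
#' @param sel [select_atoms()] result: the atoms analysed (commonly C-alpha).
#' @param fit_reference optional [md_frame()] to superpose on; \code{NULL}
#'   analyses coordinates as stored (useful when frames are already in a
#'   common frame of reference).
#' @param fit_sel selection used for the superposition (required when
#'   \code{fit_reference} is given).
#' @return object of class \code{pc_model}: \code{mean_coords} (3N vector,
#'   nm), \code{eigenvectors} (3N x 3N orthonormal columns),
#'   \code{eigenvalues} (descending, nm^2), \code{trace} (total positional
#'   variance), \code{degenerate} (logical per adjacent pair),
#'   \code{sel_idx}, \code{fit_reference}, \code{fit_idx}.
#' @export
fit_pca <- function(traj, sel, fit_reference = NULL, fit_sel = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2) stop("insufficient-data error: PCA needs at least 2 frames")
  n <- nrow(traj$topology$atoms)
  sel_idx <- .as_indices(sel, n)
  fit_idx <- if (!is.null(fit_reference)) .as_indices(fit_sel, n) else NULL
  X <- .flatten_aligned(traj, sel_idx, fit_reference, fit_idx)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  gaps <- abs(diff(vals)) / pmax(vals[-length(vals)], .Machine$double.eps)
  structure(list(
    mean_coords = mu,
    eigenvectors = vecs,
    eigenvalues = vals,
    trace = sum(diag(C)),
    degenerate = gaps < 1e-6,
    sel_idx = sel_idx,
    fit_reference = fit_reference,
    fit_idx = fit_idx
  ), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d coordinates, trace %.4g nm^2; top eigenvalues: %s\n",
              length(x$mean_coords), x$trace,
              paste(signif(utils::head(x$eigenvalues, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Cumulative variance accounted for by the leading components
#'
#' @param model a [fit_pca()] model.
#' @return numeric vector: cumulative fraction of total variance after
#'   1, 2, ... components.
#' @export
variance_accounting <- function(model) {
  stopifnot(inherits(model, "pc_model"))
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(rep(0, length(model$eigenvalues)))
  cumsum(model$eigenvalues) / tot
}

#' Smallest number of components reaching a variance fraction
#'
#' @param model a [fit_pca()] model.
#' @param fraction target cumulative variance fraction in (0, 1].
#' @return integer component count.
#' @export
components_needed <- function(model, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("domain error: fraction must be in (0, 1]")
  curve <- variance_accounting(model)
  k <- which(curve >= fraction - 1e-12)[1]
  if (is.na(k)) stop("requested variance fraction not reached")
  as.integer(k)
}

#' Project a trajectory onto one principal component
#'
#' Frames are aligned exactly as during fitting (when the model carries a fit
#' reference), mean-centered with the model mean, and dotted with
#' eigenvector \code{k}.
#'
#' @param traj an [md_trajectory()] over the same topology.
#' @param model a [fit_pca()] model.
#' @param k component index.
#' @return numeric per-frame projection values (nm).
#' @export
project_component <- function(traj, model, k) {
  stopifnot(inherits(model, "pc_model"))
  if (k < 1 || k > ncol(model$eigenvectors)) stop("index error: component out of range")
  X <- .flatten_aligned(traj, model$sel_idx, model$fit_reference, model$fit_idx)
  as.numeric(sweep(X, 2, model$mean_coords) %*% model$eigenvectors[, k])
}

#' One-Gaussian essential-space classification of a component projection
#'
#' Histograms the projection (50 bins over mean +/- 4 sd by default), fits a
#' single Gaussian \eqn{A exp(-(x-\mu)^2 / 2\sigma^2)} to the bin densities by
#' least squares, and computes the coefficient of determination
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}}. Classification follows the three-band
#' rule used for essential dynamics: \eqn{r^2 < 0.9} essential (markedly
#' non-Gaussian), \eqn{0.9 \le r^2 < 0.98} partial (retains significant
#' non-Gaussian features), \eqn{r^2 \ge 0.98} non-essential (Gaussian
#' fluctuation).
#'
#' @param values per-frame projection values (at least 100).
#' @param n_bins histogram bin count.
#' @param thresholds length-2 classification thresholds (default
#'   \code{c(0.9, 0.98)}).
#' @return object of class \code{gaussian_fit}: \code{amplitude}, \code{mu},
#'   \code{sigma}, \code{r_squared}, \code{classification}, \code{converged}.
#' @export
classify_gaussianity <- function(values, n_bins = 50, thresholds = c(0.9, 0.98)) {
  values <- as.numeric(values)
  if (length(values) < 100) stop("need at least 100 samples for classification")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) stop("degenerate projection: zero variance")
  edges <- seq(m - 4 * s, m + 4 * s, length.out = n_bins + 1)
  inside <- values[values >= edges[1] & values <= edges[n_bins + 1]]
  counts <- as.integer(table(cut(inside, breaks = edges, include.lowest = TRUE)))
  width <- diff(edges)[1]
  dens <- counts / (length(values) * width)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  # fit in standardized units: r^2 is scale-invariant and the least-squares
  # gradient stays well conditioned for projections of any magnitude
  df <- data.frame(x = (mids - m) / s, d = dens * s)
  start <- list(A = max(df$d), mu = 0, sig = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ A * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
                      start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(amplitude = NA_real_, mu = NA_real_, sigma = NA_real_,
                          r_squared = NA_real_, classification = NA_character_,
                          converged = FALSE, diagnostics = conditionMessage(fit)),
                     class = "gaussian_fit"))
  }
  co <- stats::coef(fit)
  pred <- co[["A"]] * exp(-(df$x - co[["mu"]])^2 / (2 * co[["sig"]]^2))
  ss_res <- sum((df$d - pred)^2)
  ss_tot <- sum((df$d - mean(df$d))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(
    amplitude = co[["A"]] / s, mu = m + s * co[["mu"]], sigma = s * abs(co[["sig"]]),
    r_squared = r2,
    classification = classify_r_squared(r2, thresholds),
    converged = TRUE
  ), class = "gaussian_fit")
}

#' Three-band essential-space rule on a fit's coefficient of determination
#'
#' @param r_squared coefficient of determination of the one-Gaussian fit.
#' @param thresholds length-2 increasing thresholds, default
#'   \code{c(0.9, 0.98)}.
#' @return \code{"essential"}, \code{"partial"} or \code{"non-essential"}.
#' @export
classify_r_squared <- function(r_squared, thresholds = c(0.9, 0.98)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (is.na(r_squared)) return(NA_character_)
  if (r_squared < thresholds[1]) "essential"
  else if (r_squared < thresholds[2]) "partial"
  else "non-essential"
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("gaussian_fit: did not converge (", x$diagnostics, ")\n")
  } else {
    cat(sprintf("gaussian_fit: A=%.4g mu=%.4g sigma=%.4g r^2=%.4f -> %s\n",
                x$amplitude, x$mu, x$sigma, x$r_squared, x$classification))
  }
  invisible(x)
}

#' Inner-product matrix between two models' leading eigenvectors
#'
#' Entry (i, j) is the absolute dot product of unit eigenvector i of model A
#' with unit eigenvector j of model B. Values near 1 mean the two components
#' span the same direction of collective motion (collinearity); near 0,
#' orthogonal subspaces.
#'
#' @param modelA,modelB [fit_pca()] models over selections of equal size.
#' @param k number of leading components to compare.
#' @return k x k numeric matrix with entries in [0, 1].
#' @export
inner_products <- function(modelA, modelB, k = 10) {
  stopifnot(inherits(modelA, "pc_model"), inherits(modelB, "pc_model"))
  if (length(modelA$mean_coords) != length(modelB$mean_coords)) {
    stop("shape error: models have different coordinate dimensions")
  }
  k <- min(k, ncol(modelA$eigenvectors), ncol(modelB$eigenvectors))
  M <- abs(crossprod(modelA$eigenvectors[, seq_len(k), drop = FALSE],
                     modelB$eigenvectors[, seq_len(k), drop = FALSE]))
  dimnames(M) <- list(paste0("A", seq_len(k)), paste0("B", seq_len(k)))
  M
}
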