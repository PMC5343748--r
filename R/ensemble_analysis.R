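#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of `mobile` onto `ref` using a
#' proper rotation (determinant +1) computed on a subset of atoms; the
#' whole coordinate set is transformed.
#'
#' @param mobile n x 3 coordinate matrix to transform.
#' @param ref n x 3 reference coordinates.
#' @param subset atom indices used for the fit (default all; at least 3,
#'   non-collinear).
#' @return list with `coords` (transformed mobile), `rmsd` (subset RMSD).
#' @export
kabsch_superpose <- function(mobile, ref, subset = seq_len(nrow(ref))) {
  stopifnot(nrow(mobile) == nrow(ref), length(subset) >= 3)
  p <- mobile[subset, , drop = FALSE]
  q <- ref[subset, , drop = FALSE]
  if (svd(sweep(p, 2, colMeans(p)))$d[2] < 1e-10 * max(1, max(abs(p)))) {
    stop("degenerate (collinear) subset for superposition")
  }
  pc <- colMeans(p); qc <- colMeans(q)
  sv <- svd(crossprod(sweep(p, 2, pc), sweep(q, 2, qc)))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(sweep(mobile, 2, pc) %*% t(rot), 2, qc, "+")
  list(coords = out,
       rmsd = sqrt(mean(rowSums((out[subset, , drop = FALSE] - q)^2))))
}

#' Plain RMSD between two coordinate sets (no superposition)
#' @param a,b n x 3 matrices
#' @param subset optional atom indices
#' @return RMSD in Angstroms
#' @export
rmsd_plain <- function(a, b, subset = seq_len(nrow(a))) {
  sqrt(mean(rowSums((a[subset, , drop = FALSE] -
                       b[subset, , drop = FALSE])^2)))
}

#' RMSD after optimal superposition
#' @inheritParams rmsd_plain
#' @return RMSD in Angstroms
#' @export
rmsd_fit <- function(a, b, subset = seq_len(nrow(a))) {
  kabsch_superpose(a, b, subset)$rmsd
}

#' Reference-free iterative ensemble alignment
#'
#' All models are superposed on the first, the centroid average is
#' taken, models are re-superposed on the average, and the cycle repeats
#' until the average moves by less than `tol` RMSD (or `max_iter`
#' rounds). No single model acts as the reference for the converged
#' frame.
#'
#' @param e a `pse_ensemble` with at least 2 models.
#' @param subset atom indices used for the fits (default C-alpha atoms).
#' @param tol convergence threshold on the average-structure RMSD
#'   between rounds, Angstroms.
#' @param max_iter maximum alignment rounds.
#' @return the aligned ensemble (`aligned = TRUE`).
#' @export
iterative_align <- function(e, subset = NULL, tol = 1e-4, max_iter = 50) {
  stopifnot(n_models(e) >= 2)
  if (is.null(subset)) {
    subset <- which(e$roster$name == "CA")
    if (length(subset) < 3) subset <- seq_len(nrow(e$roster))
  }
  models <- lapply(e$models, function(m) {
    kabsch_superpose(m, e$models[[1]], subset)$coords
  })
  avg <- Reduce(`+`, models) / length(models)
  for (it in seq_len(max_iter)) {
    models <- lapply(models, function(m) kabsch_superpose(m, avg, subset)$coords)
    new_avg <- Reduce(`+`, models) / length(models)
    shift <- rmsd_plain(new_avg, avg, subset)
    avg <- new_avg
    if (shift < tol) break
  }
  e$models <- models
  e$aligned <- TRUE
  e
}

#' Average structure of an aligned ensemble
#'
#' Per-atom arithmetic mean (the centroid of the coordinates across the
#' ensemble after superposition).
#'
#' @param e an aligned `pse_ensemble`
#' @return n_atoms x 3 matrix
#' @export
average_structure <- function(e) {
  if (!isTRUE(e$aligned)) stop("ensemble must be aligned first")
  Reduce(`+`, e$models) / n_models(e)
}

#' Principal component analysis of an ensemble
#'
#' The covariance matrix over the 3 N_C C-alpha coordinates,
#' C_ij = <(x_i - <x_i>) (x_j - <x_j>)> with ensemble averages in the
#' angle brackets, is diagonalised to give the orthogonal motions that
#' describe the variation of the ensemble. Eigenvector signs are fixed
#' so the largest-magnitude entry is positive (reproducible plots).
#'
#' @param e an aligned `pse_ensemble` with at least 2 models.
#' @param ca_only use C-alpha atoms only (default TRUE).
#' @return list of class `pse_pca` with `mean` (3N vector), `eigenvalues`
#'   (descending, Angstrom^2), `eigenvectors` (columns, orthonormal),
#'   `variance_fractions`, `atom_subset`.
#' @export
pca_ensemble <- function(e, ca_only = TRUE) {
  if (!isTRUE(e$aligned)) stop("ensemble must be aligned first")
  stopifnot(n_models(e) >= 2)
  subset <- if (ca_only) which(e$roster$name == "CA") else seq_len(nrow(e$roster))
  x <- t(vapply(e$models,
                function(m) as.vector(t(m[subset, , drop = FALSE])),
                numeric(3 * length(subset))))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / nrow(x)  # population covariance: <...> is the mean
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  tot <- sum(vals)
  structure(list(mean = mu, eigenvalues = vals, eigenvectors = vecs,
                 variance_fractions = if (tot > 0) vals / tot else rep(0, length(vals)),
                 atom_subset = subset),
            class = "pse_pca")
}

#' Project a conformation onto a principal component
#'
#' Dot product of the centred coordinate vector with the eigenvector.
#' The coordinates must already sit in the PCA frame (ensemble members
#' after alignment do; external structures should first be superposed
#' onto the PCA mean).
#'
#' @param xyz full-roster coordinate matrix.
#' @param pca a `pse_pca` object.
#' @param component component index (1 = largest eigenvalue).
#' @return scalar projection, Angstroms.
#' @export
project_onto_pc <- function(xyz, pca, component) {
  v <- as.vector(t(xyz[pca$atom_subset, , drop = FALSE])) - pca$mean
  sum(v * pca$eigenvectors[, component])
}

#' Superpose an external structure into a PCA frame
#'
#' External conformations (e.g. crystal structures not in the ensemble)
#' must sit in the PCA frame before projection; they are superposed by
#' Kabsch onto the PCA mean using the PCA atom subset.
#'
#' @param xyz full-roster coordinate matrix.
#' @param pca a `pse_pca` object.
#' @return transformed coordinate matrix, ready for [project_onto_pc]
#' @export
superpose_to_pca <- function(xyz, pca) {
  mean_xyz <- matrix(pca$mean, ncol = 3, byrow = TRUE)
  sub <- xyz[pca$atom_subset, , drop = FALSE]
  pc <- colMeans(sub); qc <- colMeans(mean_xyz)
  sv <- svd(crossprod(sweep(sub, 2, pc), sweep(mean_xyz, 2, qc)))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(xyz, 2, pc) %*% t(rot), 2, qc, "+")
}

#' Per-residue mean square fluctuation
#'
#' MSF = <|x_CA - <x_CA>|^2> over the aligned ensemble, one value per
#' residue, in Angstrom^2; a measure of the conformational flexibility
#' of the residue across the ensemble.
#'
#' @param e an aligned `pse_ensemble`
#' @return numeric vector, one value per residue with a C-alpha atom
#' @export
rmsf <- function(e) {
  if (!isTRUE(e$aligned)) stop("ensemble must be aligned first")
  cas <- which(e$roster$name == "CA")
  avg <- average_structure(e)[cas, , drop = FALSE]
  msf <- rep(0, length(cas))
  for (m in e$models) {
    msf <- msf + rowSums((m[cas, , drop = FALSE] - avg)^2)
  }
  msf / n_models(e)
}

#' Per-residue MSF ratio between two ensembles
#'
#' Elementwise MSF(perturbed) / MSF(reference); values below 1 mark
#' residues rigidified by the perturbation. Residues whose reference MSF
#' is below 1e-12 Angstrom^2 are reported as NaN and should be excluded
#' from summaries.
#'
#' @param perturbed,reference aligned ensembles on the same residue roster.
#' @return numeric vector of ratios (NaN where the reference is static)
#' @export
rmsf_ratio <- function(perturbed, reference) {
  if (!identical(perturbed$roster$name, reference$roster$name) ||
      !identical(perturbed$roster$resseq, reference$roster$resseq)) {
    stop("ensembles have different rosters")
  }
  mp <- rmsf(perturbed)
  mr <- rmsf(reference)
  out <- mp / mr
  out[mr < 1e-12] <- NaN
  out
}
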