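#' Pocket container
#'
#' A candidate binding pocket: a point cloud from any grid pocket finder
#' plus the pocket centre and volume the finder reports.
#'
#' @param id integer identifier (conventionally rank by descending volume).
#' @param center 3-vector, Angstroms.
#' @param points n x 3 matrix of pocket points.
#' @param volume pocket volume in Angstrom^3 as supplied by the finder.
#' @return object of class `pse_pocket`
#' @export
pse_pocket <- function(id, center, points, volume) {
  points <- matrix(as.numeric(points), ncol = 3)
  structure(list(id = as.integer(id), center = as.numeric(center),
                 points = points, volume = as.numeric(volume)),
            class = "pse_pocket")
}

#' Select pockets for perturbation
#'
#' Keeps pockets with volume strictly greater than 13 Angstrom^3 (below
#' that a small-molecule modulator is unlikely to fit), at most eight
#' per protein, by descending volume.
#'
#' @param pockets list of `pse_pocket`
#' @param min_volume volume cutoff (default 13).
#' @param max_pockets maximum retained (default 8).
#' @return filtered list (possibly empty, with a warning)
#' @export
filter_pockets <- function(pockets, min_volume = 13, max_pockets = 8) {
  vols <- vapply(pockets, function(p) p$volume, numeric(1))
  keep <- which(vols > min_volume)
  if (length(keep) == 0) {
    warning("no pockets pass the volume filter")
    return(list())
  }
  keep <- keep[order(-vols[keep])]
  pockets[keep[seq_len(min(max_pockets, length(keep)))]]
}

#' Sample a fixed number of pocket points
#'
#' Exactly `n` points are drawn uniformly so perturbation strength does
#' not depend on pocket size: without replacement when the pocket has at
#' least `n` points, with replacement (resampling) otherwise.
#'
#' @param p a `pse_pocket` with nonempty points.
#' @param n number of points (default 120).
#' @param seed integer seed.
#' @return n x 3 matrix
#' @export
sample_pocket_points <- function(p, n = 120, seed = 1L) {
  np <- nrow(p$points)
  stopifnot(np >= 1)
  idx <- with_seed(seed, sample.int(np, n, replace = np < n))
  p$points[idx, , drop = FALSE]
}

#' Lattice ball of pseudo-modulator points
#'
#' A cubic lattice with the given spacing centred on `center`,
#' intersected with the smallest ball holding at least `n` points; the
#' `n` points closest to the centre are returned (ties broken by
#' lexicographic lattice order). Used to fake a rigid modulator at a
#' known site, e.g. around a ligand atom position.
#'
#' @param center 3-vector, Angstroms.
#' @param spacing lattice constant (default 1.2 A).
#' @param n number of points (default 120).
#' @return n x 3 matrix
#' @export
ball_points <- function(center, spacing = 1.2, n = 120) {
  # lattice radius guaranteed to contain >= n points: volume argument
  r <- spacing * ceiling((3 * n / (4 * pi))^(1 / 3)) + 2 * spacing
  m <- ceiling(r / spacing)
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  pts <- as.matrix(g) * spacing
  d2 <- rowSums(pts^2)
  ord <- order(d2, g$i, g$j, g$k)
  pts <- pts[ord[seq_len(n)], , drop = FALSE]
  sweep(pts, 2, center, "+")
}

#' Modulator distance constraints at sampled points
#'
#' Each pocket point becomes a pseudo-atom appended to the roster; every
#' point-protein pair closer than `cutoff` (7 A) gets a constraint of
#' d +/- `tol` (0.1 A), pinning the local protein environment around the
#' simulated modulator. Points with no protein atom in reach draw a
#' warning (they add no constraint).
#'
#' @param points n x 3 matrix of sampled pocket points.
#' @param s the `pse_structure` the distances are measured in.
#' @param roster_offset index of the last protein atom (pseudo-atom j
#'   indices start at `roster_offset + 1`).
#' @param cutoff protein-point distance cutoff, Angstroms.
#' @param tol constraint half-width, Angstroms.
#' @return data frame of constraints (columns i, j, lower, upper, type);
#'   type is the generic code 15 (the tolerance is fixed, not scaled).
#' @export
modulator_constraints <- function(points, s, roster_offset = n_atoms(s),
                                  cutoff = 7, tol = 0.1) {
  xyz <- coords(s)
  out <- vector("list", nrow(points))
  unconstrained <- 0L
  for (k in seq_len(nrow(points))) {
    d <- sqrt(colSums((t(xyz) - points[k, ])^2))
    hit <- which(d <= cutoff)
    if (length(hit) == 0) {
      unconstrained <- unconstrained + 1L
      next
    }
    out[[k]] <- data.frame(i = hit, j = roster_offset + k,
                           lower = pmax(d[hit] - tol, 1e-3),
                           upper = d[hit] + tol, type = 15L)
  }
  if (unconstrained > 0) {
    warning(unconstrained, " pocket point(s) have no protein atom within ",
            cutoff, " A and add no constraints")
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(i = integer(0), j = integer(0),
                                    lower = numeric(0), upper = numeric(0),
                                    type = integer(0))
  rownames(df) <- NULL
  df
}

# point-point constraints making the fake modulator quasi-rigid; an
# unconnected cloud could not transmit a perturbation through the pocket
point_rigidity_constraints <- function(points, roster_offset, tol = 0.1) {
  n <- nrow(points)
  if (n < 2) return(NULL)
  cmb <- utils::combn(n, 2)
  d <- sqrt(rowSums((points[cmb[1, ], , drop = FALSE] -
                       points[cmb[2, ], , drop = FALSE])^2))
  data.frame(i = roster_offset + cmb[1, ], j = roster_offset + cmb[2, ],
             lower = pmax(d - tol, 1e-3), upper = d + tol, type = 15L)
}

#' Augment a constraint set with modulator pseudo-atoms
#'
#' Appends the sampled points as pseudo-atoms after the protein roster
#' and adds point-protein constraints. Optionally the points can also be
#' constrained pairwise into a quasi-rigid body (`rigid_points = TRUE`);
#' that roughly triples the constraint count, which dilutes the random
#' sampling of protein constraints during embedding and inflates protein
#' fluctuations, so it is off by default. The protein-protein
#' constraints are unchanged either way.
#'
#' @param base_cs the unperturbed [pse_constraint_set].
#' @param points sampled pocket points (n x 3).
#' @param s structure the distances are measured in.
#' @param rigid_points add point-point constraints (default FALSE).
#' @param cutoff,tol see [modulator_constraints].
#' @return a [pse_constraint_set] over `n_atoms + nrow(points)` points
#' @export
augment_constraints <- function(base_cs, points, s, rigid_points = FALSE,
                                cutoff = 7, tol = 0.1) {
  off <- base_cs$n_atoms
  add <- modulator_constraints(points, s, roster_offset = off,
                               cutoff = cutoff, tol = tol)
  if (rigid_points) add <- rbind(add, point_rigidity_constraints(points, off, tol))
  pse_constraint_set(rbind(base_cs$df, add),
                     n_atoms = off + nrow(points),
                     wb = base_cs$wb, seed = base_cs$seed)
}

#' Perturb each pocket and rank by ensemble-average shift
#'
#' For every pocket: sample 120 points, add modulator constraints to the
#' base set, generate a perturbed ensemble, align the pooled
#' (unperturbed + perturbed) models into one frame without a reference,
#' and measure the C-alpha RMSD between the two ensemble averages. The
#' shift RMSD ranks the pockets (largest to smallest; ties by pocket
#' id) by predicted allosteric effect.
#'
#' @param a,b intersected input structures (`b` may equal `a` for the
#'   single-structure workflow); pocket-point distances are measured in `a`.
#' @param pockets list of `pse_pocket` (already filtered).
#' @param base_cs unperturbed [pse_constraint_set].
#' @param n_models_per models per ensemble (default 250; tests use
#'   fewer to stay fast).
#' @param params an [spe_params]
#' @param n_points points sampled per pocket (default 120).
#' @param rigid_points see [augment_constraints].
#' @param unperturbed optional precomputed unperturbed ensemble (must
#'   come from `base_cs` with `params`).
#' @return list of class `pse_perturbation_ranking`: per-pocket results
#'   (`pocket_id`, `volume`, `n_constraints`, `shift_rmsd`, `rank`,
#'   `perturbed_ensemble`), plus the unperturbed ensemble.
#' @export
perturb_and_rank <- function(a, b, pockets, base_cs, n_models_per = 250,
                             params = spe_params(), n_points = 120,
                             rigid_points = FALSE, unperturbed = NULL) {
  if (is.null(unperturbed)) {
    unperturbed <- generate_ensemble(base_cs, n_models_per, a, params)
  }
  cas <- ca_indices(a)
  res <- vector("list", length(pockets))
  for (k in seq_along(pockets)) {
    p <- pockets[[k]]
    pts <- sample_pocket_points(p, n_points,
                                seed = derive_seed(params$seed, 5000 + p$id))
    cs2 <- augment_constraints(base_cs, pts, a, rigid_points = rigid_points)
    pk <- params
    pk$seed <- derive_seed(params$seed, 7000 + p$id)
    pert <- generate_ensemble(cs2, n_models_per, a, pk)
    pooled <- pse_ensemble(a$atoms, c(unperturbed$models, pert$models))
    pooled <- iterative_align(pooled)
    nu <- n_models(unperturbed)
    avg_u <- Reduce(`+`, pooled$models[seq_len(nu)]) / nu
    avg_p <- Reduce(`+`, pooled$models[-seq_len(nu)]) / n_models(pert)
    res[[k]] <- list(pocket_id = p$id, volume = p$volume,
                     n_constraints = nrow(cs2$df) - nrow(base_cs$df),
                     shift_rmsd = rmsd_plain(avg_u, avg_p, cas),
                     perturbed_ensemble = pert)
  }
  shifts <- vapply(res, function(r) r$shift_rmsd, numeric(1))
  ids <- vapply(res, function(r) r$pocket_id, numeric(1))
  ord <- order(-shifts, ids)
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  for (k in seq_along(res)) res[[k]]$rank <- rk[k]
  structure(list(results = res, unperturbed = unperturbed),
            class = "pse_perturbation_ranking")
}

#' Ranking table of a perturbation run
#' @param ranking a `pse_perturbation_ranking`
#' @return data frame with pocket_id, volume, n_constraints, shift_rmsd, rank
#' @export
ranking_table <- function(ranking) {
  df <- do.call(rbind, lapply(ranking$results, function(r) {
    data.frame(pocket_id = r$pocket_id, volume = r$volume,
               n_constraints = r$n_constraints,
               shift_rmsd = r$shift_rmsd, rank = r$rank)
  }))
  df[order(df$rank), ]
}

#' Allosteric-pocket validation criterion
#'
#' A pocket counts as allosteric if its centre lies within `cutoff`
#' (6 A) of at least one atom of the known modulator.
#'
#' @param p a `pse_pocket`
#' @param modulator_atoms m x 3 coordinate matrix of modulator atoms.
#' @param cutoff distance cutoff, Angstroms (default 6).
#' @return logical
#' @export
is_allosteric_pocket <- function(p, modulator_atoms, cutoff = 6) {
  modulator_atoms <- matrix(as.numeric(modulator_atoms), ncol = 3)
  if (nrow(modulator_atoms) == 0) stop("empty modulator atom list")
  min(sqrt(colSums((t(modulator_atoms) - p$center)^2))) <= cutoff
}

#' Read pockets from a TSV of points
#'
#' Columns: x, y, z, pocket_id, volume (one row per point; volume is
#' repeated within a pocket). Centres are the point-cloud means.
#'
#' @param path TSV path
#' @return list of `pse_pocket`
#' @export
read_pockets_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  lapply(sort(unique(df$pocket_id)), function(id) {
    sub <- df[df$pocket_id == id, ]
    pts <- as.matrix(sub[, c("x", "y", "z")])
    pse_pocket(id, colMeans(pts), pts, sub$volume[1])
  })
}

#' Read pockets from PDB-format point files
#'
#' Accepts the common pocket-finder convention of one PDB-like file of
#' pseudo-atoms per pocket; every ATOM/HETATM coordinate becomes a
#' pocket point. Volumes are not part of the PDB format and must be
#' supplied alongside.
#'
#' @param paths character vector of PDB-like files, one pocket each.
#' @param volumes numeric vector of pocket volumes (Angstrom^3), same
#'   length as `paths`.
#' @return list of `pse_pocket` (ids in file order)
#' @export
read_pockets_pdb <- function(paths, volumes) {
  stopifnot(length(paths) == length(volumes))
  lapply(seq_along(paths), function(k) {
    lines <- readLines(paths[k], warn = FALSE)
    rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
    if (length(rec) == 0) stop("no points in pocket file ", paths[k])
    pts <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    pse_pocket(k, colMeans(pts), pts, volumes[k])
  })
}

#' Write pockets as a TSV of points
#' @param pockets list of `pse_pocket`
#' @param path output path
#' @return path, invisibly
#' @export
write_pockets_tsv <- function(pockets, path) {
  df <- do.call(rbind, lapply(pockets, function(p) {
    data.frame(x = p$points[, 1], y = p$points[, 2], z = p$points[, 3],
               pocket_id = p$id, volume = p$volume)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
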