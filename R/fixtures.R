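# Synthetic two-state hinge peptides: ideal covalent geometry, two helical
# arms joined by a three-residue loop, the conformations differing only by
# a rigid rotation of arm 2 about the hinge phi bond. Everything the
# pipeline needs (structures, pockets, modulator atoms) is generated in
# code, so no downloads or binary fixtures are required.

# natural extension reference frame: place D bonded to C with |CD| = r,
# angle(B,C,D) = theta and dihedral(A,B,C,D) = chi (degrees)
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c + d2[1] * bc + d2[2] * m - d2[3] * n
}

.aa1to3 <- c(A = "ALA", L = "LEU", K = "LYS", E = "GLU", G = "GLY")

.ideal <- list(
  n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5,
  # improper C'-N-CA-CB for an L-amino acid (places CB on the correct side)
  cb_improper = 122.5, ang_n_ca_cb = 110.4, ca_cb = 1.53
)

#' Hinge-peptide specification
#'
#' @param n_res_per_arm residues per helical arm (>= 5).
#' @param hinge_angle_a,hinge_angle_b hinge openings of the two
#'   conformations, degrees in (0, 180); the conformations differ by a
#'   rigid rotation of arm 2 by `hinge_angle_b - hinge_angle_a` about
#'   the hinge phi bond.
#' @param sequence one-letter sequence (A/L/K/E; NULL for the default
#'   helix-favouring pattern with i, i+4 Lys/Glu salt-bridge partners).
#' @param seed stored with the spec for provenance (construction itself
#'   is deterministic).
#' @return list of class `hinge_spec`
#' @export
hinge_spec <- function(n_res_per_arm = 11, hinge_angle_a = 50,
                       hinge_angle_b = 110, sequence = NULL, seed = 1L) {
  stopifnot(n_res_per_arm >= 5,
            hinge_angle_a > 0, hinge_angle_a < 180,
            hinge_angle_b > 0, hinge_angle_b < 180)
  n_total <- 2 * n_res_per_arm + 3
  if (is.null(sequence)) {
    arm <- substr(strrep("KALAE", ceiling(n_res_per_arm / 5)), 1, n_res_per_arm)
    sequence <- paste0(arm, "ALA", arm)
  }
  stopifnot(nchar(sequence) == n_total,
            all(strsplit(sequence, "")[[1]] %in% names(.aa1to3)))
  structure(list(n_res_per_arm = n_res_per_arm,
                 hinge_angle_a = hinge_angle_a,
                 hinge_angle_b = hinge_angle_b,
                 sequence = sequence, seed = seed),
            class = "hinge_spec")
}

build_peptide <- function(seq3, phi, psi, title = "") {
  nres <- length(seq3)
  stopifnot(length(phi) == nres, length(psi) == nres)
  id <- .ideal
  atoms <- list()
  pos <- list()  # per-residue named coordinate lists
  add <- function(r, name, xyz, element = substr(name, 1, 1)) {
    pos[[r]][[name]] <<- xyz
    atoms[[length(atoms) + 1]] <<- data.frame(
      record = "ATOM", serial = length(atoms) + 1L, name = name,
      altloc = " ", resname = seq3[r], chain = "A", resseq = r,
      icode = " ", x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      element = element, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nres)) {
    pos[[r]] <- list()
    if (r == 1) {
      N <- c(0, 0, 0)
      CA <- c(id$n_ca, 0, 0)
      th <- id$ang_n_ca_c * pi / 180
      C <- CA + c(-cos(th), sin(th), 0) * id$ca_c
    } else {
      p <- pos[[r - 1]]
      N <- nerf_place(p$N, p$CA, p$C, id$c_n, id$ang_ca_c_n, psi[r - 1])
      CA <- nerf_place(p$CA, p$C, N, id$n_ca, id$ang_c_n_ca, 180)  # omega
      C <- nerf_place(p$C, N, CA, id$ca_c, id$ang_n_ca_c, phi[r])
    }
    add(r, "N", N); add(r, "CA", CA); add(r, "C", C)
  }
  for (r in seq_len(nres)) {
    p <- pos[[r]]
    opsi <- if (r < nres) psi[r] else -47
    add(r, "O", nerf_place(p$N, p$CA, p$C, id$c_o, id$ang_ca_c_o, opsi + 180))
    sc <- sidechain_atoms(seq3[r], p)
    for (nm in names(sc)) add(r, nm, sc[[nm]])
  }
  df <- do.call(rbind, atoms)
  df <- df[canonical_order(df), , drop = FALSE]
  df$serial <- seq_len(nrow(df))
  rownames(df) <- NULL
  pse_structure(df, title = title)
}

sidechain_atoms <- function(resname, p) {
  id <- .ideal
  if (resname == "GLY") return(list())
  cb <- nerf_place(p$C, p$N, p$CA, id$ca_cb, id$ang_n_ca_cb, id$cb_improper)
  out <- list(CB = cb)
  chain <- function(prev3, bond, angle, chi) {
    nerf_place(prev3[[1]], prev3[[2]], prev3[[3]], bond, angle, chi)
  }
  if (resname == "LEU") {
    # tt rotamer: the common mt clashes with the preceding backbone O at
    # ideal helix torsions
    cg <- chain(list(p$N, p$CA, cb), 1.53, 114, 180)
    out$CG <- cg
    out$CD1 <- chain(list(p$CA, cb, cg), 1.53, 111, 180)
    out$CD2 <- chain(list(p$CA, cb, cg), 1.53, 111, -60)
  } else if (resname == "LYS") {
    # rotamer chosen so Lys(i) NZ meets Glu(i+4) OE at ~3.3 A on the helix
    # face, giving the fixture its salt bridges
    cg <- chain(list(p$N, p$CA, cb), 1.53, 114, 180)
    cd <- chain(list(p$CA, cb, cg), 1.53, 111, -60)
    ce <- chain(list(cb, cg, cd), 1.53, 111, 180)
    out$CG <- cg; out$CD <- cd; out$CE <- ce
    out$NZ <- chain(list(cg, cd, ce), 1.49, 112, 60)
  } else if (resname == "GLU") {
    cg <- chain(list(p$N, p$CA, cb), 1.53, 114, 60)
    cd <- chain(list(p$CA, cb, cg), 1.52, 114, 180)
    out$CG <- cg; out$CD <- cd
    out$OE1 <- chain(list(cb, cg, cd), 1.25, 118, 0)
    out$OE2 <- chain(list(cb, cg, cd), 1.25, 118, 180)
  }
  out
}

#' Generate the two conformations of an idealised hinge peptide
#'
#' Both structures share one atom roster and differ only in the phi
#' dihedral of the first arm-2 residue, i.e. a rigid rotation of arm 2
#' about the hinge C-N bond that preserves all covalent geometry. Arm
#' residues use ideal alpha-helix torsions (phi -57, psi -47); the
#' three-residue loop sits in the generic coil region (phi -70,
#' psi 150).
#'
#' @param spec a [hinge_spec]
#' @return list with elements `a` and `b` (`pse_structure`s)
#' @export
make_hinge_pair <- function(spec = hinge_spec()) {
  n <- spec$n_res_per_arm
  nres <- 2 * n + 3
  seq3 <- unname(.aa1to3[strsplit(spec$sequence, "")[[1]]])
  phi <- rep(-57, nres); psi <- rep(-47, nres)
  loop <- (n + 1):(n + 3)
  phi[loop] <- -70; psi[loop] <- 150
  hinge <- n + 4
  mk <- function(angle, tag) {
    ph <- phi; ph[hinge] <- -angle
    build_peptide(seq3, ph, psi, title = sprintf("hinge fixture %s", tag))
  }
  list(a = mk(spec$hinge_angle_a, "A"), b = mk(spec$hinge_angle_b, "B"))
}

arm_residues <- function(spec) {
  n <- spec$n_res_per_arm
  list(arm1 = 1:n, arm2 = (n + 4):(2 * n + 3))
}

min_dist_to <- function(points, xyz) {
  apply(points, 1, function(p) min(sqrt(colSums((t(xyz) - p)^2))))
}

#' Synthetic pockets for a hinge pair
#'
#' Builds one "bridging" pocket whose points reach atoms of BOTH arms
#' (in the hinge cleft) and `n_decoys` surface pockets touching only one
#' arm, all with volumes passing the 13 Angstrom^3 filter. Pocket
#' geometry is measured in conformation `a`. Pocket ids are assigned by
#' descending volume and the bridging pocket is deliberately not the
#' largest; its id is stored in the `bridging_id` attribute.
#'
#' @param pair output of [make_hinge_pair]
#' @param spec the [hinge_spec] used
#' @param n_decoys number of single-arm decoy pockets (default 3).
#' @param seed integer seed for point sampling.
#' @return list of `pse_pocket` with attribute `bridging_id`
#' @export
make_pockets <- function(pair, spec = hinge_spec(), n_decoys = 3, seed = 1L) {
  s <- pair$a
  xyz <- coords(s)
  ridx <- residue_index(s)
  arms <- arm_residues(spec)
  a1 <- which(ridx %in% arms$arm1)
  a2 <- which(ridx %in% arms$arm2)
  cas <- ca_indices(s)
  ca1 <- intersect(cas, a1); ca2 <- intersect(cas, a2)

  # bridging pocket: centre in the cleft, reachable (<= 5.5 A) from both arms
  cand <- expand.grid(i = ca1, j = ca2)
  mid <- (xyz[cand$i, , drop = FALSE] + xyz[cand$j, , drop = FALSE]) / 2
  d1 <- min_dist_to(mid, xyz[a1, , drop = FALSE])
  d2 <- min_dist_to(mid, xyz[a2, , drop = FALSE])
  dmin <- min_dist_to(mid, xyz)
  ok <- d1 <= 5.5 & d2 <= 5.5 & dmin >= 1.8
  if (!any(ok)) ok <- d1 <= 6.5 & d2 <= 6.5 & dmin >= 1.5
  sc <- pmax(d1, d2) - dmin  # prefer centres close to both arms yet unburied
  centre_b <- mid[which(ok)[which.min(sc[ok])], ]

  sample_cloud <- function(centre, n_keep, accept, seed_off) {
    pts <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(pts) < n_keep && tries < 60) {
      tries <- tries + 1
      raw <- with_seed(seed + 131 * seed_off + tries, {
        m <- matrix(rnorm(3 * 400), ncol = 3)
        m <- m / sqrt(rowSums(m^2)) * runif(400)^(1 / 3) * 2.2
        sweep(m, 2, centre, "+")
      })
      pts <- rbind(pts, raw[accept(raw), , drop = FALSE])
    }
    if (nrow(pts) < n_keep) stop("could not place pocket points")
    pts[seq_len(n_keep), , drop = FALSE]
  }

  accept_bridge <- function(p) {
    min_dist_to(p, xyz[a1, , drop = FALSE]) <= 7 &
      min_dist_to(p, xyz[a2, , drop = FALSE]) <= 7 &
      min_dist_to(p, xyz) >= 1.5
  }
  pts_b <- sample_cloud(centre_b, 150, accept_bridge, 1)

  decoys <- list()
  centroid <- colMeans(xyz)
  used_anchors <- integer(0)
  for (k in seq_len(n_decoys)) {
    own <- if (k %% 2 == 1) a1 else a2
    other <- if (k %% 2 == 1) a2 else a1
    own_ca <- intersect(cas, own)
    # anchor decoys near the middle of the arm (the stiff part of the
    # helix, like a surface patch on a packed domain), walking outward
    # until the decoy cannot reach the other arm
    mid <- stats::median(seq_along(own_ca))
    ord <- own_ca[order(abs(seq_along(own_ca) - mid))]
    far_enough <- min_dist_to(xyz[ord, , drop = FALSE],
                              xyz[other, , drop = FALSE]) > 8
    ord <- c(ord[far_enough], ord[!far_enough])
    ord <- setdiff(ord, used_anchors)
    centre_d <- NULL
    for (anchor in ord) {
      dir <- xyz[anchor, ] - centroid
      dir <- dir / sqrt(sum(dir^2))
      cd <- xyz[anchor, ] + 4.5 * dir
      if (min(sqrt(colSums((t(xyz[other, , drop = FALSE]) - cd)^2))) > 9.5) {
        centre_d <- cd
        used_anchors <- c(used_anchors, anchor)
        break
      }
    }
    if (is.null(centre_d)) stop("could not place decoy pocket ", k)
    accept_decoy <- function(p) {
      min_dist_to(p, xyz[own, , drop = FALSE]) <= 7 &
        min_dist_to(p, xyz[other, , drop = FALSE]) > 7.2 &
        min_dist_to(p, xyz) >= 1.5
    }
    decoys[[k]] <- sample_cloud(centre_d, 130, accept_decoy, 10 + k)
  }

  vols_decoy <- c(150, 60, 40, 30, 25, 20)[seq_len(n_decoys)]
  clouds <- c(list(pts_b), decoys)
  vols <- c(90, vols_decoy)
  ord <- order(-vols)
  pockets <- lapply(seq_along(ord), function(r) {
    k <- ord[r]
    pse_pocket(id = r, center = colMeans(clouds[[k]]),
               points = clouds[[k]], volume = vols[k])
  })
  attr(pockets, "bridging_id") <- which(ord == 1)
  pockets
}

#' Pseudo-modulator atom cluster for a pocket
#'
#' A rigid 10-atom cluster of diameter under 4 Angstroms centred on the
#' pocket centre, for exercising the 6 Angstrom allosteric validation
#' rule.
#'
#' @param pocket a `pse_pocket`
#' @return 10 x 3 coordinate matrix
#' @export
make_modulator_atoms <- function(pocket) {
  stopifnot(nrow(pocket$points) >= 1)
  offs <- rbind(c(0, 0, 0),
                expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)) * 0.8,
                c(1.4, 0, 0))
  sweep(as.matrix(offs), 2, pocket$center, "+")
}
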