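#' Interaction type table
#'
#' The fifteen atom-pair interaction classes used for constraint
#' generation, each with its distance tolerance in Angstroms. Types 1-14
#' are specific interactions; type 15 is the generic "all other pairs"
#' class whose large tolerance lets unrelated parts of the protein move.
#'
#' @return data frame with columns `code`, `name`, `tolerance`
#' @export
interaction_types <- function() {
  data.frame(
    code = 1:15,
    name = c("covalent bond", "bond angle", "ring", "double bond 1-4",
             "omega 1-4", "tight phi/psi 1-4", "loose phi/psi 1-4",
             "other phi/psi 1-4", "other 1-4", "secondary structure",
             "salt bridge", "hydrogen bond", "tight hydrophobic",
             "loose hydrophobic", "all other pairs"),
    tolerance = c(0.02, 0.05, 0.1, 0.1, 0.1, 0.2, 0.4, 0.3, 0.4, 0.5,
                  0.75, 0.5, 0.5, 1.0, 5.0),
    stringsAsFactors = FALSE
  )
}

.tolerances <- c(0.02, 0.05, 0.1, 0.1, 0.1, 0.2, 0.4, 0.3, 0.4, 0.5,
                 0.75, 0.5, 0.5, 1.0, 5.0)

#' Classify every atom pair into an interaction type
#'
#' Each pair is assigned the lowest-numbered interaction type whose
#' criterion it meets; pairs matching none of types 1-14 get the generic
#' type 15. Requires `sec_struct` to be assigned (types 6-8 and 10 depend
#' on it).
#'
#' @param s a `pse_structure` with secondary structure assigned.
#' @return symmetric integer matrix `n_atoms x n_atoms` of type codes
#'   (diagonal 0).
#' @export
classify_pairs <- function(s) {
  if (is.null(s$sec_struct)) stop("assign secondary structure first")
  a <- s$atoms
  n <- nrow(a)
  xyz <- coords(s)
  ridx <- residue_index(s)
  ss <- s$sec_struct
  segid <- ss_segments(s)
  types <- matrix(15L, n, n)
  diag(types) <- 0L

  set_type <- function(i, j, t) {
    # lowest-numbered matching criterion wins
    idx <- cbind(c(i, j), c(j, i))
    cur <- types[idx]
    types[idx] <<- pmin(cur, as.integer(t))
  }

  bonds <- covalent_bonds(s)
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }

  # type 1: covalent
  set_type(bonds[, 1], bonds[, 2], 1L)

  # type 2: both bonded to the same atom (1-3)
  for (b in seq_len(n)) {
    nb <- nbrs[[b]]
    if (length(nb) > 1) {
      cmb <- utils::combn(nb, 2)
      set_type(cmb[1, ], cmb[2, ], 2L)
    }
  }

  # type 3: rings
  for (r in unique(ridx)) {
    rn <- a$resname[match(r, ridx)]
    ring <- .ring_atoms[[rn]]
    if (!is.null(ring)) {
      idx <- which(ridx == r & a$name %in% ring)
      if (length(idx) > 1) {
        cmb <- utils::combn(idx, 2)
        set_type(cmb[1, ], cmb[2, ], 3L)
      }
    }
  }

  # types 4-9: 1-4 pairs classified by the central bond of the a-b-c-d path
  for (k in seq_len(nrow(bonds))) {
    b <- bonds[k, 1]; cc <- bonds[k, 2]
    aa <- setdiff(nbrs[[b]], cc)
    dd <- setdiff(nbrs[[cc]], b)
    if (length(aa) == 0 || length(dd) == 0) next
    t14 <- central_bond_class(b, cc, a, ridx, ss)
    for (ai in aa) for (di in dd) {
      if (ai == di) next
      tt <- t14
      if (t14 %in% c(6L, 7L, 8L)) tt <- phi_psi_subclass(ai, di, a, ridx, ss)
      set_type(ai, di, tt)
    }
  }

  # distance-dependent classes share one cutoff-limited neighbour search
  dmat <- as.matrix(stats::dist(xyz))

  # type 10: backbone pairs in the same helix/strand segment, <= 4 residues
  bb_atoms <- which(a$name %in% c("N", "CA", "C", "O"))
  if (length(bb_atoms) > 1) {
    seg <- segid[ridx[bb_atoms]]
    lab <- ss[ridx[bb_atoms]]
    cmb <- utils::combn(seq_along(bb_atoms), 2)
    i <- bb_atoms[cmb[1, ]]; j <- bb_atoms[cmb[2, ]]
    ok <- lab[cmb[1, ]] %in% c("H", "E") &
      seg[cmb[1, ]] == seg[cmb[2, ]] &
      abs(ridx[i] - ridx[j]) <= 4
    if (any(ok)) set_type(i[ok], j[ok], 10L)
  }

  # type 11: salt bridges < 4 A
  pos <- charged_atoms(a, ridx, .salt_positive)
  neg <- c(charged_atoms(a, ridx, .salt_negative), which(a$name == "OXT"))
  if (length(pos) && length(neg)) {
    grid <- expand.grid(i = pos, j = neg)
    grid <- grid[grid$i != grid$j, ]
    ok <- dmat[cbind(grid$i, grid$j)] < 4
    if (any(ok)) set_type(grid$i[ok], grid$j[ok], 11L)
  }

  # type 12: hydrogen bonds, heavy-atom criterion (no explicit hydrogens):
  # donor-acceptor <= 3.5 A and antecedent-donor-acceptor angle >= 90 deg
  dons <- donor_atoms(s, nbrs)
  accs <- acceptor_atoms(a, ridx)
  if (nrow(dons) && length(accs)) {
    for (k in seq_len(nrow(dons))) {
      d <- dons$donor[k]; ante <- dons$ante[k]
      close_acc <- accs[dmat[d, accs] <= 3.5 & accs != d & accs != ante]
      for (acc in close_acc) {
        v1 <- xyz[ante, ] - xyz[d, ]; v2 <- xyz[acc, ] - xyz[d, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= 90) set_type(d, acc, 12L)
      }
    }
  }

  # types 13/14: hydrophobic C..C pairs (H absent by construction)
  carb <- which(a$element == "C")
  if (length(carb) > 1) {
    cmb <- utils::combn(carb, 2)
    dd <- dmat[cbind(cmb[1, ], cmb[2, ])]
    thr <- 2 * .vdw_radii[["C"]]
    tight <- dd < thr + 0.5
    loose <- !tight & dd < thr + 1.0
    if (any(tight)) set_type(cmb[1, tight], cmb[2, tight], 13L)
    if (any(loose)) set_type(cmb[1, loose], cmb[2, loose], 14L)
  }

  types
}

ss_segments <- function(s) {
  ss <- s$sec_struct
  a <- s$atoms
  rid <- paste(a$chain, a$resseq, a$icode, sep = "|")
  chain_of <- a$chain[match(unique(rid), rid)]
  brk <- c(TRUE, ss[-1] != ss[-length(ss)] |
             chain_of[-1] != chain_of[-length(chain_of)])
  cumsum(brk)
}

central_bond_class <- function(b, cc, a, ridx, ss) {
  nb <- a$name[b]; nc <- a$name[cc]
  rb <- ridx[b]; rc <- ridx[cc]
  pair <- sort(c(nb, nc))
  if (rb == rc) {
    rn <- a$resname[b]
    dbl <- .double_bond_central[[rn]]
    if (!is.null(dbl)) {
      for (bd in dbl) if (identical(sort(bd), pair)) return(4L)
    }
    if (identical(pair, c("CA", "N")) || identical(pair, c("C", "CA"))) {
      return(6L)  # phi/psi; subclass resolved per pair
    }
  } else if (abs(rb - rc) == 1 && identical(pair, c("C", "N"))) {
    return(5L)  # omega
  }
  9L
}

phi_psi_subclass <- function(ai, di, a, ridx, ss) {
  res <- c(ridx[ai], ridx[di])
  rn <- a$resname[c(ai, di)]
  lab <- ss[res]
  if (any(rn == "PRO")) return(6L)
  if (all(lab == "H") || all(lab == "E")) return(6L)
  if (any(rn == "GLY")) return(7L)
  if (all(lab == "C")) return(7L)
  8L
}

charged_atoms <- function(a, ridx, table) {
  idx <- integer(0)
  for (rn in names(table)) {
    idx <- c(idx, which(a$resname == rn & a$name %in% table[[rn]]))
  }
  idx
}

donor_atoms <- function(s, nbrs) {
  a <- s$atoms
  # backbone N (except proline, whose N has no H): antecedent CA
  bbn <- which(a$name == "N" & a$resname != "PRO")
  ridx <- residue_index(s)
  don <- data.frame(donor = integer(0), ante = integer(0))
  for (d in bbn) {
    ca <- which(ridx == ridx[d] & a$name == "CA")
    if (length(ca) == 1) don <- rbind(don, data.frame(donor = d, ante = ca))
  }
  for (rn in names(.side_donors)) {
    for (da in .side_donors[[rn]]) {
      dd <- which(a$resname == rn & a$name == da[1])
      for (d in dd) {
        ante <- which(ridx == ridx[d] & a$name == da[2])
        if (length(ante) == 1) {
          don <- rbind(don, data.frame(donor = d, ante = ante))
        }
      }
    }
  }
  don
}

acceptor_atoms <- function(a, ridx) {
  idx <- which(a$name %in% c("O", "OXT"))
  for (rn in names(.side_acceptors)) {
    idx <- c(idx, which(a$resname == rn & a$name %in% .side_acceptors[[rn]]))
  }
  sort(unique(idx))
}

#' Distance bounds for one atom pair
#'
#' Bounds are the observed distance plus/minus the interaction tolerance
#' scaled by the global tolerance weight `wb`: lower = d - wb * t,
#' upper = d + wb * t. A non-positive lower bound (conceivable only for
#' the generic class at small distances) is clamped to d / 2.
#'
#' @param d observed interatomic distance, Angstroms (> 0).
#' @param itype interaction type code 1-15.
#' @param wb tolerance weight in \[0, 1\].
#' @return numeric vector `c(lower, upper)` in Angstroms.
#' @export
make_bounds <- function(d, itype, wb) {
  stopifnot(all(d > 0), all(itype %in% 1:15), all(wb >= 0), all(wb <= 1))
  t <- .tolerances[itype]
  lower <- d - wb * t
  lower[lower <= 0] <- 0.5 * d[lower <= 0]
  c(lower = unname(lower), upper = unname(d + wb * t))
}

#' Combine the bounds of one atom pair across two structures
#'
#' The combined interval covers both input intervals (min of lowers, max
#' of uppers) so that both conformations satisfy the result; the type is
#' the tighter (lower-numbered) of the two.
#'
#' @param c1,c2 lists/rows with fields `i`, `j`, `lower`, `upper`, `type`.
#' @return list with fields `i`, `j`, `lower`, `upper`, `type`.
#' @export
combine_bounds <- function(c1, c2) {
  if (c1$i != c2$i || c1$j != c2$j) stop("constraints are for different atom pairs")
  list(i = c1$i, j = c1$j,
       lower = min(c1$lower, c2$lower),
       upper = max(c1$upper, c2$upper),
       type = min(c1$type, c2$type))
}

#' Constraint set container
#' @param df data frame with columns `i`, `j`, `lower`, `upper`, `type`.
#' @param n_atoms number of embedded points the indices refer to.
#' @param wb tolerance weight used.
#' @param seed RNG seed used for generic-pair subsampling.
#' @return object of class `pse_constraint_set`
#' @export
pse_constraint_set <- function(df, n_atoms, wb, seed = NA_integer_) {
  stopifnot(all(c("i", "j", "lower", "upper", "type") %in% names(df)))
  stopifnot(all(df$i < df$j), all(df$j <= n_atoms), all(df$lower > 0),
            all(df$lower <= df$upper))
  if (anyDuplicated(paste(df$i, df$j))) stop("duplicate atom pair in constraint set")
  structure(list(df = df, n_atoms = as.integer(n_atoms), wb = wb, seed = seed),
            class = "pse_constraint_set")
}

#' @export
print.pse_constraint_set <- function(x, ...) {
  cat(sprintf("<pse_constraint_set> %d constraints over %d atoms (wb=%s)\n",
              nrow(x$df), x$n_atoms, format(x$wb)))
  invisible(x)
}

#' Subsample generic ("all other") pairs
#'
#' Generic pairs vastly outnumber specific ones (N_A^2 vs N_A), so each is
#' retained independently with probability p = min(1, 20 n_atoms / n_pairs),
#' making the expected retained count about 20 per atom.
#'
#' @param pairs data frame of candidate generic pairs.
#' @param n_atoms atom count N_A.
#' @param seed integer seed (deterministic subsets).
#' @return retained subset of `pairs`.
#' @export
subsample_other_pairs <- function(pairs, n_atoms, seed) {
  npairs <- nrow(pairs)
  if (npairs == 0) return(pairs)
  p <- min(1, 20 * n_atoms / npairs)
  if (p >= 1) return(pairs)
  keep <- with_seed(seed, runif(npairs) < p)
  pairs[keep, , drop = FALSE]
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Build the combined constraint set from two conformations
#'
#' Pairs are classified independently in each structure, per-structure
#' bounds are built with the shared tolerance weight, and the two
#' intervals are merged so both conformations satisfy every constraint.
#' Pairs generic (type 15) in BOTH structures are subsampled to about
#' 20 per atom; a pair specific in either structure is always kept.
#'
#' @param a,b atom-intersected `pse_structure` pair in canonical order,
#'   with secondary structure assigned.
#' @param wb tolerance weight in \[0, 1\].
#' @param seed integer seed for generic-pair subsampling.
#' @return a [pse_constraint_set]
#' @export
build_constraint_set <- function(a, b, wb, seed = 1L) {
  stopifnot(identical(atom_keys(a$atoms), atom_keys(b$atoms)))
  n <- n_atoms(a)
  ta <- classify_pairs(a)
  tb <- classify_pairs(b)
  iu <- which(upper.tri(ta))
  i <- row(ta)[iu]; j <- col(ta)[iu]
  tolv <- .tolerances
  da <- as.matrix(stats::dist(coords(a)))[iu]
  db <- as.matrix(stats::dist(coords(b)))[iu]
  tya <- ta[iu]; tyb <- tb[iu]
  la <- da - wb * tolv[tya]; la[la <= 0] <- 0.5 * da[la <= 0]
  ua <- da + wb * tolv[tya]
  lb <- db - wb * tolv[tyb]; lb[lb <= 0] <- 0.5 * db[lb <= 0]
  ub <- db + wb * tolv[tyb]
  df <- data.frame(i = i, j = j,
                   lower = pmin(la, lb), upper = pmax(ua, ub),
                   type = pmin(tya, tyb))
  generic <- df$type == 15L
  kept <- rbind(df[!generic, , drop = FALSE],
                subsample_other_pairs(df[generic, , drop = FALSE], n, seed))
  kept <- kept[order(kept$i, kept$j), , drop = FALSE]
  rownames(kept) <- NULL
  pse_constraint_set(kept, n_atoms = n, wb = wb, seed = seed)
}

#' Build a single-structure constraint set
#'
#' Degenerate case of [build_constraint_set] used when only one input
#' conformation is available (the perturbation-only workflow).
#'
#' @inheritParams build_constraint_set
#' @param s the input `pse_structure` (sec_struct assigned).
#' @return a [pse_constraint_set]
#' @export
build_constraint_set_single <- function(s, wb, seed = 1L) {
  build_constraint_set(s, s, wb, seed)
}

#' Write a constraint set as TSV
#' @param cs a `pse_constraint_set`
#' @param path output path
#' @return path, invisibly
#' @export
write_constraints <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_atoms=%d wb=%s seed=%s", cs$n_atoms,
                     format(cs$wb), format(cs$seed)), con)
  write.table(cs$df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a constraint set from TSV
#' @param path TSV written by [write_constraints]
#' @return a `pse_constraint_set`
#' @export
read_constraints <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eNA]+", hdr))[[1]]
  vals <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1)
  pse_constraint_set(df, n_atoms = as.integer(vals[["n_atoms"]]),
                     wb = as.numeric(vals[["wb"]]),
                     seed = suppressWarnings(as.integer(vals[["seed"]])))
}
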