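# Shared fixtures, built once per test run. The tiny pair keeps unit
# tests fast; the default 25-residue pair is used where the acceptance
# criteria prescribe it.

tiny_spec <- hinge_spec(n_res_per_arm = 6,
                        sequence = paste0("KALAEA", "ALA", "KALAEA"))
tiny_pair_raw <- make_hinge_pair(tiny_spec)
tiny_a <- assign_secondary_structure(tiny_pair_raw$a)
tiny_b <- assign_secondary_structure(tiny_pair_raw$b)

default_spec <- hinge_spec()
default_pair_raw <- make_hinge_pair(default_spec)
default_a <- assign_secondary_structure(default_pair_raw$a)
default_b <- assign_secondary_structure(default_pair_raw$b)

# fast embedding parameters for tests of mechanics (not of convergence)
fast_params <- function(seed = 1L) {
  spe_params(iterations_per_atom = 6000, seed = seed)
}

# independent R-level error-score oracle: double loop over constraints
error_score_oracle <- function(xyz, cs) {
  s <- 0
  for (k in seq_len(nrow(cs$df))) {
    i <- cs$df$i[k]; j <- cs$df$j[k]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    v <- max(0, cs$df$lower[k] - d, d - cs$df$upper[k])
    s <- s + v^2
  }
  s
}

# a lone phenylalanine with an idealised hexagonal ring, for ring-type
# tests (six-rings have genuine 1-4 pairs across the ring)
mini_phe <- function() {
  nrf <- protsemble:::nerf_place
  N <- c(0, 0, 0); CA <- c(1.46, 0, 0)
  C <- CA + 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  O <- nrf(N, CA, C, 1.23, 120.5, 133)
  CB <- nrf(C, N, CA, 1.53, 110.4, 122.5)
  CG <- nrf(N, CA, CB, 1.5, 114, 180)
  # regular hexagon of side 1.39 in the plane through CG
  ax <- CG - CB; ax <- ax / sqrt(sum(ax^2))
  perp <- c(-ax[2], ax[1], 0); perp <- perp / sqrt(sum(perp^2))
  ctr <- CG + 1.39 * ax
  hex <- function(theta) ctr + 1.39 * (cos(theta) * (-ax) + sin(theta) * perp)
  ringpos <- lapply(seq(0, 5) * pi / 3, hex)
  nm <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  xyz <- rbind(N, CA, C, O, CB, do.call(rbind, ringpos))
  df <- data.frame(record = "ATOM", serial = seq_along(nm), name = nm,
                   altloc = " ", resname = "PHE", chain = "A", resseq = 1L,
                   icode = " ", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occ = 1, element = substr(nm, 1, 1),
                   stringsAsFactors = FALSE)
  df <- df[protsemble:::canonical_order(df), ]
  s <- pse_structure(df, title = "mini phe")
  s$sec_struct <- "C"
  s
}

# minimal DSSP-format text for a structure, one code per residue
write_dssp_stub <- function(s, codes, path) {
  a <- s$atoms
  rid <- unique(paste(a$chain, a$resseq, a$icode, sep = "|"))
  stopifnot(length(codes) == length(rid))
  parts <- strsplit(rid, "\\|")
  lines <- c("==== Secondary Structure Definition, stub ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             vapply(seq_along(rid), function(k) {
               sprintf("%5d%5s%1s%1s %1s  %1s",
                       k, parts[[k]][2], parts[[k]][3], parts[[k]][1], "A",
                       codes[k])
             }, character(1)))
  writeLines(lines, path)
  path
}
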