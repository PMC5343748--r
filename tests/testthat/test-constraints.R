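test_that("interaction type table carries the canonical tolerances", {
  tab <- interaction_types()
  expect_equal(tab$tolerance,
               c(0.02, 0.05, 0.1, 0.1, 0.1, 0.2, 0.4, 0.3, 0.4, 0.5,
                 0.75, 0.5, 0.5, 1.0, 5.0))
  expect_equal(tab$code, 1:15)
})

test_that("classify_pairs assigns the expected classes on the fixture", {
  s <- tiny_a
  ty <- classify_pairs(s)
  a <- s$atoms
  ridx <- residue_index(s)
  at <- function(r, nm) which(ridx == r & a$name == nm)
  # covalent bond: backbone N-CA
  expect_equal(ty[at(2, "N"), at(2, "CA")], 1L)
  # bond angle: N and C both bonded to CA
  expect_equal(ty[at(2, "N"), at(2, "C")], 2L)
  # omega 1-4: CA(i)..CA(i+1) across the peptide bond
  expect_equal(ty[at(2, "CA"), at(3, "CA")], 5L)
  # salt bridge: Lys NZ to Glu OE at ~3.3 A
  i <- at(1, "NZ"); j <- at(5, "OE2")
  expect_lt(sqrt(sum((coords(s)[i, ] - coords(s)[j, ])^2)), 4)
  expect_equal(ty[i, j], 11L)
  # backbone pairs inside one helix, <= 4 residues apart: the secondary
  # structure class (10) outranks the hydrogen bond class (12)
  expect_equal(ty[at(2, "O"), at(6, "N")], 10L)
  expect_equal(ty[at(2, "CA"), at(6, "CA")], 10L)
  # hydrogen bonds still appear where type 10 does not reach, and every
  # type-12 pair meets the heavy-atom donor-acceptor criterion
  hb <- which(ty == 12L & upper.tri(ty), arr.ind = TRUE)
  expect_gt(nrow(hb), 0)
  dmat <- as.matrix(dist(coords(s)))
  expect_true(all(dmat[hb] <= 3.5))
  # all other pairs: across the two arms
  expect_equal(ty[at(1, "CA"), at(15, "CA")], 15L)
  # symmetry and empty diagonal
  expect_identical(ty, t(ty))
  expect_true(all(diag(ty) == 0L))
})

test_that("ring systems are classified as type 3", {
  s <- mini_phe()
  ty <- classify_pairs(s)
  a <- s$atoms
  at <- function(nm) which(a$name == nm)
  # bonded and angle ring pairs take the lower-numbered classes
  expect_equal(ty[at("CG"), at("CD1")], 1L)
  expect_equal(ty[at("CD1"), at("CD2")], 2L)
  # para pairs across the six-ring are 1-4 paths but the ring class wins
  expect_equal(ty[at("CG"), at("CZ")], 3L)
  expect_equal(ty[at("CD1"), at("CE2")], 3L)
  # CB is not a ring atom: CB..CE1 is a plain 1-4 (type 9)
  expect_equal(ty[at("CB"), at("CE1")], 9L)
})

test_that("make_bounds applies tolerance scaling and clamping", {
  expect_equal(make_bounds(1.54, 1L, 0.5), c(lower = 1.53, upper = 1.55))
  expect_equal(make_bounds(3.7, 9L, 0), c(lower = 3.7, upper = 3.7))
  expect_equal(make_bounds(3.0, 14L, 1.0), c(lower = 2.0, upper = 4.0))
  # clamp: type 15 at small distance
  b <- make_bounds(0.8, 15L, 1.0)
  expect_equal(unname(b["lower"]), 0.4)
  expect_gt(b["lower"], 0)
  expect_error(make_bounds(-1, 1L, 0.5))
  expect_error(make_bounds(1.5, 1L, 2))
})

test_that("combine_bounds covers both intervals and keeps the tighter class", {
  c1 <- list(i = 3L, j = 9L, lower = 6.0, upper = 7.0, type = 12L)
  c2 <- list(i = 3L, j = 9L, lower = 6.5, upper = 7.5, type = 15L)
  cc <- combine_bounds(c1, c2)
  expect_equal(cc$lower, 6.0)
  expect_equal(cc$upper, 7.5)
  expect_equal(cc$type, 12L)
  expect_identical(combine_bounds(c1, c1)[c("lower", "upper")],
                   c1[c("lower", "upper")])
  c3 <- list(i = 3L, j = 9L, lower = 2.0, upper = 3.0, type = 14L)
  c4 <- list(i = 3L, j = 9L, lower = 5.0, upper = 6.0, type = 14L)
  expect_equal(combine_bounds(c3, c4)[c("lower", "upper")],
               list(lower = 2.0, upper = 6.0))
  expect_error(combine_bounds(c1, list(i = 1L, j = 2L, lower = 1, upper = 2,
                                       type = 1L)), "different atom pairs")
})

test_that("build_constraint_set combines per-structure bounds", {
  cs0 <- build_constraint_set(tiny_a, tiny_b, 0, seed = 5)
  da <- as.matrix(dist(coords(tiny_a)))
  db <- as.matrix(dist(coords(tiny_b)))
  ij <- cbind(cs0$df$i, cs0$df$j)
  expect_equal(cs0$df$lower, pmin(da[ij], db[ij]), tolerance = 1e-12)
  expect_equal(cs0$df$upper, pmax(da[ij], db[ij]), tolerance = 1e-12)

  # a == b at wb = 0.5: per-pair bounds equal single-structure make_bounds
  cs1 <- build_constraint_set(tiny_a, tiny_a, 0.5, seed = 5)
  ty <- classify_pairs(tiny_a)
  ij <- cbind(cs1$df$i, cs1$df$j)
  tol <- interaction_types()$tolerance[ty[ij]]
  expect_equal(cs1$df$lower, pmax(da[ij] - 0.5 * tol,
                                  ifelse(da[ij] - 0.5 * tol <= 0,
                                         0.5 * da[ij], -Inf)), tolerance = 1e-12)
  expect_equal(cs1$df$upper, da[ij] + 0.5 * tol, tolerance = 1e-12)
})

test_that("combined constraints are satisfied by both inputs and contain both intervals", {
  for (wb in c(0, 0.3, 1)) {
    cs <- build_constraint_set(default_a, default_b, wb, seed = 2)
    expect_equal(error_score(coords(default_a), cs), 0)
    expect_equal(error_score(coords(default_b), cs), 0)
  }
  # superset property on a random subsample of pairs
  cs <- build_constraint_set(default_a, default_b, 0.4, seed = 2)
  da <- as.matrix(dist(coords(default_a)))
  db <- as.matrix(dist(coords(default_b)))
  ta <- classify_pairs(default_a); tb <- classify_pairs(default_b)
  tol <- interaction_types()$tolerance
  rows <- withr::with_seed(3, sample(nrow(cs$df), 500))
  for (k in rows) {
    i <- cs$df$i[k]; j <- cs$df$j[k]
    la <- da[i, j] - 0.4 * tol[ta[i, j]]
    lb <- db[i, j] - 0.4 * tol[tb[i, j]]
    expect_lte(cs$df$lower[k], max(min(la, lb), 0.5 * min(da[i, j], db[i, j])))
    expect_gte(cs$df$upper[k], max(da[i, j] + 0.4 * tol[ta[i, j]],
                                   db[i, j] + 0.4 * tol[tb[i, j]]) - 1e-12)
  }
})

test_that("generic pairs are subsampled to about 20 per atom", {
  n_atoms <- 500
  npairs <- 200000
  pairs <- data.frame(i = rep(1L, npairs), j = seq_len(npairs) + 1L)
  kept <- subsample_other_pairs(pairs, n_atoms, seed = 11)
  p <- 20 * n_atoms / npairs
  expect_equal(p, 0.05)
  mu <- npairs * p
  sigma <- sqrt(npairs * p * (1 - p))
  expect_lt(abs(nrow(kept) - mu), 3 * sigma)
  # determinism and the p >= 1 branch
  expect_identical(kept, subsample_other_pairs(pairs, n_atoms, seed = 11))
  small <- pairs[1:100, ]
  expect_identical(subsample_other_pairs(small, n_atoms, seed = 1), small)
})

test_that("specific constraints scale with atoms; generic stay near 20 per atom", {
  specs <- list(hinge_spec(n_res_per_arm = 6, sequence = NULL),
                hinge_spec(n_res_per_arm = 12, sequence = NULL))
  counts <- vapply(specs, function(sp) {
    pr <- make_hinge_pair(sp)
    aa <- assign_secondary_structure(pr$a)
    bb <- assign_secondary_structure(pr$b)
    cs <- build_constraint_set(aa, bb, 0.5, seed = 1)
    c(n = n_atoms(aa), spec = sum(cs$df$type < 15), gen = sum(cs$df$type == 15))
  }, numeric(3))
  ratio_atoms <- counts["n", 2] / counts["n", 1]
  ratio_spec <- counts["spec", 2] / counts["spec", 1]
  # specific interactions grow roughly linearly with atom count
  expect_lt(abs(ratio_spec / ratio_atoms - 1), 0.5)
  # generic pairs after subsampling: about 20 per atom (binomial spread)
  for (k in 1:2) {
    expect_lt(abs(counts["gen", k] - 20 * counts["n", k]),
              4 * sqrt(20 * counts["n", k]) + 0.05 * 20 * counts["n", k])
  }
})

test_that("constraint sets round-trip through TSV", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.3, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(cs, path)
  cs2 <- read_constraints(path)
  expect_equal(cs2$df, cs$df, tolerance = 1e-12)
  expect_equal(cs2$n_atoms, cs$n_atoms)
  expect_equal(cs2$wb, cs$wb)
})
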