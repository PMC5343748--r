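test_that("kabsch_superpose recovers rigid motions and matches a search oracle", {
  xyz <- coords(tiny_a)
  expect_equal(kabsch_superpose(xyz, xyz)$rmsd, 0, tolerance = 1e-10)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- xyz %*% rot + matrix(c(3, 4, -5), nrow(xyz), 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, xyz)
  expect_lt(fit$rmsd, 1e-8)

  # 4-point toy sets: optimal RMSD equals a brute-force search over
  # rotations (Euler grid + local refinement), translations at centroids
  p <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
  q <- rbind(c(0.1, 0, 0), c(2, 0.2, 0), c(-0.2, 2.8, 0.3), c(0, 0.1, 4.2))
  got <- kabsch_superpose(p, q)$rmsd
  rot_rmsd <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1]); cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    R <- matrix(c(cy * cz, -cy * sz, sy,
                  cx * sz + sx * sy * cz, cx * cz - sx * sy * sz, -sx * cy,
                  sx * sz - cx * sy * cz, sx * cz + cx * sy * sz, cx * cy),
                3, 3, byrow = TRUE)
    pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
    sqrt(mean(rowSums((pc %*% t(R) - qc)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 9),
                                b = seq(0, 2 * pi, length.out = 9),
                                c = seq(0, 2 * pi, length.out = 9)))
  vals <- apply(grid, 1, rot_rmsd)
  best <- stats::optim(grid[which.min(vals), ], rot_rmsd,
                       control = list(reltol = 1e-14, maxit = 5000))$value
  expect_equal(got, best, tolerance = 1e-3)

  # degenerate (collinear) subsets are rejected
  lin <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(lin + 0, lin), "collinear")
})

test_that("iterative_align converges without a reference", {
  xyz <- coords(tiny_a)
  rots <- withr::with_seed(4, lapply(1:5, function(k) {
    th <- runif(3, 0, 2 * pi)
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
    rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    xyz %*% (rx %*% rz) + matrix(runif(3, -9, 9), nrow(xyz), 3, byrow = TRUE)
  }))
  e <- iterative_align(pse_ensemble(tiny_a$atoms, rots))
  expect_true(e$aligned)
  for (k in 2:5) expect_lt(rmsd_plain(e$models[[1]], e$models[[k]]), 1e-6)

  # idempotence: a converged ensemble is a fixed point
  e2 <- iterative_align(e)
  for (k in 1:5) expect_lt(rmsd_plain(e$models[[k]], e2$models[[k]]), 1e-6)
})

test_that("the ensemble average is permutation invariant and equals the oracle", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e <- iterative_align(generate_ensemble(cs, 8, tiny_a, fast_params(seed = 3)))
  avg <- average_structure(e)
  # brute-force per-coordinate loop
  man <- e$models[[1]] * 0
  for (m in e$models) man <- man + m
  expect_equal(avg, man / n_models(e), tolerance = 1e-12)

  perm <- withr::with_seed(9, sample(n_models(e)))
  ep <- iterative_align(pse_ensemble(e$roster, e$models[perm]))
  expect_lt(rmsd_fit(average_structure(ep), avg), 1e-4)

  # unaligned ensembles are refused
  raw <- pse_ensemble(e$roster, e$models)
  expect_error(average_structure(raw), "aligned")
  # two-model midpoint
  e2 <- pse_ensemble(e$roster, e$models[1:2], aligned = TRUE)
  expect_equal(average_structure(e2), (e$models[[1]] + e$models[[2]]) / 2)
})

test_that("pca matches the covariance oracle and conserves variance", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e <- iterative_align(generate_ensemble(cs, 10, tiny_a, fast_params(seed = 5)))
  pc <- pca_ensemble(e)
  cas <- which(e$roster$name == "CA")
  x <- t(vapply(e$models, function(m) as.vector(t(m[cas, ])),
                numeric(3 * length(cas))))
  # brute-force double loop over the covariance definition
  mu <- colMeans(x)
  n3 <- ncol(x)
  cov_o <- matrix(0, n3, n3)
  for (i in seq_len(n3)) for (j in seq_len(n3)) {
    cov_o[i, j] <- mean((x[, i] - mu[i]) * (x[, j] - mu[j]))
  }
  recon <- pc$eigenvectors %*% diag(pc$eigenvalues) %*% t(pc$eigenvectors)
  expect_equal(recon, cov_o, tolerance = 1e-10)
  # eigenvalue/trace conservation and orthonormality
  expect_equal(sum(pc$eigenvalues), sum(diag(cov_o)), tolerance = 1e-8)
  expect_equal(crossprod(pc$eigenvectors), diag(n3), tolerance = 1e-8)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))

  # completeness: projections onto all PCs reconstruct each member exactly
  for (k in c(1, n_models(e))) {
    proj <- vapply(seq_len(n3), function(c2) project_onto_pc(e$models[[k]],
                                                             pc, c2),
                   numeric(1))
    rec <- pc$mean + as.vector(pc$eigenvectors %*% proj)
    expect_equal(rec, as.vector(t(e$models[[k]][cas, ])), tolerance = 1e-8)
  }
})

test_that("pca handles degenerate ensembles", {
  # variation along one atom's x-coordinate only
  base <- coords(tiny_a)
  models <- lapply(c(-1, 0, 1), function(s) {
    m <- base; m[ca_indices(tiny_a)[2], 1] <- m[ca_indices(tiny_a)[2], 1] + s
    m
  })
  e <- pse_ensemble(tiny_a$atoms, models, aligned = TRUE)
  pc <- pca_ensemble(e)
  expect_equal(pc$variance_fractions[1], 1, tolerance = 1e-10)
  expect_lt(pc$eigenvalues[2], 1e-12)

  # rigid ensemble: all eigenvalues zero
  er <- pse_ensemble(tiny_a$atoms, replicate(3, base, simplify = FALSE),
                     aligned = TRUE)
  expect_true(all(pca_ensemble(er)$eigenvalues < 1e-12))
})

test_that("projections behave like orthonormal coordinates", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e <- iterative_align(generate_ensemble(cs, 6, tiny_a, fast_params(seed = 9)))
  pc <- pca_ensemble(e)
  cas <- which(e$roster$name == "CA")
  mean_xyz <- coords(tiny_a)
  mean_xyz[cas, ] <- matrix(pc$mean, ncol = 3, byrow = TRUE)
  for (k in 1:3) expect_equal(project_onto_pc(mean_xyz, pc, k), 0,
                              tolerance = 1e-10)
  shifted <- mean_xyz
  shifted[cas, ] <- shifted[cas, ] +
    matrix(pc$eigenvectors[, 2], ncol = 3, byrow = TRUE)
  expect_equal(project_onto_pc(shifted, pc, 2), 1, tolerance = 1e-8)
  expect_equal(project_onto_pc(shifted, pc, 1), 0, tolerance = 1e-8)
  # random structure equals the brute-force dot product
  rnd <- withr::with_seed(2, mean_xyz + matrix(rnorm(length(mean_xyz)),
                                               ncol = 3))
  man <- sum((as.vector(t(rnd[cas, ])) - pc$mean) * pc$eigenvectors[, 3])
  expect_equal(project_onto_pc(rnd, pc, 3), man, tolerance = 1e-12)
})

test_that("rmsf and rmsf_ratio follow their definitions", {
  base <- coords(tiny_a)
  cas <- ca_indices(tiny_a)
  # rigid ensemble: zero MSF everywhere
  er <- pse_ensemble(tiny_a$atoms, replicate(4, base, simplify = FALSE),
                     aligned = TRUE)
  expect_true(all(rmsf(er) == 0))
  # one CA alternating +-1 A in x: MSF exactly 1 for that residue
  m1 <- base; m1[cas[3], 1] <- m1[cas[3], 1] + 1
  m2 <- base; m2[cas[3], 1] <- m2[cas[3], 1] - 1
  ea <- pse_ensemble(tiny_a$atoms, list(m1, m2), aligned = TRUE)
  msf <- rmsf(ea)
  expect_equal(msf[3], 1.0)
  expect_true(all(msf[-3] == 0))
  # oracle equivalence on a generated ensemble
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e <- iterative_align(generate_ensemble(cs, 6, tiny_a, fast_params(seed = 2)))
  man <- rep(0, length(cas))
  avg <- average_structure(e)
  for (m in e$models) man <- man + rowSums((m[cas, ] - avg[cas, ])^2)
  expect_equal(rmsf(e), man / n_models(e), tolerance = 1e-12)

  # ratios: identity, zero-reference guard, roster mismatch
  expect_true(all(rmsf_ratio(e, e) == 1))
  rr <- rmsf_ratio(ea, er)
  expect_true(all(is.nan(rr)))
  sub <- pse_ensemble(tiny_a$atoms[1:20, ],
                      lapply(e$models, function(m) m[1:20, ]), aligned = TRUE)
  expect_error(rmsf_ratio(e, sub), "rosters")
})

test_that("pca and rmsf are invariant to a global rigid transform", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e0 <- generate_ensemble(cs, 6, tiny_a, fast_params(seed = 13))
  th <- 0.8
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e1 <- pse_ensemble(e0$roster, lapply(e0$models, function(m) m %*% rot + 7))
  a0 <- iterative_align(e0); a1 <- iterative_align(e1)
  expect_equal(rmsf(a0), rmsf(a1), tolerance = 1e-6)
  expect_equal(pca_ensemble(a0)$eigenvalues, pca_ensemble(a1)$eigenvalues,
               tolerance = 1e-6)
})

test_that("external structures can be superposed into the PCA frame", {
  cs <- build_constraint_set(tiny_a, tiny_b, 0.4, seed = 8)
  e <- iterative_align(generate_ensemble(cs, 6, tiny_a, fast_params(seed = 4)))
  pc <- pca_ensemble(e)
  # a rigidly moved copy of an ensemble member projects identically after
  # superposition into the PCA frame
  m <- e$models[[2]]
  th <- 1.3
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- m %*% rot + matrix(c(8, -3, 2), nrow(m), 3, byrow = TRUE)
  back <- superpose_to_pca(moved, pc)
  expect_equal(project_onto_pc(back, pc, 1), project_onto_pc(m, pc, 1),
               tolerance = 1e-6)
})
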