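test_that("DWI synthesis follows the tensor attenuation model", {
  sh <- c(4, 4, 4)
  # isotropic d = 0.7 um^2/ms, S0 = 100
  comp <- array(0, c(sh, 6)); comp[, , , 1:3] <- 0.7
  f <- tensor_field(comp, array(100, sh))
  sch <- direction_set(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 1000))
  dwi <- synthesize_dwi(f, sch)
  expect_equal(unique(as.vector(dwi$data[, , , 1])), 100)  # b=0 -> S0
  expect_equal(unique(as.vector(dwi$data[, , , 2])), 100 * exp(-0.7),
               tolerance = 1e-12)
  # gradient aligned with the principal axis of a diagonal tensor
  comp2 <- array(0, c(sh, 6))
  comp2[, , , 1] <- 1.7; comp2[, , , 2] <- 0.3; comp2[, , , 3] <- 0.3
  f2 <- tensor_field(comp2, array(100, sh))
  dwi2 <- synthesize_dwi(f2, direction_set(rbind(c(1, 0, 0)), 1000))
  expect_equal(unique(as.vector(dwi2$data)), 100 * exp(-1.7),
               tolerance = 1e-12)
})

test_that("noise-free OLS fit inverts the synthesis exactly", {
  ph <- make_tensor_phantom(32, seed = 1)
  sch <- test_scheme()
  dwi <- synthesize_dwi(ph$tensors, sch)
  fit <- fit_tensor_ols(dwi, sch, ph$mask)
  idx <- which(ph$mask$data)
  nvox <- prod(spatial_shape(ph$truth))
  for (j in 1:6) {
    est <- fit$components[idx + (j - 1) * nvox]
    tru <- ph$tensors$components[idx + (j - 1) * nvox]
    expect_lt(max(abs(est - tru)) / max(abs(ph$tensors$components)), 1e-8)
  }
  expect_equal(fit$s0[idx], ph$tensors$s0[idx], tolerance = 1e-8)
  # isotropic voxels recover equal eigenvalues
  met <- tensor_metrics(fit, ph$mask)
  iso <- ph$regions == 1L
  expect_lt(max(abs(met$l1[iso] - 0.7)), 1e-10)
  expect_lt(max(abs(met$l3[iso] - 0.7)), 1e-10)
})

test_that("rank-deficient encoding geometry is rejected by name", {
  sh <- c(4, 4, 4)
  comp <- array(0, c(sh, 6)); comp[, , , 1:3] <- 0.7
  f <- tensor_field(comp, array(100, sh))
  # seven entries but all gradients along x: cannot span six components
  g <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 6), ncol = 3, byrow = TRUE))
  sch <- direction_set(g, c(0, rep(1000, 6)))
  dwi <- synthesize_dwi(f, sch)
  expect_error(fit_tensor_ols(dwi, sch, array(TRUE, sh)), "rank-deficient")
})

test_that("tensor fitting recovers MD without bias under moderate noise", {
  set.seed(2)
  sh <- c(22, 22, 22)  # ~10^4 voxels
  comp <- array(0, c(sh, 6))
  comp[, , , 1] <- 1.0; comp[, , , 2] <- 0.8; comp[, , , 3] <- 0.6
  f <- tensor_field(comp, array(100, sh))
  # 12 directions: icosahedral-like spread from the optimizer plus rotations
  opt <- optimize_directions(6, restarts = 10, seed = 3)
  R <- noise2average:::random_rotation()
  g12 <- rbind(opt$scheme$directions, opt$scheme$directions %*% t(R))
  sch <- direction_set(rbind(c(0, 0, 0), g12), c(0, rep(1000, 12)))
  dwi <- synthesize_dwi(f, sch)
  noisy <- dwi$data + array(rnorm(length(dwi$data), 0, 0.05 * 100),
                            dim(dwi$data))
  fit <- fit_tensor_ols(as_volume(noisy), sch, array(TRUE, sh))
  md_est <- (fit$components[, , , 1] + fit$components[, , , 2] +
               fit$components[, , , 3]) / 3
  expect_equal(mean(md_est), 0.8, tolerance = 0.02)
})

test_that("DTI metrics match closed forms for known eigenvalues", {
  sh <- c(4, 4, 4)
  lam <- c(1.7, 0.3, 0.3)
  comp <- array(0, c(sh, 6))
  comp[, , , 1] <- lam[1]; comp[, , , 2] <- lam[2]; comp[, , , 3] <- lam[3]
  met <- tensor_metrics(tensor_field(comp, array(100, sh)))
  fa_expected <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(unique(round(as.vector(met$fa), 12)),
               round(fa_expected, 12))
  expect_equal(fa_expected, 0.799, tolerance = 1e-3)
  expect_equal(unique(as.vector(met$md)), mean(lam))
  expect_equal(unique(as.vector(met$ad)), 1.7)
  expect_equal(unique(as.vector(met$rd)), 0.3)
  # V1 parallel to x (either sign)
  expect_equal(unique(abs(as.vector(met$v1[, , , 1]))), 1)
  expect_equal(unique(abs(as.vector(met$v1[, , , 2]))), 0)
  # FA bounds: prolate limit approaches 1
  comp2 <- comp
  comp2[, , , 1] <- 1; comp2[, , , 2] <- 1e-6; comp2[, , , 3] <- 1e-6
  met2 <- tensor_metrics(tensor_field(comp2, array(1, sh)))
  expect_gt(min(met2$fa), 0.999)
  expect_lte(max(met2$fa), 1)
})

test_that("the encoding condition number flags degenerate geometry", {
  # six coplanar directions: rank < 6
  ang <- seq(0, pi, length.out = 7)[1:6]
  coplanar <- cbind(cos(ang), sin(ang), 0)
  k <- condition_number(coplanar)
  expect_false(is.finite(k))
  expect_true(isTRUE(attr(k, "degenerate")))
  # duplicated direction
  g <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  expect_false(is.finite(condition_number(g)))
  # any full-rank scheme has kappa >= 1
  set.seed(4)
  for (i in 1:10) {
    gg <- matrix(rnorm(18), 6, 3)
    gg <- gg / sqrt(rowSums(gg^2))
    kk <- condition_number(gg)
    if (is.finite(kk)) expect_gte(kk, 1)
  }
  expect_error(condition_number(gg[1:5, ]), "six")
})

test_that("direction optimization improves monotonically with restarts", {
  r1 <- optimize_directions(6, restarts = 1, seed = 5)
  r10 <- optimize_directions(6, restarts = 10, seed = 5)
  expect_lte(r10$kappa, r1$kappa)
  expect_true(all(abs(sqrt(rowSums(r10$scheme$directions^2)) - 1) < 1e-8))
  expect_gte(r10$kappa, 1)
})

test_that("electrostatic energy matches closed forms and is rotation-invariant", {
  # two orthogonal unit vectors: both pair distances are sqrt(2)
  expect_equal(electrostatic_energy(rbind(c(1, 0, 0), c(0, 1, 0))), sqrt(2))
  # antipodal pair is degenerate
  e <- electrostatic_energy(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_false(is.finite(e))
  set.seed(6)
  g <- matrix(rnorm(18), 6, 3); g <- g / sqrt(rowSums(g^2))
  R <- noise2average:::random_rotation()
  expect_lt(abs(electrostatic_energy(g) - electrostatic_energy(g %*% t(R))),
            1e-10)
  # moving two directions closer (60 instead of 90 degrees apart, third
  # direction unaffected) strictly increases the energy
  base <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  closer <- base
  closer[2, ] <- c(cos(pi / 3), sin(pi / 3), 0)
  expect_gt(electrostatic_energy(closer), electrostatic_energy(base))
})

test_that("nearest-subset selection respects rotation, distinctness, and kappa", {
  opt <- optimize_directions(6, restarts = 20, seed = 7)
  ref <- opt$scheme$directions
  # the selection is deterministic under its seed: reconstruct the first
  # rotation it will draw and plant that exact rotated copy in the pool
  set.seed(9)
  R1 <- noise2average:::random_rotation()
  rotated_copy <- ref %*% t(R1)
  # decoys: each copy direction tilted by exactly 25 degrees (less than half
  # the scheme's minimum pairwise angle), so the copy is always the nearest
  tilt <- 25 * pi / 180
  decoys <- t(apply(rotated_copy, 1, function(u) {
    e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(u[2] * e[3] - u[3] * e[2], u[3] * e[1] - u[1] * e[3],
           u[1] * e[2] - u[2] * e[1])
    v <- v / sqrt(sum(v^2))
    cos(tilt) * u + sin(tilt) * v
  }))
  pool <- direction_set(rbind(rotated_copy, decoys), rep(1000, 12))
  # note: the encoding condition number is not rotation-invariant, so the
  # rotated copy has its own kappa; it passes any threshold above that
  kappa_rot <- condition_number(rotated_copy)
  subs <- select_nearest_subsets(pool, ref, n_rotations = 1,
                                 kappa_max = kappa_rot + 0.1, seed = 9)
  expect_length(subs, 1L)
  expect_setequal(attr(subs[[1]], "indices"), 1:6)
  expect_equal(attr(subs[[1]], "kappa"), kappa_rot, tolerance = 1e-10)
  # and it is rejected under a threshold below its kappa
  subs_tight <- select_nearest_subsets(pool, ref, n_rotations = 1,
                                       kappa_max = kappa_rot - 0.1, seed = 9)
  expect_length(subs_tight, 0L)
  # a collapsed pool (all directions nearly parallel) yields no subsets
  base <- c(1, 0, 0)
  tight <- t(vapply(seq(-0.005, 0.005, length.out = 8), function(e) {
    v <- base + c(0, e, e / 2); v / sqrt(sum(v^2))
  }, numeric(3)))
  subs2 <- select_nearest_subsets(direction_set(tight, rep(1000, 8)), ref,
                                  n_rotations = 20, seed = 10)
  expect_length(subs2, 0)
})

test_that("minimum-energy pair selection agrees with brute force", {
  set.seed(11)
  mk <- function() {
    g <- matrix(rnorm(18), 6, 3); g / sqrt(rowSums(g^2))
  }
  subsets <- replicate(4, mk(), simplify = FALSE)
  best <- pick_min_energy_pair(subsets)
  # brute force over all pairs
  pairs <- utils::combn(4, 2)
  energies <- apply(pairs, 2, function(p)
    electrostatic_energy(rbind(subsets[[p[1]]], subsets[[p[2]]])))
  expect_equal(best$energy, min(energies, na.rm = TRUE))
  expect_equal(sort(best$pair),
               sort(pairs[, which.min(energies)]))
  # sampling with n_trials >= number of pairs matches the exhaustive answer
  best2 <- pick_min_energy_pair(subsets, n_trials = 10, seed = 12)
  expect_equal(best2$energy, best$energy)
  # a duplicated subset pairs to infinite energy and is never selected
  subsets_dup <- c(subsets[1], subsets[1], subsets[2])
  bd <- pick_min_energy_pair(subsets_dup)
  expect_true(is.finite(bd$energy))
  expect_false(identical(sort(bd$pair), c(1L, 2L)))
  expect_error(pick_min_energy_pair(subsets[1]), "two subsets")
})

test_that("bvec/bval files round trip in FSL layout", {
  sch <- test_scheme()
  fv <- tempfile(fileext = ".bvec"); fb <- tempfile(fileext = ".bval")
  write_bvec_bval(sch, fv, fb)
  expect_length(readLines(fv), 3L)  # 3 x N layout
  sch2 <- read_bvec_bval(fv, fb)
  expect_equal(sch2$directions, sch$directions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sch2$bvalues, sch$bvalues)
})
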