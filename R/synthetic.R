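#' Simulation configuration for repetition synthesis
#'
#' The defaults mirror the simulation study conditions: additive zero-mean
#' Gaussian noise with absolute scale `sigma` times the population standard
#' deviation of brain-voxel intensities of the noise-free truth, and optional
#' small residual affine misalignment. The full transform ranges (translations
#' up to 10 voxels, rotations within +/-3 degrees per axis, left-right scaling
#' 1.0-1.4) describe the raw perturbations; co-registered inputs retain only a
#' residual fraction of them, controlled by `perturb_fraction` (default 0.1).
#'
#' @param sigma relative noise level (fraction of masked intensity SD), >= 0.
#' @param n_repetitions number of repetitions to simulate, >= 1.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of the
#'   signal plus complex Gaussian noise with per-component SD `sigma_abs`).
#' @param translation_max maximum translation per axis, voxels.
#' @param rotation_max maximum rotation per axis, degrees.
#' @param lr_scale_range left-right scaling factor range, `c(low, high)`.
#' @param misalign apply a residual random affine perturbation per repetition.
#' @param perturb_fraction fraction of the stated transform ranges surviving
#'   co-registration; applied only when `misalign = TRUE`.
#' @param seed integer seed making the simulation deterministic.
#' @return An object of class `n2a_simulation_config`.
#' @export
simulation_config <- function(sigma = 0.3, n_repetitions = 2L,
                              noise_model = c("gaussian", "rician"),
                              translation_max = 10, rotation_max = 3,
                              lr_scale_range = c(1.0, 1.4),
                              misalign = FALSE, perturb_fraction = 0.1,
                              seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  if (lr_scale_range[1] > lr_scale_range[2])
    stop("lr_scale_range must be ordered low <= high")
  structure(list(sigma = sigma, n_repetitions = as.integer(n_repetitions),
                 noise_model = noise_model, translation_max = translation_max,
                 rotation_max = rotation_max, lr_scale_range = lr_scale_range,
                 misalign = isTRUE(misalign),
                 perturb_fraction = perturb_fraction, seed = seed),
            class = "n2a_simulation_config")
}

# Normalized coordinates in [-1, 1] per axis, as three arrays.
norm_coords <- function(shape) {
  cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / ((shape[1] - 1) / 2)
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / ((shape[2] - 1) / 2)
  cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / ((shape[3] - 1) / 2)
  list(x = array(rep(cx, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
       z = array(rep(cz, each = shape[1] * shape[2]), shape))
}

#' Generate a structured T1w-like phantom
#'
#' Builds a deterministic synthetic "head": nested ellipsoidal regions of
#' distinct mean intensity (outer tissue, cortex-like shell, white-matter-like
#' interior, deep-gray core) plus smooth low-frequency texture, with a brain
#' mask covering the outer region. It stands in for high-SNR anatomical
#' ground truth when exercising the denoising pipeline at desk scale.
#'
#' @param spatial_shape integer length 1 or 3, >= 32 per axis.
#' @param seed integer seed; identical seeds give identical phantoms.
#' @return An object of class `n2a_phantom`: `truth` (volume), `mask`,
#'   `regions` (integer array of region labels 0-4), `tensors = NULL`.
#' @export
make_structural_phantom <- function(spatial_shape = 64L, seed = 1L) {
  if (length(spatial_shape) == 1L) spatial_shape <- rep(spatial_shape, 3L)
  spatial_shape <- as.integer(spatial_shape)
  if (any(spatial_shape < 32L))
    stop("phantom needs >= 32 voxels per axis to hold its nested structure")
  set.seed(seed)
  co <- norm_coords(spatial_shape)
  # ellipsoidal radii (slightly anisotropic head shape)
  r_head <- sqrt((co$x / 0.92)^2 + (co$y / 0.85)^2 + (co$z / 0.88)^2)
  r_in   <- sqrt((co$x / 0.70)^2 + (co$y / 0.62)^2 + (co$z / 0.66)^2)
  r_core <- sqrt(((co$x - 0.05) / 0.22)^2 + (co$y / 0.20)^2 + (co$z / 0.24)^2)
  regions <- array(0L, spatial_shape)
  regions[r_head <= 1] <- 1L                 # outer tissue / CSF-like rim
  regions[r_in <= 1] <- 2L                   # cortex-like band
  regions[r_in <= 0.72] <- 3L                # white-matter-like interior
  regions[r_core <= 1] <- 4L                 # deep gray core
  base <- c(0, 40, 110, 160, 70)[regions + 1L]
  dim(base) <- spatial_shape
  # smooth low-frequency texture: a few random 3D cosine modes
  tex <- array(0, spatial_shape)
  for (k in 1:5) {
    f <- stats::runif(3, 0.5, 3); ph <- stats::runif(3, 0, 2 * pi)
    tex <- tex + cos(pi * f[1] * co$x + ph[1]) *
      cos(pi * f[2] * co$y + ph[2]) * cos(pi * f[3] * co$z + ph[3])
  }
  truth <- base + 8 * tex * (regions > 0L)
  truth[truth < 0] <- 0
  structure(list(truth = as_volume(truth), mask = as_mask(regions > 0L),
                 regions = regions, tensors = NULL),
            class = "n2a_phantom")
}

#' Generate a diffusion tensor phantom
#'
#' Builds a per-voxel tensor field with an isotropic core, a coherent
#' anisotropic region with principal direction along x, and a curved/fanning
#' anisotropic region whose principal direction rotates tangentially around
#' the z axis. All tensors are positive-definite; S0 is constant inside the
#' mask. Used as generative ground truth for DWI synthesis and tensor-fit
#' recovery tests.
#'
#' @param spatial_shape integer length 1 or 3, >= 32 per axis.
#' @param seed integer seed.
#' @param s0 baseline non-diffusion-weighted signal inside the mask.
#' @return An `n2a_phantom` whose `tensors` is an `n2a_tensor_field`
#'   (components in um^2/ms), with `truth` the S0 volume and `regions`
#'   labelling 1 = isotropic, 2 = coherent anisotropic, 3 = curved.
#' @export
make_tensor_phantom <- function(spatial_shape = 32L, seed = 1L, s0 = 100) {
  if (length(spatial_shape) == 1L) spatial_shape <- rep(spatial_shape, 3L)
  spatial_shape <- as.integer(spatial_shape)
  if (any(spatial_shape < 32L)) stop("tensor phantom needs >= 32 voxels per axis")
  set.seed(seed)
  co <- norm_coords(spatial_shape)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  maskarr <- r <= 0.9
  regions <- array(0L, spatial_shape)
  regions[maskarr] <- 3L                      # curved outer shell (default)
  regions[maskarr & r < 0.55] <- 2L           # coherent anisotropic band
  regions[maskarr & r < 0.25] <- 1L           # isotropic core
  comp <- array(0, c(spatial_shape, 6L))      # Dxx,Dyy,Dzz,Dxy,Dxz,Dyz
  # default/outside voxels: mild isotropic medium (keeps all tensors SPD)
  comp[, , , 1] <- comp[, , , 2] <- comp[, , , 3] <- 0.7
  # region 2: eigenvalues (1.7, 0.3, 0.3) um^2/ms along x -> diagonal tensor
  i2 <- which(regions == 2L)
  nv <- prod(spatial_shape)
  comp[i2] <- 1.7; comp[i2 + nv] <- 0.3; comp[i2 + 2 * nv] <- 0.3
  # region 3: principal direction tangential around z: e1 = (-y, x, 0)/|.|
  i3 <- which(regions == 3L)
  tx <- -co$y[i3]; ty <- co$x[i3]
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm < 1e-6] <- 1
  tx <- tx / nrm; ty <- ty / nrm
  l1 <- 1.5; l23 <- 0.4
  # D = l23*I + (l1-l23) * e1 e1^T  (e1 in the xy-plane)
  comp[i3]           <- l23 + (l1 - l23) * tx * tx
  comp[i3 + nv]      <- l23 + (l1 - l23) * ty * ty
  comp[i3 + 2 * nv]  <- l23
  comp[i3 + 3 * nv]  <- (l1 - l23) * tx * ty
  comp[i3 + 4 * nv]  <- 0
  comp[i3 + 5 * nv]  <- 0
  s0arr <- array(0, spatial_shape)
  s0arr[maskarr] <- s0
  field <- tensor_field(comp, s0arr)
  structure(list(truth = as_volume(s0arr), mask = as_mask(maskarr),
                 regions = regions, tensors = field),
            class = "n2a_phantom")
}

#' @export
print.n2a_phantom <- function(x, ...) {
  cat("<n2a_phantom> ", paste(spatial_shape(x$truth), collapse = " x "),
      " voxels, ", sum(x$mask$data), " mask voxels",
      if (!is.null(x$tensors)) ", with tensor field", "\n", sep = "")
  invisible(x)
}

# Rotation (deg, per axis) + LR scaling + translation (voxels) about centre.
affine_matrix <- function(rot_deg, scale_x, trans) {
  r <- rot_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3)
  S <- diag(c(scale_x, 1, 1))
  list(A = Rz %*% Ry %*% Rx %*% S, t = trans)
}

# Resample one channel through an affine map with trilinear interpolation.
# Returns list(values, infield): out-of-field voxels are 0 / FALSE.
affine_resample <- function(arr3, A, t) {
  sh <- dim(arr3)
  ctr <- (sh + 1) / 2
  co <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]), z = seq_len(sh[3]))
  P <- t(as.matrix(co)) - ctr                 # 3 x N, centred target coords
  Q <- A %*% P + (t + ctr)                    # source coordinates
  x <- Q[1, ]; y <- Q[2, ]; z <- Q[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  infield <- x0 >= 1 & x0 + 1 <= sh[1] & y0 >= 1 & y0 + 1 <= sh[2] &
    z0 >= 1 & z0 + 1 <= sh[3]
  val <- numeric(length(x))
  ii <- which(infield)
  if (length(ii)) {
    lin <- function(xi, yi, zi) xi + sh[1] * (yi - 1) + sh[1] * sh[2] * (zi - 1)
    x0i <- x0[ii]; y0i <- y0[ii]; z0i <- z0[ii]
    fxi <- fx[ii]; fyi <- fy[ii]; fzi <- fz[ii]
    v000 <- arr3[lin(x0i,     y0i,     z0i)]
    v100 <- arr3[lin(x0i + 1, y0i,     z0i)]
    v010 <- arr3[lin(x0i,     y0i + 1, z0i)]
    v110 <- arr3[lin(x0i + 1, y0i + 1, z0i)]
    v001 <- arr3[lin(x0i,     y0i,     z0i + 1)]
    v101 <- arr3[lin(x0i + 1, y0i,     z0i + 1)]
    v011 <- arr3[lin(x0i,     y0i + 1, z0i + 1)]
    v111 <- arr3[lin(x0i + 1, y0i + 1, z0i + 1)]
    val[ii] <-
      v000 * (1 - fxi) * (1 - fyi) * (1 - fzi) +
      v100 * fxi       * (1 - fyi) * (1 - fzi) +
      v010 * (1 - fxi) * fyi       * (1 - fzi) +
      v110 * fxi       * fyi       * (1 - fzi) +
      v001 * (1 - fxi) * (1 - fyi) * fzi +
      v101 * fxi       * (1 - fyi) * fzi +
      v011 * (1 - fxi) * fyi       * fzi +
      v111 * fxi       * fyi       * fzi
  }
  dim(val) <- sh
  dim(infield) <- sh
  list(values = val, infield = infield)
}

#' Simulate noisy repetitions of a phantom
#'
#' For each repetition, optionally applies a small residual affine
#' perturbation (emulating imperfect co-registration) with trilinear
#' resampling, then adds noise with absolute scale `sigma_abs = sigma *
#' population SD of the truth inside the mask` (per channel). Gaussian noise
#' is additive; Rician noise is the magnitude of the signal plus complex
#' Gaussian noise with per-component SD `sigma_abs`. Noise is independent
#' across repetitions and the whole simulation is deterministic under
#' `config$seed`. Voxels falling out of field in any misaligned repetition
#' are removed from the returned mask.
#'
#' @param phantom a phantom from [make_structural_phantom()] or
#'   [make_tensor_phantom()], or any list with `truth` and `mask`.
#' @param config an [simulation_config()].
#' @return An [repetition_set()] whose attribute `"sigma_abs"` records the
#'   per-channel absolute noise scales used.
#' @export
simulate_repetitions <- function(phantom, config) {
  if (!inherits(config, "n2a_simulation_config")) stop("not a simulation config")
  truth <- as_volume(phantom$truth)
  mask <- as_mask(phantom$mask)
  if (!is.null(config$seed)) set.seed(config$seed)
  a <- vol_data4(truth)
  nc <- dim(a)[4]
  sigma_abs <- vapply(seq_len(nc), function(c) {
    v <- masked_values(truth, mask, c)
    config$sigma * sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  maskarr <- mask$data
  reps <- vector("list", config$n_repetitions)
  for (k in seq_len(config$n_repetitions)) {
    rep_a <- a
    if (config$misalign) {
      pf <- config$perturb_fraction
      rot <- stats::runif(3, -config$rotation_max, config$rotation_max) * pf
      trans <- stats::runif(3, -config$translation_max, config$translation_max) * pf
      sc_raw <- stats::runif(1, config$lr_scale_range[1], config$lr_scale_range[2])
      sc <- 1 + (sc_raw - 1) * pf
      af <- affine_matrix(rot, sc, trans)
      for (c in seq_len(nc)) {
        rs <- affine_resample(a[, , , c], af$A, af$t)
        rep_a[, , , c] <- rs$values
        if (c == 1L) maskarr <- maskarr & rs$infield
      }
    }
    for (c in seq_len(nc)) {
      nvox <- length(rep_a[, , , c])
      if (config$noise_model == "gaussian") {
        rep_a[, , , c] <- rep_a[, , , c] +
          array(stats::rnorm(nvox, 0, sigma_abs[c]), dim(rep_a)[1:3])
      } else {
        n1 <- array(stats::rnorm(nvox, 0, sigma_abs[c]), dim(rep_a)[1:3])
        n2 <- array(stats::rnorm(nvox, 0, sigma_abs[c]), dim(rep_a)[1:3])
        rep_a[, , , c] <- sqrt((rep_a[, , , c] + n1)^2 + n2^2)
      }
    }
    reps[[k]] <- vol_like(rep_a, truth)
  }
  out <- repetition_set(reps, as_mask(maskarr),
                        require_pair = config$n_repetitions >= 2L)
  attr(out, "sigma_abs") <- sigma_abs
  out
}

#' Write a phantom and its simulated repetitions to disk
#'
#' Writes the truth, mask, and repetitions as NIfTI plus a JSON sidecar
#' recording the simulation configuration. Tensor phantoms additionally get
#' a 6-channel tensor NIfTI and an S0 NIfTI.
#'
#' @param phantom a phantom.
#' @param reps optional repetition set from [simulate_repetitions()].
#' @param config optional simulation config used (stored in the sidecar).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, reps = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$truth, file.path(dir, "truth.nii.gz"))
  write_mask(phantom$mask, file.path(dir, "mask.nii.gz"))
  if (!is.null(phantom$tensors)) {
    write_volume(as_volume(phantom$tensors$components),
                 file.path(dir, "tensors.nii.gz"))
    write_volume(as_volume(phantom$tensors$s0), file.path(dir, "s0.nii.gz"))
  }
  if (!is.null(reps)) {
    for (k in seq_along(reps$repetitions))
      write_volume(reps$repetitions[[k]],
                   file.path(dir, sprintf("rep_%02d.nii.gz", k)))
  }
  sidecar <- list(generator = "noise2average synthetic phantom",
                  config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
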