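#' Map intensities to the approximate [0, 1] metric range
#'
#' Standardizes per channel and then applies the fixed affine transform
#' `(v_std + 3) / 6`, so the masked mean lands at 0.5 and mean + 3 SD at
#' 1.0. All similarity metrics are computed on this scale, which makes the
#' PSNR peak and the SSIM dynamic range equal to 1.
#'
#' @param volume a volume.
#' @param params standardization parameters (shared by the two images being
#'   compared).
#' @return The transformed volume.
#' @export
metric_normalize <- function(volume, params) {
  sv <- standardize(as_volume(volume), params)
  vol_like((vol_data4(sv) + 3) / 6, as_volume(volume))
}

# Sampled Gaussian kernel, radius = floor(truncate * sigma + 0.5).
gaussian_kernel <- function(sigma = 1.5, truncate = 3.5) {
  r <- floor(truncate * sigma + 0.5)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian filtering of a 3D array with symmetric (edge-repeating)
# boundary padding, matching common reference implementations.
gaussian_filter3 <- function(a, w) {
  r <- (length(w) - 1L) %/% 2L
  filt_first_dim <- function(x) {
    d <- dim(x)
    n <- d[1]
    padidx <- c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1L))
    m <- matrix(x, nrow = n)
    m <- m[padidx, , drop = FALSE]
    f <- stats::filter(m, w, method = "convolution", sides = 2)
    f <- f[r + seq_len(n), , drop = FALSE]
    array(f, d)
  }
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    a <- aperm(filt_first_dim(aperm(a, perm)), order(perm))
  }
  a
}

# Local SSIM map of two 3D arrays on the [0,1] scale.
ssim_map3 <- function(a, b, sigma = 1.5, C1 = 0.01^2, C2 = 0.03^2) {
  w <- gaussian_kernel(sigma)
  ux <- gaussian_filter3(a, w); uy <- gaussian_filter3(b, w)
  uxx <- gaussian_filter3(a * a, w); uyy <- gaussian_filter3(b * b, w)
  uxy <- gaussian_filter3(a * b, w)
  vx <- uxx - ux^2; vy <- uyy - uy^2; cxy <- uxy - ux * uy
  ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

#' Masked image-similarity metrics
#'
#' Normalizes both volumes with the shared parameters
#' ([metric_normalize()]), then computes, over masked voxels only: MAE,
#' PSNR `= 10 log10(1 / MSE)` with peak 1 (reported as `Inf` for identical
#' images), and SSIM as the mean over masked voxels of a local 3D SSIM map
#' (Gaussian window, sigma 1.5, 11^3 support, constants `C1 = 0.01^2`,
#' `C2 = 0.03^2` for dynamic range 1). The SSIM windows may straddle the
#' mask boundary; values are sampled at masked centres.
#'
#' @param a,b volumes of identical shape (estimate and reference).
#' @param mask a brain mask.
#' @param params shared standardization parameters (typically from the
#'   ground truth or the raw input mean).
#' @return An object of class `n2a_metrics_report`: scalars `mae`, `mse`,
#'   `psnr`, `ssim` plus a `per_channel` data frame.
#' @export
image_similarity <- function(a, b, mask, params) {
  a <- as_volume(a); b <- as_volume(b); mask <- as_mask(mask)
  if (!identical(dim(vol_data4(a)), dim(vol_data4(b))))
    stop("volume shapes differ")
  if (!identical(spatial_shape(a), spatial_shape(mask)))
    stop("mask shape does not match volumes")
  an <- vol_data4(metric_normalize(a, params))
  bn <- vol_data4(metric_normalize(b, params))
  nc <- dim(an)[4]
  idx <- which(mask$data)
  nvox <- prod(dim(an)[1:3])
  rows <- lapply(seq_len(nc), function(c) {
    av <- an[idx + (c - 1) * nvox]; bv <- bn[idx + (c - 1) * nvox]
    mae <- mean(abs(av - bv))
    mse <- mean((av - bv)^2)
    psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
    smap <- ssim_map3(an[, , , c], bn[, , , c])
    ssim <- mean(smap[idx])
    data.frame(channel = c, mae = mae, mse = mse, psnr = psnr, ssim = ssim)
  })
  per_channel <- do.call(rbind, rows)
  mse_all <- mean(per_channel$mse)
  structure(list(mae = mean(per_channel$mae), mse = mse_all,
                 psnr = if (mse_all == 0) Inf else 10 * log10(1 / mse_all),
                 ssim = mean(per_channel$ssim),
                 per_channel = per_channel),
            class = "n2a_metrics_report")
}

#' @export
print.n2a_metrics_report <- function(x, ...) {
  cat(sprintf("<n2a_metrics_report> MAE %.4g | PSNR %.4g dB | SSIM %.4g\n",
              x$mae, x$psnr, x$ssim))
  invisible(x)
}

#' Unsupervised mean squared error (uMSE)
#'
#' Estimates the MSE between a denoised volume and the unknown truth using
#' only noisy data: `uMSE = mean_mask((d - y*)^2) - sigma2_hat`, where `y*`
#' is an additional noisy repetition not used to produce `d`, and the noise
#' variance is estimated from a pair of same-level noisy repetitions as
#' `sigma2_hat = mean_mask((y1 - y2)^2) / 2`. Under independent zero-mean
#' noise this is unbiased for `MSE(d, truth)`, which makes it usable as an
#' iteration-stopping criterion without ground truth.
#'
#' @param denoised the denoised volume `d`.
#' @param extra_rep an additional noisy repetition `y*` (held out from the
#'   denoising).
#' @param noise_pair list or repetition set giving two noisy repetitions at
#'   the same noise level, used for the variance estimate.
#' @param mask a brain mask.
#' @return Scalar uMSE (on the raw intensity scale of the inputs).
#' @export
umse <- function(denoised, extra_rep, noise_pair, mask) {
  mask <- as_mask(mask)
  d <- as_volume(denoised); ystar <- as_volume(extra_rep)
  if (inherits(noise_pair, "n2a_repetition_set"))
    noise_pair <- noise_pair$repetitions[1:2]
  y1 <- as_volume(noise_pair[[1]]); y2 <- as_volume(noise_pair[[2]])
  nc <- n_channels(d)
  vals <- vapply(seq_len(nc), function(c) {
    dd <- masked_values(d, mask, c) - masked_values(ystar, mask, c)
    nn <- masked_values(y1, mask, c) - masked_values(y2, mask, c)
    mean(dd^2) - mean(nn^2) / 2
  }, numeric(1))
  mean(vals)
}

#' Masked mean angular error of principal eigenvectors
#'
#' Per voxel `theta = acos(|v_est . v_true|)` in degrees
#' (antipodally-invariant, in [0, 90]); returns the masked mean. Vectors
#' off unit norm by more than 1e-3 are renormalized with a warning.
#'
#' @param v_est,v_true arrays `(X, Y, Z, 3)` of (approximately) unit
#'   vectors.
#' @param tissue_mask mask of voxels entering the mean.
#' @return Scalar mean angular error in degrees.
#' @export
v1_angular_error <- function(v_est, v_true, tissue_mask) {
  m <- as_mask(tissue_mask)
  idx <- which(m$data)
  nvox <- prod(dim(m$data))
  get3 <- function(v) {
    cbind(v[idx], v[idx + nvox], v[idx + 2 * nvox])
  }
  ve <- get3(v_est); vt <- get3(v_true)
  renorm <- function(v, label) {
    nr <- sqrt(rowSums(v^2))
    if (any(abs(nr - 1) > 1e-3)) {
      warning(label, " vectors deviate from unit norm; renormalizing")
    }
    nr[nr == 0] <- 1
    v / nr
  }
  ve <- renorm(ve, "estimated"); vt <- renorm(vt, "true")
  dt <- pmin(1, abs(rowSums(ve * vt)))
  mean(acos(dt)) * 180 / pi
}

#' DTI metric error report against ground truth
#'
#' Masked MAE for FA, MD, AD, RD (um^2/ms for the diffusivities) and the
#' masked mean angular V1 error in degrees, within a tissue mask (typically
#' gray + white matter, excluding CSF).
#'
#' @param est,truth `n2a_dti_metrics` objects from [tensor_metrics()].
#' @param tissue_mask the evaluation mask.
#' @return An object of class `n2a_dti_error_report` with fields
#'   `v1_error_deg`, `fa_error`, `md_error`, `ad_error`, `rd_error`.
#' @export
dti_error_report <- function(est, truth, tissue_mask) {
  m <- as_mask(tissue_mask)
  if (!identical(dim(est$fa), dim(truth$fa)))
    stop("metric shapes differ")
  idx <- which(m$data)
  mae_of <- function(f) mean(abs(est[[f]][idx] - truth[[f]][idx]))
  structure(list(v1_error_deg = v1_angular_error(est$v1, truth$v1, m),
                 fa_error = mae_of("fa"), md_error = mae_of("md"),
                 ad_error = mae_of("ad"), rd_error = mae_of("rd")),
            class = "n2a_dti_error_report")
}

#' @export
print.n2a_dti_error_report <- function(x, ...) {
  cat(sprintf(paste0("<n2a_dti_error_report> V1 %.3g deg | FA %.3g | ",
                     "MD %.3g | AD %.3g | RD %.3g um^2/ms\n"),
              x$v1_error_deg, x$fa_error, x$md_error, x$ad_error, x$rd_error))
  invisible(x)
}

#' Write a metrics report to JSON and/or CSV
#' @param report an `n2a_metrics_report` or `n2a_dti_error_report`.
#' @param json_path,csv_path optional output paths.
#' @return The report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  flat <- unclass(report)
  per_channel <- flat$per_channel
  flat$per_channel <- NULL
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    tab <- if (!is.null(per_channel)) per_channel
           else as.data.frame(flat)
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(report)
}
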