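#' Diffusion encoding scheme (directions + b-values)
#'
#' @param directions numeric matrix, one unit 3-vector per row (rows with
#'   nonzero b must have unit norm within 1e-8; b = 0 rows may be zero).
#' @param bvalues numeric b-values in s/mm^2, one per row (0 allowed).
#' @return An object of class `n2a_direction_set`.
#' @export
direction_set <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) != nrow(directions))
    stop("lengths of directions and bvalues differ")
  nrm <- sqrt(rowSums(directions^2))
  bad <- bvalues > 0 & abs(nrm - 1) > 1e-8
  if (any(bad))
    stop("non-unit direction(s) at nonzero b: rows ",
         paste(which(bad), collapse = ", "))
  structure(list(directions = directions, bvalues = bvalues),
            class = "n2a_direction_set")
}

#' @export
print.n2a_direction_set <- function(x, ...) {
  cat("<n2a_direction_set> ", nrow(x$directions), " entries, b in {",
      paste(sort(unique(x$bvalues)), collapse = ", "), "} s/mm^2\n", sep = "")
  invisible(x)
}

#' Per-voxel diffusion tensor field
#'
#' @param components array `(X, Y, Z, 6)` with the symmetric tensor
#'   components `[Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]` in um^2/ms.
#' @param s0 array `(X, Y, Z)` of non-diffusion-weighted signal.
#' @return An object of class `n2a_tensor_field`.
#' @export
tensor_field <- function(components, s0) {
  components <- as.array(components)
  if (length(dim(components)) != 4L || dim(components)[4] != 6L)
    stop("components must be an (X,Y,Z,6) array")
  s0 <- as.array(s0)
  if (!identical(dim(s0), dim(components)[1:3]))
    stop("s0 shape does not match components")
  structure(list(components = components, s0 = s0),
            class = "n2a_tensor_field")
}

#' @export
print.n2a_tensor_field <- function(x, ...) {
  cat("<n2a_tensor_field> ", paste(dim(x$s0), collapse = " x "),
      " voxels\n", sep = "")
  invisible(x)
}

# Unit conversion: 1 um^2/ms = 1e-3 mm^2/s; b [s/mm^2] * D [mm^2/s] is
# dimensionless, so the attenuation exponent uses b * D_um * 1e-3.
UM2MS_TO_MM2S <- 1e-3

#' Synthesize diffusion-weighted volumes from a tensor field
#'
#' Per voxel and scheme entry: `S = S0 * exp(-b * g' D g)` with b in s/mm^2
#' and D converted from um^2/ms to mm^2/s internally; b = 0 entries return
#' S0 exactly.
#'
#' @param field an [tensor_field()].
#' @param scheme an [direction_set()].
#' @return A volume with one channel per scheme entry.
#' @export
synthesize_dwi <- function(field, scheme) {
  if (!inherits(field, "n2a_tensor_field")) stop("not a tensor field")
  if (!inherits(scheme, "n2a_direction_set")) stop("not a direction set")
  comp <- field$components
  sh <- dim(comp)[1:3]
  ne <- nrow(scheme$directions)
  out <- array(0, c(sh, ne))
  for (e in seq_len(ne)) {
    b <- scheme$bvalues[e]
    if (b == 0) { out[, , , e] <- field$s0; next }
    g <- scheme$directions[e, ]
    quad <- g[1]^2 * comp[, , , 1] + g[2]^2 * comp[, , , 2] +
      g[3]^2 * comp[, , , 3] + 2 * g[1] * g[2] * comp[, , , 4] +
      2 * g[1] * g[3] * comp[, , , 5] + 2 * g[2] * g[3] * comp[, , , 6]
    out[, , , e] <- field$s0 * exp(-b * UM2MS_TO_MM2S * quad)
  }
  as_volume(out)
}

# 7-column log-linear design matrix for the tensor model.
tensor_design <- function(scheme) {
  g <- scheme$directions; b <- scheme$bvalues
  bd <- b * UM2MS_TO_MM2S  # so that fitted D comes out in um^2/ms
  cbind(1,
        -bd * g[, 1]^2, -bd * g[, 2]^2, -bd * g[, 3]^2,
        -2 * bd * g[, 1] * g[, 2],
        -2 * bd * g[, 1] * g[, 3],
        -2 * bd * g[, 2] * g[, 3])
}

#' Ordinary least squares diffusion tensor fit
#'
#' Log-linear OLS of `ln S` against the 7-column design `[1, -b gx^2,
#' -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`, fitted per masked
#' voxel (the common design is factorized once). Nonpositive signals are
#' clamped to a small positive floor (`1e-6` of the largest masked signal)
#' before the logarithm. Fit-output tensors may have negative eigenvalues
#' in noisy voxels; they are reported as-is, not clamped.
#'
#' @param dwis volume with one channel per scheme entry.
#' @param scheme the acquisition [direction_set()]; needs >= 7 entries with
#'   a full-rank design (>= 6 non-collinear nonzero-b directions plus b=0,
#'   or equivalent).
#' @param mask brain mask; voxels outside keep zero tensors and S0 = 0.
#' @return An [tensor_field()] (components in um^2/ms).
#' @export
fit_tensor_ols <- function(dwis, scheme, mask) {
  dwis <- as_volume(dwis); mask <- as_mask(mask)
  a <- vol_data4(dwis)
  ne <- dim(a)[4]
  if (ne != nrow(scheme$directions))
    stop("volume has ", ne, " channels but scheme has ",
         nrow(scheme$directions), " entries")
  if (ne < 7L) stop("need >= 7 volumes for a 7-parameter tensor fit")
  X <- tensor_design(scheme)
  qrx <- qr(X)
  if (qrx$rank < 7L)
    stop("rank-deficient encoding design (rank ", qrx$rank,
         "): directions do not span the six tensor components; ",
         "add non-collinear directions")
  idx <- which(mask$data)
  nvox <- prod(dim(a)[1:3])
  S <- matrix(0, nrow = ne, ncol = length(idx))
  for (e in seq_len(ne)) S[e, ] <- a[idx + (e - 1) * nvox]
  floor_val <- 1e-6 * max(S)
  S[S < floor_val] <- floor_val
  B <- qr.coef(qrx, log(S))  # 7 x nmask
  comp <- array(0, c(dim(a)[1:3], 6L))
  s0 <- array(0, dim(a)[1:3])
  s0[idx] <- exp(B[1, ])
  for (j in 1:6) comp[idx + (j - 1) * nvox] <- B[j + 1, ]
  tensor_field(comp, s0)
}

# Symmetric 3x3 tensor from a 6-component vector.
tensor3 <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Per-voxel DTI metrics from a tensor field
#'
#' Eigendecomposes each voxel's tensor and derives: eigenvalues
#' `l1 >= l2 >= l3`, the principal eigenvector V1 (unit norm, sign
#' unconstrained), FA `= sqrt(3/2) * ||lambda - MD|| / ||lambda||`,
#' MD `= (l1+l2+l3)/3`, AD `= l1`, RD `= (l2+l3)/2`.
#'
#' @param field an [tensor_field()].
#' @param mask optional mask restricting computation (default: all voxels).
#' @return An object of class `n2a_dti_metrics`: arrays `fa`, `md`, `ad`,
#'   `rd`, `l1`, `l2`, `l3` `(X,Y,Z)` and `v1` `(X,Y,Z,3)`.
#' @export
tensor_metrics <- function(field, mask = NULL) {
  comp <- field$components
  if (!all(is.finite(comp))) stop("tensor field contains non-finite values")
  sh <- dim(comp)[1:3]
  idx <- if (is.null(mask)) seq_len(prod(sh)) else which(as_mask(mask)$data)
  nvox <- prod(sh)
  fa <- md <- ad <- rd <- l1 <- l2 <- l3 <- array(0, sh)
  v1 <- array(0, c(sh, 3L))
  cm <- matrix(0, nrow = length(idx), ncol = 6L)
  for (j in 1:6) cm[, j] <- comp[idx + (j - 1) * nvox]
  for (k in seq_along(idx)) {
    eg <- eigen(tensor3(cm[k, ]), symmetric = TRUE)
    lam <- eg$values  # decreasing
    i <- idx[k]
    l1[i] <- lam[1]; l2[i] <- lam[2]; l3[i] <- lam[3]
    mdv <- mean(lam)
    md[i] <- mdv; ad[i] <- lam[1]; rd[i] <- (lam[2] + lam[3]) / 2
    denom <- sqrt(sum(lam^2))
    fa[i] <- if (denom > 0) sqrt(1.5) * sqrt(sum((lam - mdv)^2)) / denom else 0
    v1[i] <- eg$vectors[1, 1]
    v1[i + nvox] <- eg$vectors[2, 1]
    v1[i + 2 * nvox] <- eg$vectors[3, 1]
  }
  structure(list(fa = fa, md = md, ad = ad, rd = rd,
                 l1 = l1, l2 = l2, l3 = l3, v1 = v1),
            class = "n2a_dti_metrics")
}

#' Encoding-matrix condition number of a six-direction scheme
#'
#' Builds the 6x6 matrix with rows `[gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz,
#' 2 gy gz]` (one per direction) and returns its 2-norm condition number.
#' Degenerate geometries (rank < 6) return `Inf` with attribute
#' `degenerate = TRUE`.
#'
#' @param directions a 6 x 3 matrix of unit vectors (or an
#'   [direction_set()] with exactly six nonzero-b entries).
#' @return Scalar condition number >= 1 (or `Inf`).
#' @export
condition_number <- function(directions) {
  if (inherits(directions, "n2a_direction_set"))
    directions <- directions$directions[directions$bvalues > 0, , drop = FALSE]
  directions <- as.matrix(directions)
  if (nrow(directions) != 6L) stop("exactly six directions are required")
  g <- directions
  M <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  d <- svd(M, nu = 0, nv = 0)$d
  if (d[6] <= d[1] * 1e-12) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d[1] / d[6]
}

# Spherical parameterization of k unit vectors (2k parameters).
angles_to_dirs <- function(theta) {
  k <- length(theta) / 2
  t1 <- theta[seq_len(k)]; t2 <- theta[k + seq_len(k)]
  cbind(sin(t1) * cos(t2), sin(t1) * sin(t2), cos(t1))
}

#' Optimize six encoding directions by condition-number minimization
#'
#' Multi-start local minimization (BFGS over spherical coordinates) of the
#' encoding-matrix condition number. The best-so-far value is non-increasing
#' in the number of restarts; the known optimum is approximately 1.3228.
#'
#' @param n number of directions (only 6 is supported).
#' @param restarts number of random restarts, >= 1.
#' @param seed integer seed for the restart stream.
#' @return List with `scheme` (an [direction_set()] at b = 1000 s/mm^2),
#'   `kappa` (best condition number), and `energy` (electrostatic energy of
#'   the best scheme).
#' @export
optimize_directions <- function(n = 6L, restarts = 100L, seed = 1L) {
  if (n != 6L) stop("condition-number design is defined for six directions")
  if (restarts < 1L) stop("restarts must be >= 1")
  set.seed(seed)
  obj <- function(theta) {
    k <- condition_number(angles_to_dirs(theta))
    if (!is.finite(k)) 1e6 else k
  }
  best <- Inf; best_theta <- NULL
  for (r in seq_len(restarts)) {
    theta0 <- c(acos(stats::runif(6, -1, 1)), stats::runif(6, 0, 2 * pi))
    fit <- try(stats::optim(theta0, obj, method = "BFGS",
                            control = list(maxit = 300, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$value < best) { best <- fit$value; best_theta <- fit$par }
  }
  dirs <- angles_to_dirs(best_theta)
  list(scheme = direction_set(dirs, rep(1000, 6)),
       kappa = condition_number(dirs),
       energy = electrostatic_energy(dirs))
}

#' Electrostatic potential energy of a direction set
#'
#' Coulomb-like energy over antipodally symmetrized directions:
#' `E = sum_{i<j} 1/|ui - uj| + 1/|ui + uj|`. Lower energy means more
#' uniformly distributed directions. Parallel or antiparallel pairs give
#' `Inf` with attribute `degenerate = TRUE`.
#'
#' @param directions an n x 3 matrix of unit vectors (n >= 2) or an
#'   [direction_set()] (nonzero-b entries used).
#' @return Scalar energy.
#' @export
electrostatic_energy <- function(directions) {
  if (inherits(directions, "n2a_direction_set"))
    directions <- directions$directions[directions$bvalues > 0, , drop = FALSE]
  u <- as.matrix(directions)
  n <- nrow(u)
  if (n < 2L) stop("need at least two directions")
  E <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm <- sqrt(sum((u[i, ] - u[j, ])^2))
      dp <- sqrt(sum((u[i, ] + u[j, ])^2))
      if (dm < 1e-12 || dp < 1e-12) {
        out <- Inf
        attr(out, "degenerate") <- TRUE
        return(out)
      }
      E <- E + 1 / dm + 1 / dp
    }
  }
  E
}

# Uniform random 3D rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  d <- diag(qr.R(qrd))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Antipodally-invariant angle between unit vectors, radians in [0, pi/2].
antipodal_angle <- function(u, v) acos(pmin(1, abs(drop(u %*% v))))

#' Select well-conditioned six-direction subsets near a rotated reference
#'
#' For each of `n_rotations` uniformly random rotations of the reference
#' scheme, picks for every rotated reference direction the nearest pool
#' direction (antipodally-invariant arc angle) and keeps the subset iff the
#' six picks are distinct and their condition number is below `kappa_max`
#' (default 1.6).
#'
#' @param pool an [direction_set()] with >= 6 nonzero-b directions.
#' @param reference an [direction_set()] (or 6 x 3 matrix) with six
#'   directions.
#' @param n_rotations number of random rotations to try.
#' @param kappa_max condition-number acceptance threshold.
#' @param seed integer seed.
#' @return List of accepted subsets; each is a 6 x 3 direction matrix with
#'   attributes `indices` (rows of the pool) and `kappa`. May be empty.
#' @export
select_nearest_subsets <- function(pool, reference, n_rotations = 100L,
                                   kappa_max = 1.6, seed = 1L) {
  pool_dirs <- if (inherits(pool, "n2a_direction_set"))
    pool$directions[pool$bvalues > 0, , drop = FALSE] else as.matrix(pool)
  ref <- if (inherits(reference, "n2a_direction_set"))
    reference$directions[reference$bvalues > 0, , drop = FALSE]
  else as.matrix(reference)
  if (nrow(pool_dirs) < 6L) stop("pool needs >= 6 directions")
  if (nrow(ref) != 6L) stop("reference must have six directions")
  set.seed(seed)
  out <- list()
  for (t in seq_len(n_rotations)) {
    R <- random_rotation()
    rotated <- ref %*% t(R)
    picks <- vapply(seq_len(6L), function(i) {
      ang <- antipodal_angle(pool_dirs, rotated[i, ])
      which.min(ang)
    }, integer(1))
    if (length(unique(picks)) < 6L) next
    sub <- pool_dirs[picks, , drop = FALSE]
    k <- condition_number(sub)
    if (is.finite(k) && k < kappa_max) {
      attr(sub, "indices") <- picks
      attr(sub, "kappa") <- k
      out[[length(out) + 1L]] <- sub
    }
  }
  out
}

#' Pick the minimum-energy pair of six-direction subsets
#'
#' Evaluates pairs of subsets by the electrostatic energy of their pooled 12
#' directions and returns the lowest-energy pair. All pairs are evaluated
#' when feasible (`n_trials` at least the number of pairs, or `NULL`);
#' otherwise `n_trials` random pairs are sampled. Pairs with non-finite
#' energy (parallel directions across subsets) are excluded.
#'
#' @param subsets list of >= 2 six-direction matrices
#'   (e.g. from [select_nearest_subsets()]).
#' @param n_trials number of sampled pairs, or `NULL` for exhaustive.
#' @param seed integer seed (sampling mode only).
#' @return List with `pair` (indices into `subsets`), `directions`
#'   (12 x 3), and `energy`.
#' @export
pick_min_energy_pair <- function(subsets, n_trials = NULL, seed = 1L) {
  m <- length(subsets)
  if (m < 2L) stop("need at least two subsets")
  all_pairs <- utils::combn(m, 2L)
  np <- ncol(all_pairs)
  if (is.null(n_trials) || n_trials >= np) {
    cand <- seq_len(np)
  } else {
    set.seed(seed)
    cand <- sample.int(np, n_trials)
  }
  best_e <- Inf; best <- NULL
  for (p in cand) {
    i <- all_pairs[1, p]; j <- all_pairs[2, p]
    dirs <- rbind(as.matrix(subsets[[i]]), as.matrix(subsets[[j]]))
    e <- electrostatic_energy(dirs)
    if (is.finite(e) && e < best_e) {
      best_e <- e
      best <- list(pair = c(i, j), directions = dirs, energy = e)
    }
  }
  if (is.null(best)) stop("no pair with finite energy")
  best
}

#' Read FSL-style bvec/bval files
#' @param bvec_path 3 x N whitespace-separated text file of directions.
#' @param bval_path 1 x N whitespace-separated text file of b-values.
#' @return An [direction_set()].
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L) stop("bvec file must have 3 rows")
  bval <- as.numeric(unlist(utils::read.table(bval_path)))
  direction_set(t(bvec), bval)
}

#' Write FSL-style bvec/bval files
#' @param scheme an [direction_set()].
#' @param bvec_path,bval_path output paths.
#' @return `bvec_path`, invisibly.
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  utils::write.table(t(scheme$directions), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  cat(paste(scheme$bvalues, collapse = " "), "\n", file = bval_path)
  invisible(bvec_path)
}
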