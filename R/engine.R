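#' Run configuration for the denoising engine
#'
#' @param iterations iteration count; default `NULL` picks 2 when n = 2 and
#'   1 when n > 2 (the recommended settings for pairs vs. larger repetition
#'   counts).
#' @param mode `"n2a"` (iterative average-target), `"n2n"` (other-repetition
#'   target), or `"supervised"` (ground-truth target).
#' @param networks_per `"shared"` (one network trained on all repetitions'
#'   pairs, the default), `"per_channel"` (one network per image channel,
#'   for multi-contrast inputs), or `"per_volume"` (one network per channel
#'   with all channels appended to the input, for many-direction diffusion
#'   data).
#' @param epochs_per_iteration fine-tuning epochs at each iteration.
#' @param warm_start if `TRUE` (default) iteration i + 1 resumes the weights
#'   from iteration i; if `FALSE` every iteration restarts from the weights
#'   the run began with.
#' @param block_shape block extent for training/inference grids (scalar or
#'   length 3); default 80 voxels, clamped to the volume extent.
#' @param seed integer seed for the run.
#' @return An object of class `n2a_run_config`.
#' @export
run_config <- function(iterations = NULL, mode = c("n2a", "n2n", "supervised"),
                       networks_per = c("shared", "per_channel", "per_volume"),
                       epochs_per_iteration = 10L, warm_start = TRUE,
                       block_shape = 80L, seed = 1L) {
  mode <- match.arg(mode)
  networks_per <- match.arg(networks_per)
  if (!is.null(iterations) && iterations < 1L) stop("iterations must be >= 1")
  structure(list(iterations = iterations, mode = mode,
                 networks_per = networks_per,
                 epochs_per_iteration = as.integer(epochs_per_iteration),
                 warm_start = isTRUE(warm_start),
                 block_shape = block_shape, seed = seed),
            class = "n2a_run_config")
}

#' Oracle denoisers for property testing
#'
#' Idealized denoisers that stand in for a trained network when testing the
#' iteration machinery: `perfect_target` returns the current training target
#' exactly (the ideal CNN); `matched_noise` returns the ground truth plus
#' fresh independent Gaussian noise whose variance matches the current
#' target's residual noise variance (the ideal CNN that matches target image
#' quality without copying its noise); `identity` returns its input
#' unchanged.
#'
#' @param kind oracle kind.
#' @param truth ground-truth volume, required for `matched_noise`.
#' @return An object of class `n2a_oracle`.
#' @export
oracle_denoiser <- function(kind = c("perfect_target", "matched_noise",
                                     "identity"), truth = NULL) {
  kind <- match.arg(kind)
  if (kind == "matched_noise" && is.null(truth))
    stop("matched_noise oracle requires the ground truth")
  structure(list(kind = kind,
                 truth = if (!is.null(truth)) as_volume(truth)),
            class = "n2a_oracle")
}

is_oracle <- function(x) inherits(x, "n2a_oracle")

# Apply an oracle to one repetition given the current target.
oracle_apply <- function(oracle, input, target, mask) {
  switch(oracle$kind,
    identity = input,
    perfect_target = target,
    matched_noise = {
      # per-channel noise variance of the current target, estimated against
      # the oracle's ground truth inside the mask
      a <- vol_data4(oracle$truth)
      nc <- dim(a)[4]
      for (c in seq_len(nc)) {
        tv <- masked_values(target, mask, c) -
              masked_values(oracle$truth, mask, c)
        v <- mean(tv^2)
        a[, , , c] <- a[, , , c] +
          array(stats::rnorm(prod(dim(a)[1:3]), 0, sqrt(v)), dim(a)[1:3])
      }
      vol_like(a, as_volume(input))
    })
}

#' Build the training target for one iteration
#'
#' Iteration 1 targets the voxelwise mean of all n noisy repetitions;
#' iteration i >= 2 targets the previous iteration's output (the voxelwise
#' mean of its per-repetition denoised volumes).
#'
#' @param reps the repetition set (required at i = 1).
#' @param i iteration index, 1-based.
#' @param state_prev the previous `n2a_iteration` state (required at i >= 2).
#' @return A volume.
#' @export
build_iteration_target <- function(reps, i, state_prev = NULL) {
  if (i == 1L) {
    if (!inherits(reps, "n2a_repetition_set") || reps$n < 2L)
      stop("iteration 1 requires a repetition set with n >= 2")
    average_volumes(reps$repetitions)
  } else {
    if (is.null(state_prev) || !inherits(state_prev, "n2a_iteration"))
      stop("iteration ", i, " requires the previous iteration state")
    average_volumes(state_prev$denoised)
  }
}

#' Build standardized residual training pairs
#'
#' For every repetition r and every block b of the grid, produces the pair
#' (standardized input block of r, standardized residual block of
#' `target - r`, mask block). Blocks whose mask slice is empty are dropped.
#'
#' @param reps a repetition set.
#' @param target the training-target volume.
#' @param grid a block grid.
#' @param params standardization parameters.
#' @param channels optional integer vector restricting input channels.
#' @param target_channels optional integer vector restricting which target
#'   channels form the residual (defaults to `channels`).
#' @return List of pairs for [train_denoiser()]. Attribute
#'   `"n_dropped_empty"` counts mask-empty blocks removed per repetition.
#' @export
make_training_pairs <- function(reps, target, grid, params,
                                channels = NULL, target_channels = channels) {
  target <- as_volume(target)
  if (!identical(spatial_shape(target), spatial_shape(reps$mask)))
    stop("target shape does not match repetitions")
  mask_blocks <- extract_blocks(as_volume(array(as.numeric(reps$mask$data),
                                                dim(reps$mask$data))), grid)
  mask_blocks <- lapply(mask_blocks, function(b) {
    m <- b[, , , 1]; dim(m) <- dim(b)[1:3]; m > 0
  })
  keep <- vapply(mask_blocks, any, logical(1))
  st <- standardize(target, params)
  tgt_blocks <- extract_blocks(st, grid)
  pairs <- list()
  dropped <- 0L
  for (r in reps$repetitions) {
    sr <- standardize(r, params)
    in_blocks <- extract_blocks(sr, grid)
    for (j in seq_along(in_blocks)) {
      if (!keep[j]) { dropped <- dropped + 1L; next }
      inp <- in_blocks[[j]]
      res <- tgt_blocks[[j]] - in_blocks[[j]]
      if (!is.null(channels)) inp <- inp[, , , channels, drop = FALSE]
      if (!is.null(target_channels))
        res <- res[, , , target_channels, drop = FALSE]
      pairs[[length(pairs) + 1L]] <-
        list(input = inp, target = res, mask = mask_blocks[[j]])
    }
  }
  attr(pairs, "n_dropped_empty") <- dropped
  pairs
}

new_iteration_state <- function(i, target, denoised) {
  structure(list(index = i, target = target, denoised = denoised,
                 output = average_volumes(denoised)),
            class = "n2a_iteration")
}

#' @export
print.n2a_iteration <- function(x, ...) {
  cat("<n2a_iteration> i = ", x$index, ", n = ", length(x$denoised),
      " denoised repetition(s)\n", sep = "")
  invisible(x)
}

default_iterations <- function(cfg, n) {
  if (!is.null(cfg$iterations)) return(as.integer(cfg$iterations))
  if (n == 2L) 2L else 1L
}

# Shared setup: standardization from the repetition mean, grid over the mask.
engine_setup <- function(reps, cfg) {
  m <- average_volumes(reps$repetitions)
  params <- compute_standardization(m, reps$mask)
  grid <- plan_blocks(spatial_shape(reps$mask), cfg$block_shape,
                      channel_count = n_channels(reps$repetitions[[1]]))
  list(params = params, grid = grid, mean_vol = m)
}

# Denoise every repetition with a model or oracle for the current target.
denoise_reps <- function(denoiser, reps, target, params, grid) {
  lapply(reps$repetitions, function(r) {
    if (is_oracle(denoiser)) oracle_apply(denoiser, r, target, reps$mask)
    else denoise_volume(denoiser, r, reps$mask, params, grid)
  })
}

# Deep-copy list of models keyed by channel for per_channel/per_volume modes.
replicate_models <- function(model, k) lapply(seq_len(k), function(i) model)

#' Run the iterative average-target denoising loop
#'
#' At each iteration the training target is built ([build_iteration_target()]),
#' a trainable model is fine-tuned for `cfg$epochs_per_iteration` epochs on
#' the standardized residual pairs, every repetition is denoised, and the
#' denoised volumes are averaged into the iteration output. Oracle
#' denoisers skip training and are applied volume-wise.
#'
#' @param reps a repetition set with n >= 2.
#' @param denoiser an `n2a_denoiser`, a list of them (for `per_channel` /
#'   `per_volume` modes), or an [oracle_denoiser()].
#' @param cfg an [run_config()].
#' @param tcfg an [training_config()] (ignored for oracles).
#' @return List of `n2a_iteration` states, one per iteration; each holds the
#'   target, the per-repetition denoised volumes, and their average
#'   (`output`).
#' @export
noise2average_run <- function(reps, denoiser, cfg = run_config(),
                              tcfg = training_config()) {
  if (!inherits(reps, "n2a_repetition_set") || reps$n < 2L)
    stop("the average-target mode requires n >= 2 repetitions")
  n_iter <- default_iterations(cfg, reps$n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  states <- vector("list", n_iter)
  trainable <- !is_oracle(denoiser)
  if (trainable) {
    setup <- engine_setup(reps, cfg)
    models <- if (cfg$networks_per == "shared") list(denoiser)
              else if (is.list(denoiser) && !inherits(denoiser, "n2a_denoiser"))
                denoiser
              else replicate_models(denoiser,
                                    n_channels(reps$repetitions[[1]]))
    models0 <- models
  }
  state_prev <- NULL
  for (i in seq_len(n_iter)) {
    target <- build_iteration_target(reps, i, state_prev)
    if (trainable) {
      if (!cfg$warm_start && i > 1L) models <- models0
      itcfg <- tcfg
      itcfg$epochs <- rep(cfg$epochs_per_iteration, length(tcfg$learning_rate))
      if (length(itcfg$epochs) > 1L) itcfg$epochs <- itcfg$epochs[1]
      if (length(itcfg$learning_rate) > 1L)
        itcfg$learning_rate <- itcfg$learning_rate[1]
      if (!is.null(itcfg$seed)) itcfg$seed <- itcfg$seed + i
      models <- train_engine_models(models, reps, target, setup, cfg, itcfg)
      denoised <- denoise_engine_models(models, reps, setup, cfg)
    } else {
      denoised <- denoise_reps(denoiser, reps, target, NULL, NULL)
    }
    state_prev <- new_iteration_state(i, target, denoised)
    states[[i]] <- state_prev
  }
  states
}

# Train the model set for one iteration under the configured sharing mode.
train_engine_models <- function(models, reps, target, setup, cfg, tcfg) {
  nc <- n_channels(reps$repetitions[[1]])
  if (cfg$networks_per == "shared") {
    pairs <- make_training_pairs(reps, target, setup$grid, setup$params)
    models[[1]] <- train_denoiser(models[[1]], pairs, tcfg)
  } else if (cfg$networks_per == "per_channel") {
    for (c in seq_len(nc)) {
      pairs <- make_training_pairs(reps, target, setup$grid, setup$params,
                                   channels = c)
      models[[c]] <- train_denoiser(models[[c]], pairs, tcfg)
    }
  } else {  # per_volume: all channels in, one channel out
    for (c in seq_len(nc)) {
      pairs <- make_training_pairs(reps, target, setup$grid, setup$params,
                                   channels = seq_len(nc),
                                   target_channels = c)
      models[[c]] <- train_denoiser(models[[c]], pairs, tcfg)
    }
  }
  models
}

denoise_engine_models <- function(models, reps, setup, cfg) {
  nc <- n_channels(reps$repetitions[[1]])
  if (cfg$networks_per == "shared") {
    lapply(reps$repetitions, function(r)
      denoise_volume(models[[1]], r, reps$mask, setup$params, setup$grid))
  } else {
    lapply(reps$repetitions, function(r) {
      sv <- standardize(r, setup$params)
      blocks <- extract_blocks(sv, setup$grid)
      den_blocks <- lapply(blocks, function(b) {
        out <- b
        for (c in seq_len(nc)) {
          inp <- if (cfg$networks_per == "per_channel")
            b[, , , c, drop = FALSE] else b
          res <- predict_residual(models[[c]], inp)
          out[, , , c] <- b[, , , c] + array(res, dim(b)[1:3])
        }
        out
      })
      out <- assemble_blocks(den_blocks, setup$grid,
                             voxel_size = r$voxel_size)
      vol_like(vol_data4(standardize(out, setup$params, inverse = TRUE)), r)
    })
  }
}

#' Run classic other-repetition-target denoising
#'
#' Training pairs map repetition k to repetition `(k mod n) + 1` (for n = 2,
#' the mutual pairing of the two repetitions). After training, each
#' repetition is denoised and the results are averaged.
#'
#' @inheritParams noise2average_run
#' @return The averaged denoised volume.
#' @export
noise2noise_run <- function(reps, denoiser, cfg = run_config(mode = "n2n"),
                            tcfg = training_config()) {
  if (!inherits(reps, "n2a_repetition_set") || reps$n < 2L)
    stop("this mode requires n >= 2 repetitions")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- reps$n
  partner <- function(k) (k %% n) + 1L
  if (is_oracle(denoiser)) {
    denoised <- lapply(seq_len(n), function(k)
      oracle_apply(denoiser, reps$repetitions[[k]],
                   reps$repetitions[[partner(k)]], reps$mask))
    return(average_volumes(denoised))
  }
  setup <- engine_setup(reps, cfg)
  pairs <- list()
  for (k in seq_len(n)) {
    sub <- repetition_set(list(reps$repetitions[[k]]), reps$mask,
                          require_pair = FALSE)
    pk <- make_training_pairs(sub, reps$repetitions[[partner(k)]],
                              setup$grid, setup$params)
    pairs <- c(pairs, pk)
  }
  itcfg <- tcfg
  itcfg$epochs <- cfg$epochs_per_iteration
  itcfg$learning_rate <- tcfg$learning_rate[1]
  model <- train_denoiser(denoiser, pairs, itcfg)
  denoised <- lapply(reps$repetitions, function(r)
    denoise_volume(model, r, reps$mask, setup$params, setup$grid))
  average_volumes(denoised)
}

#' Run supervised denoising against a ground-truth volume
#'
#' The input is the mean of the repetitions; the residual target is
#' `truth - input`. After training, the mean volume is denoised.
#'
#' @inheritParams noise2average_run
#' @param truth the ground-truth volume.
#' @return The denoised volume.
#' @export
supervised_run <- function(reps, truth, denoiser,
                           cfg = run_config(mode = "supervised"),
                           tcfg = training_config()) {
  truth <- as_volume(truth)
  if (!identical(spatial_shape(truth), spatial_shape(reps$mask)))
    stop("truth shape does not match repetitions")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  input <- average_volumes(reps$repetitions)
  if (is_oracle(denoiser))
    return(oracle_apply(denoiser, input, truth, reps$mask))
  setup <- engine_setup(reps, cfg)
  sub <- repetition_set(list(input), reps$mask, require_pair = FALSE)
  pairs <- make_training_pairs(sub, truth, setup$grid, setup$params)
  itcfg <- tcfg
  itcfg$epochs <- cfg$epochs_per_iteration
  itcfg$learning_rate <- tcfg$learning_rate[1]
  model <- train_denoiser(denoiser, pairs, itcfg)
  denoise_volume(model, input, reps$mask, setup$params, setup$grid)
}

#' Pretrain a denoiser on a corpus of simulated phantoms
#'
#' For every phantom, simulates a noisy volume and builds supervised
#' residual pairs against the phantom's own truth; trains with a fixed
#' 80/20 subject-level split and the (possibly two-phase) learning-rate
#' schedule carried by `tcfg`. The returned model is intended as the warm
#' start for subject-specific fine-tuning.
#'
#' @param phantoms list of >= 2 phantoms.
#' @param sim an [simulation_config()] describing the corpus noise (e.g.
#'   sigma = 0.5 for T1w-style corpora; 0.1 for b0 / 0.3 for DWI channels
#'   in diffusion-style corpora).
#' @param ncfg an [network_config()].
#' @param tcfg an [training_config()]; vector `learning_rate`/`epochs`
#'   encode the schedule (defaults mimic 1e-4 then 1e-5).
#' @param block_shape training block extent.
#' @param seed initialization seed for the fresh model.
#' @return A pretrained `n2a_denoiser`.
#' @export
pretrain_on_corpus <- function(phantoms, sim, ncfg,
                               tcfg = training_config(
                                 learning_rate = c(1e-4, 1e-5),
                                 epochs = c(20L, 20L)),
                               block_shape = 80L, seed = 1L) {
  if (length(phantoms) < 2L) stop("need at least 2 phantoms for a corpus split")
  model <- build_munet(ncfg, seed = seed)
  pairs <- list()
  subject_of <- integer(0)
  for (s in seq_along(phantoms)) {
    ph <- phantoms[[s]]
    sim_s <- sim
    sim_s$n_repetitions <- 1L
    if (!is.null(sim$seed)) sim_s$seed <- sim$seed + s
    reps <- simulate_repetitions(ph, sim_s)
    params <- compute_standardization(reps$repetitions[[1]], reps$mask)
    grid <- plan_blocks(spatial_shape(reps$mask), block_shape,
                        n_channels(reps$repetitions[[1]]))
    pk <- make_training_pairs(reps, ph$truth, grid, params)
    pairs <- c(pairs, pk)
    subject_of <- c(subject_of, rep(s, length(pk)))
  }
  ns <- length(phantoms)
  n_val_subj <- max(1L, round(0.2 * ns))
  if (!is.null(tcfg$seed)) set.seed(tcfg$seed)
  val_subjects <- sample.int(ns, n_val_subj)
  val_indices <- which(subject_of %in% val_subjects)
  train_denoiser(model, pairs, tcfg, val_indices = val_indices)
}

#' Write a JSON provenance record for a run
#'
#' @param path output JSON path.
#' @param cfg,tcfg run and training configurations.
#' @param extra optional named list appended to the record (e.g. per
#'   iteration metrics).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, cfg = NULL, tcfg = NULL, extra = NULL) {
  rec <- list(package = "noise2average",
              version = as.character(utils::packageVersion("noise2average")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              run_config = if (!is.null(cfg)) unclass(cfg),
              training_config = if (!is.null(tcfg)) unclass(tcfg))
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
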