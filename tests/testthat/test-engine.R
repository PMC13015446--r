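test_that("iteration targets are repetition means, then previous outputs", {
  tw <- tiny_reps(n = 2, sh = c(8, 8, 8), seed = 1)
  A <- tw$reps$repetitions[[1]]$data
  B <- tw$reps$repetitions[[2]]$data
  t1 <- build_iteration_target(tw$reps, 1)
  expect_equal(t1$data, (A + B) / 2)
  D1 <- as_volume(A * 0.9); D2 <- as_volume(B * 1.1)
  st <- noise2average:::new_iteration_state(1, t1, list(D1, D2))
  t2 <- build_iteration_target(tw$reps, 2, st)
  expect_equal(t2$data, (D1$data + D2$data) / 2)
  expect_error(
    build_iteration_target(repetition_set(list(as_volume(A)),
                                          array(TRUE, c(8, 8, 8)),
                                          require_pair = FALSE), 1),
    "n >= 2")
  expect_error(build_iteration_target(tw$reps, 2), "previous")
})

test_that("training pairs hold standardized inputs and exact residuals", {
  tw <- tiny_reps(n = 2, sh = c(10, 10, 10), sigma = 2, seed = 2)
  grid <- plan_blocks(c(10, 10, 10), 6)  # 2 per axis -> 8 blocks
  target <- build_iteration_target(tw$reps, 1)
  params <- compute_standardization(target, tw$reps$mask)
  pairs <- make_training_pairs(tw$reps, target, grid, params)
  expect_length(pairs, 2 * 8)
  st <- standardize(target, params)
  tgt_blocks <- extract_blocks(st, grid)
  for (j in 1:8) {
    p <- pairs[[j]]  # first repetition's blocks come first
    expect_equal(p$input + p$target, tgt_blocks[[j]], tolerance = 1e-12)
  }
  # target == repetition r gives all-zero residuals for r's pairs
  pairs_r <- make_training_pairs(tw$reps, tw$reps$repetitions[[1]], grid,
                                 params)
  for (j in 1:8) expect_equal(max(abs(pairs_r[[j]]$target)), 0)
  # empty-mask blocks are dropped
  m2 <- array(FALSE, c(10, 10, 10)); m2[1:4, 1:4, 1:4] <- TRUE
  reps2 <- repetition_set(tw$reps$repetitions, m2)
  pairs2 <- make_training_pairs(reps2, target, grid, params)
  expect_lt(length(pairs2), 16)
  expect_gt(attr(pairs2, "n_dropped_empty"), 0)
})

test_that("the perfect-target oracle makes iteration one a fixed point", {
  set.seed(3)
  A <- array(sample(0:200, 12^3, TRUE), c(12, 12, 12))
  B <- array(sample(0:200, 12^3, TRUE), c(12, 12, 12))
  reps <- repetition_set(list(A, B), array(TRUE, c(12, 12, 12)))
  st <- noise2average_run(reps, oracle_denoiser("perfect_target"),
                          run_config(iterations = 4, seed = 1))
  expect_identical(st[[1]]$output$data, (A + B) / 2)
  for (i in 2:4)
    expect_identical(st[[i]]$output$data, st[[1]]$output$data)
  # every state satisfies output == mean(denoised)
  for (s in st)
    expect_equal(s$output$data,
                 Reduce("+", lapply(s$denoised, function(v) v$data)) /
                   length(s$denoised))
})

test_that("identity oracle collapses all modes onto plain averaging", {
  tw <- tiny_reps(n = 3, sh = c(10, 10, 10), seed = 4)
  mean_data <- Reduce("+", lapply(tw$reps$repetitions,
                                  function(v) v$data)) / 3
  o <- oracle_denoiser("identity")
  s_n2a <- noise2average_run(tw$reps, o, run_config(iterations = 1, seed = 1))
  expect_equal(s_n2a[[1]]$output$data, mean_data)
  s_n2n <- noise2noise_run(tw$reps, o)
  expect_equal(s_n2n$data, mean_data)
})

test_that("cyclic pairing drives the other-repetition baseline", {
  tw <- tiny_reps(n = 2, sh = c(8, 8, 8), seed = 5)
  # perfect-target oracle returns each repetition's assigned partner;
  # averaging the swapped pair reproduces the repetition mean
  out <- noise2noise_run(tw$reps, oracle_denoiser("perfect_target"))
  mean_data <- (tw$reps$repetitions[[1]]$data +
                  tw$reps$repetitions[[2]]$data) / 2
  expect_equal(out$data, mean_data)
})

test_that("supervised mode targets the ground truth", {
  tw <- tiny_reps(n = 2, sh = c(8, 8, 8), seed = 6)
  out <- supervised_run(tw$reps, tw$truth, oracle_denoiser("perfect_target"))
  expect_equal(out$data, tw$truth$data)
})

test_that("the matched-noise oracle obeys the n^(i+1) variance schedule", {
  # pure-noise phantom at moderate size; the acceptance suite re-checks this
  # at 10^6 voxels for n in {2,3}
  sh <- c(64, 64, 64)
  truth <- as_volume(array(0, sh))
  set.seed(7)
  reps <- repetition_set(lapply(1:2, function(k) array(rnorm(prod(sh)), sh)),
                         array(TRUE, sh))
  st <- noise2average_run(reps, oracle_denoiser("matched_noise", truth = truth),
                          run_config(iterations = 2, seed = 8))
  v1 <- stats::var(as.vector(st[[1]]$output$data))
  v2 <- stats::var(as.vector(st[[2]]$output$data))
  expect_equal(v1, 1 / 4, tolerance = 0.05)
  expect_equal(v2, 1 / 8, tolerance = 0.05)
})

test_that("a trained network improves on the repetition average", {
  # small end-to-end run; the acceptance suite runs the full-size version
  ph <- make_structural_phantom(32, seed = 11)
  reps <- simulate_repetitions(ph, simulation_config(sigma = 0.3,
                                                     n_repetitions = 2,
                                                     seed = 21))
  params <- compute_standardization(ph$truth, ph$mask)
  model <- build_munet(network_config(4, 8, 1), seed = 31)
  st <- noise2average_run(reps, model,
                         run_config(iterations = 1, epochs_per_iteration = 10,
                                    block_shape = 16, seed = 41),
                         training_config(loss = "mse", learning_rate = 1e-3,
                                         seed = 51))
  m_avg <- image_similarity(build_iteration_target(reps, 1), ph$truth,
                            reps$mask, params)
  m_i1 <- image_similarity(st[[1]]$output, ph$truth, reps$mask, params)
  expect_gt(m_i1$psnr, m_avg$psnr)
})

test_that("per-channel and per-volume network modes denoise multi-channel data", {
  set.seed(12)
  sh <- c(12, 12, 12)
  truth <- array(rnorm(prod(sh) * 2, 100, 10), c(sh, 2))
  mask <- array(TRUE, sh)
  reps <- repetition_set(list(
    as_volume(truth + array(rnorm(prod(sh) * 2), c(sh, 2))),
    as_volume(truth + array(rnorm(prod(sh) * 2), c(sh, 2)))), mask)
  for (mode in c("per_channel", "per_volume")) {
    ncfg <- network_config(2, 3,
                           input_channels = if (mode == "per_volume") 2L else 1L,
                           output_channels = 1L)
    st <- noise2average_run(reps, build_munet(ncfg, seed = 1),
                           run_config(iterations = 1, epochs_per_iteration = 2,
                                      networks_per = mode, block_shape = 12,
                                      seed = 5),
                           training_config(loss = "mae", learning_rate = 1e-3,
                                           seed = 6))
    expect_identical(dim(st[[1]]$output$data), as.integer(c(sh, 2)))
    expect_true(all(is.finite(st[[1]]$output$data)))
  }
})

test_that("corpus pretraining uses a subject-level split and a usable model", {
  phantoms <- lapply(1:5, function(s) make_structural_phantom(32, seed = s))
  sim <- simulation_config(sigma = 0.5, n_repetitions = 1, seed = 100)
  m <- pretrain_on_corpus(phantoms, sim, network_config(2, 4, 1),
                          tcfg = training_config(loss = "mse",
                                                 learning_rate = c(1e-3, 1e-4),
                                                 epochs = c(2L, 1L), seed = 3),
                          block_shape = 32, seed = 7)
  expect_s3_class(m, "n2a_denoiser")
  expect_equal(nrow(m$training_log), 3L)  # two-phase schedule: 2 + 1 epochs
  expect_equal(unique(m$training_log$lr), c(1e-3, 1e-4))
  # the pretrained model denoises a new subject's volume
  ph <- make_structural_phantom(32, seed = 99)
  reps <- simulate_repetitions(ph, simulation_config(sigma = 0.5,
                                                     n_repetitions = 2,
                                                     seed = 101))
  params <- compute_standardization(build_iteration_target(reps, 1), reps$mask)
  grid <- plan_blocks(spatial_shape(reps$mask), 32)
  out <- denoise_volume(m, reps$repetitions[[1]], reps$mask, params, grid)
  expect_true(all(is.finite(out$data)))
  expect_error(pretrain_on_corpus(phantoms[1], sim, network_config(2, 4, 1)),
               "at least 2")
})
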