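# Shared in-code fixtures for the test suite; everything is generated
# deterministically at test time.

# A small repetition set with known truth: constant background + noise.
tiny_reps <- function(n = 2, sh = c(16, 16, 16), sigma = 1, seed = 1,
                      truth_value = 100) {
  set.seed(seed)
  truth <- array(truth_value, sh)
  reps <- lapply(seq_len(n), function(k)
    truth + array(rnorm(prod(sh), 0, sigma), sh))
  list(truth = as_volume(truth),
       reps = repetition_set(reps, array(TRUE, sh)))
}

# A structured two-channel volume for standardization tests.
two_channel_volume <- function(sh = c(8, 8, 8), seed = 3) {
  set.seed(seed)
  arr <- array(0, c(sh, 2))
  arr[, , , 1] <- array(rnorm(prod(sh), 10, 2), sh)
  arr[, , , 2] <- array(rnorm(prod(sh), -5, 7), sh)
  as_volume(arr)
}

# A well-conditioned seven-entry DTI scheme: one b=0 plus six directions.
test_scheme <- function(b = 1000) {
  g <- rbind(c(0, 0, 0),
             c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  direction_set(g, c(0, rep(b, 6)))
}
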