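#' Network architecture configuration
#'
#' Describes a modified 3D U-Net (MU-Net): a cascade of `depth` 3x3x3
#' convolutions at full resolution (stride 1, same padding, no pooling or
#' up-sampling), rectifier activations after every layer except the last,
#' and concatenation skips joining each early layer's output to the
#' matched-depth late layer's input. The last layer is linear and maps to
#' `output_channels` (the residual head). Two reference variants from the
#' study setup: 18 layers x 64 channels for T1w data, and 10 layers x 192
#' channels with batch normalization before every convolution for
#' multi-channel diffusion data.
#'
#' @param depth number of convolution layers, >= 2.
#' @param channels feature channels at intermediate layers, >= 1.
#' @param input_channels image channels of the input block.
#' @param output_channels channels of the predicted residual.
#' @param use_batchnorm apply batch normalization before every convolution.
#' @return An object of class `n2a_network_config`.
#' @export
network_config <- function(depth = 18L, channels = 64L, input_channels = 1L,
                           output_channels = input_channels,
                           use_batchnorm = FALSE) {
  depth <- as.integer(depth); channels <- as.integer(channels)
  if (depth < 2L) stop("depth must be >= 2")
  if (channels < 1L) stop("channels must be >= 1")
  structure(list(depth = depth, channels = channels,
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels),
                 use_batchnorm = isTRUE(use_batchnorm),
                 kernel = c(3L, 3L, 3L), stride = c(1L, 1L, 1L)),
            class = "n2a_network_config")
}

# Per-layer channel plan. skip_src[i] is the index (0 = network input) of the
# early activation concatenated onto layer i's input, or NA. The symmetric
# matched-depth rule pairs layer i with activation depth - i, so the final
# layer always sees the raw input alongside the deepest features.
munet_plan <- function(config) {
  D <- config$depth; C <- config$channels
  out_ch <- c(config$input_channels, rep(C, D - 1L), config$output_channels)
  # out_ch[i+1] = channels of activation i (activation 0 = input)
  skip_src <- rep(NA_integer_, D)
  for (i in seq_len(D)) {
    src <- D - i
    if (src >= 0L && src < i - 1L) skip_src[i] <- src
  }
  in_ch <- integer(D)
  for (i in seq_len(D)) {
    in_ch[i] <- out_ch[i]
    if (!is.na(skip_src[i])) in_ch[i] <- in_ch[i] + out_ch[skip_src[i] + 1L]
  }
  list(in_ch = in_ch, out_ch = out_ch[-1L], skip_src = skip_src)
}

#' Build an MU-Net denoiser with freshly initialized parameters
#'
#' Hidden-layer weights use He initialization scaled by fan-in; biases start
#' at zero; batch-norm scales and shifts start at one and zero. The final
#' (residual head) layer starts at exactly zero, so an untrained network
#' predicts a zero residual and denoising starts from the identity — the
#' standard initialization for residual-learning denoisers, which lets
#' short fine-tuning schedules improve on, rather than first recover, the
#' input baseline. Initialization is deterministic under `seed`, and the
#' parameter count is a deterministic function of the configuration.
#'
#' @param config an [network_config()].
#' @param seed integer seed for the initialization.
#' @return An object of class `n2a_denoiser` (a trainable residual
#'   predictor).
#' @export
build_munet <- function(config, seed = 1L) {
  if (!inherits(config, "n2a_network_config")) stop("not a network config")
  plan <- munet_plan(config)
  set.seed(seed)
  params <- list()
  for (i in seq_len(config$depth)) {
    fan_in <- 27L * plan$in_ch[i]
    W <- if (i == config$depth)
      matrix(0, nrow = fan_in, ncol = plan$out_ch[i])
    else
      matrix(stats::rnorm(fan_in * plan$out_ch[i], 0, sqrt(2 / fan_in)),
             nrow = fan_in, ncol = plan$out_ch[i])
    params[[paste0("W", i)]] <- W
    params[[paste0("b", i)]] <- numeric(plan$out_ch[i])
    if (config$use_batchnorm) {
      params[[paste0("g", i)]] <- rep(1, plan$in_ch[i])
      params[[paste0("be", i)]] <- rep(0, plan$in_ch[i])
    }
  }
  bn_stats <- NULL
  if (config$use_batchnorm)
    bn_stats <- lapply(seq_len(config$depth), function(i)
      list(mean = rep(0, plan$in_ch[i]), var = rep(1, plan$in_ch[i])))
  structure(list(config = config, plan = plan, params = params,
                 bn_stats = bn_stats, opt = NULL,
                 training_log = NULL, init_seed = seed),
            class = "n2a_denoiser")
}

#' Number of trainable parameters of a denoiser
#' @param model an `n2a_denoiser`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.n2a_denoiser <- function(x, ...) {
  cfg <- x$config
  cat("<n2a_denoiser> MU-Net: depth ", cfg$depth, ", ", cfg$channels,
      " channels, ", cfg$input_channels, " -> ", cfg$output_channels,
      " image channels", if (cfg$use_batchnorm) ", batchnorm",
      "; ", n_parameters(x), " parameters\n", sep = "")
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Forward pass. x: 4D array (X,Y,Z,Cin). Returns list(out, cache) where
# cache holds what backward needs. train controls batch-norm statistics.
munet_forward <- function(model, x, train = FALSE, keep_cache = TRUE) {
  cfg <- model$config; plan <- model$plan
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4] != cfg$input_channels)
    stop("input has ", dim(x)[4], " channel(s), network expects ",
         cfg$input_channels)
  D <- cfg$depth
  acts <- vector("list", D + 1L)   # acts[[i+1]] = activation i
  acts[[1]] <- x
  cache <- if (keep_cache) vector("list", D) else NULL
  sh <- dim(x)[1:3]
  for (i in seq_len(D)) {
    inp <- acts[[i]]
    src <- plan$skip_src[i]
    if (!is.na(src)) {
      skip <- acts[[src + 1L]]
      cat_arr <- array(0, c(sh, dim(inp)[4] + dim(skip)[4]))
      cat_arr[, , , seq_len(dim(inp)[4])] <- inp
      cat_arr[, , , dim(inp)[4] + seq_len(dim(skip)[4])] <- skip
      inp <- cat_arr
    }
    bn <- NULL
    if (cfg$use_batchnorm) {
      bn <- bn_forward(inp, model$params[[paste0("g", i)]],
                       model$params[[paste0("be", i)]],
                       model$bn_stats[[i]], train)
      inp_conv <- bn$y
    } else inp_conv <- inp
    z <- conv3d_fwd(inp_conv, model$params[[paste0("W", i)]],
                    model$params[[paste0("b", i)]])
    a <- if (i < D) pmax(z, 0) else z
    dim(a) <- dim(z)
    acts[[i + 1L]] <- a
    if (keep_cache)
      cache[[i]] <- list(x_cat = inp, x_conv = inp_conv, z = z, bn = bn)
  }
  list(out = acts[[D + 1L]], acts = acts, cache = cache)
}

bn_forward <- function(x, gamma, beta, stats, train) {
  d <- dim(x); nc <- d[4]; nvox <- prod(d[1:3])
  y <- x
  m <- v <- numeric(nc)
  xhat <- x
  for (c in seq_len(nc)) {
    xc <- x[, , , c]
    if (train) {
      m[c] <- mean(xc); v[c] <- mean((xc - m[c])^2)
    } else {
      m[c] <- stats$mean[c]; v[c] <- stats$var[c]
    }
    istd <- 1 / sqrt(v[c] + bn_eps)
    xh <- (xc - m[c]) * istd
    xhat[, , , c] <- xh
    y[, , , c] <- gamma[c] * xh + beta[c]
  }
  list(y = y, xhat = xhat, mean = m, var = v)
}

# Flip weights for the input-gradient convolution: W (27*Ci x Co) -> (27*Co x Ci)
flip_weights <- function(W, ci, co) {
  arr <- array(W, c(3, 3, 3, ci, co))
  arr <- arr[3:1, 3:1, 3:1, , , drop = FALSE]
  arr <- aperm(arr, c(1, 2, 3, 5, 4))
  matrix(arr, nrow = 27 * co, ncol = ci)
}

# Backward pass: grad_out is dLoss/d(network output). Returns named list of
# gradients matching model$params, plus updated bn running stats.
munet_backward <- function(model, fw, grad_out) {
  cfg <- model$config; plan <- model$plan; D <- cfg$depth
  grads <- list()
  # grad wrt each activation (index i+1 <-> activation i)
  gact <- vector("list", D + 1L)
  gact[[D + 1L]] <- grad_out
  for (i in rev(seq_len(D))) {
    ci <- cache_i <- fw$cache[[i]]
    g_a <- gact[[i + 1L]]
    if (i < D) {
      g_z <- g_a * (cache_i$z > 0)
      dim(g_z) <- dim(g_a)
    } else g_z <- g_a
    gw <- conv3d_gradw(cache_i$x_conv, g_z)
    grads[[paste0("W", i)]] <- gw$gw
    grads[[paste0("b", i)]] <- gw$gb
    in_ch <- plan$in_ch[i]
    Wf <- flip_weights(model$params[[paste0("W", i)]], in_ch, plan$out_ch[i])
    g_xconv <- conv3d_fwd(g_z, Wf, numeric(in_ch))
    if (cfg$use_batchnorm) {
      bb <- bn_backward(g_xconv, cache_i$bn,
                        model$params[[paste0("g", i)]])
      grads[[paste0("g", i)]] <- bb$dgamma
      grads[[paste0("be", i)]] <- bb$dbeta
      g_xcat <- bb$dx
    } else g_xcat <- g_xconv
    # split concat gradient back onto the main path and the skip source
    src <- plan$skip_src[i]
    prev_ch <- dim(fw$acts[[i]])[4]
    if (length(dim(fw$acts[[i]])) == 3L) prev_ch <- 1L
    g_prev <- g_xcat[, , , seq_len(prev_ch), drop = FALSE]
    if (is.null(gact[[i]])) gact[[i]] <- g_prev
    else gact[[i]] <- gact[[i]] + g_prev
    if (!is.na(src)) {
      g_skip <- g_xcat[, , , prev_ch + seq_len(dim(g_xcat)[4] - prev_ch),
                       drop = FALSE]
      if (is.null(gact[[src + 1L]])) gact[[src + 1L]] <- g_skip
      else gact[[src + 1L]] <- gact[[src + 1L]] + g_skip
    }
  }
  grads
}

bn_backward <- function(dy, bn, gamma) {
  d <- dim(dy); nc <- d[4]; N <- prod(d[1:3])
  dx <- dy
  dgamma <- dbeta <- numeric(nc)
  for (c in seq_len(nc)) {
    dyc <- dy[, , , c]; xh <- bn$xhat[, , , c]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    istd <- 1 / sqrt(bn$var[c] + bn_eps)
    dxh <- dyc * gamma[c]
    dx[, , , c] <- istd / N * (N * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Masked training loss
#'
#' Mean squared error or mean absolute error over the voxels inside the
#' mask only (across all channels); voxels outside the mask contribute
#' nothing. A block whose mask slice is empty returns 0 (such blocks are
#' excluded from training pairs upstream).
#'
#' @param prediction,target numeric arrays of identical shape (3D or 4D).
#' @param mask logical 3D array matching the spatial shape.
#' @param loss_type `"mse"` or `"mae"`.
#' @return Scalar loss.
#' @export
masked_loss <- function(prediction, target, mask, loss_type = c("mse", "mae")) {
  loss_type <- match.arg(loss_type)
  if (!identical(dim(prediction), dim(target)))
    stop("prediction and target shapes differ")
  p <- prediction; t <- target
  if (length(dim(p)) == 3L) { dim(p) <- c(dim(p), 1L); dim(t) <- dim(p) }
  m <- if (inherits(mask, "n2a_mask")) mask$data else mask
  if (!identical(dim(m), dim(p)[1:3]))
    stop("mask shape does not match prediction")
  nm <- sum(m)
  if (nm == 0L) return(0)
  nc <- dim(p)[4]
  idx <- which(m)
  nvox <- prod(dim(p)[1:3])
  total <- 0
  for (c in seq_len(nc)) {
    dd <- p[idx + (c - 1) * nvox] - t[idx + (c - 1) * nvox]
    total <- total + if (loss_type == "mse") sum(dd^2) else sum(abs(dd))
  }
  total / (nm * nc)
}

# Gradient of masked_loss wrt prediction (same shape as prediction).
masked_loss_grad <- function(prediction, target, mask, loss_type) {
  p <- prediction; t <- target
  was3d <- length(dim(p)) == 3L
  if (was3d) { dim(p) <- c(dim(p), 1L); dim(t) <- dim(p) }
  m <- if (inherits(mask, "n2a_mask")) mask$data else mask
  nm <- sum(m); nc <- dim(p)[4]
  g <- array(0, dim(p))
  if (nm > 0L) {
    diff <- p - t
    for (c in seq_len(nc)) {
      dc <- diff[, , , c]
      gc <- if (loss_type == "mse") 2 * dc else sign(dc)
      gc[!m] <- 0
      g[, , , c] <- gc / (nm * nc)
    }
  }
  if (was3d) dim(g) <- dim(g)[1:3]
  g
}

#' Training configuration
#'
#' `learning_rate` and `epochs` may be vectors of equal length to describe a
#' multi-phase schedule (e.g. the pretraining schedule of 20 epochs at 1e-4
#' followed by 20 at 1e-5); fine-tuning typically uses a single phase.
#'
#' @param loss `"mse"` (T1w-style data) or `"mae"` (diffusion-style data).
#' @param learning_rate Adam step size(s).
#' @param epochs epoch count(s), one per schedule phase.
#' @param batch_size fixed at 1 (one block per gradient step).
#' @param val_fraction fraction of blocks held out for validation, in (0,1).
#' @param seed integer seed controlling the split stream and shuffling.
#' @return An object of class `n2a_training_config`.
#' @export
training_config <- function(loss = c("mse", "mae"), learning_rate = 1e-3,
                            epochs = 10L, batch_size = 1L,
                            val_fraction = 0.2, seed = NULL) {
  loss <- match.arg(loss)
  if (length(learning_rate) != length(epochs))
    stop("learning_rate and epochs must have the same length (schedule phases)")
  if (any(epochs < 1L)) stop("epochs must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (batch_size != 1L) stop("batch size is fixed at 1")
  structure(list(loss = loss, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = 1L,
                 val_fraction = val_fraction, seed = seed),
            class = "n2a_training_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a denoiser on residual block pairs
#'
#' Runs Adam (batch size 1) over the training split for the configured
#' epochs. By default the 80/20 train/validation split is re-drawn at every
#' epoch (Monte Carlo cross-validation); pass `val_indices` to fix a split
#' (used for subject-level pretraining splits). Training is deterministic
#' under `tcfg$seed` with single-threaded numerics.
#'
#' @param model an `n2a_denoiser`.
#' @param pairs list of training pairs, each `list(input =, target =,
#'   mask =)` with `input`/`target` 4D standardized blocks (target is the
#'   residual) and `mask` the logical block mask.
#' @param tcfg an [training_config()].
#' @param val_indices optional fixed validation indices into `pairs`.
#' @return The updated model; `model$training_log` gains one row per epoch
#'   with train/validation loss.
#' @export
train_denoiser <- function(model, pairs, tcfg, val_indices = NULL) {
  if (!inherits(model, "n2a_denoiser")) stop("not a denoiser model")
  np <- length(pairs)
  if (np < 2L) stop("need at least 2 training pairs to form a split")
  if (!is.null(tcfg$seed)) set.seed(tcfg$seed)
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  n_val <- max(1L, round(tcfg$val_fraction * np))
  if (n_val >= np) n_val <- np - 1L
  log_rows <- list()
  epoch_global <- if (is.null(model$training_log)) 0L else nrow(model$training_log)
  for (phase in seq_along(tcfg$epochs)) {
    lr <- tcfg$learning_rate[phase]
    for (ep in seq_len(tcfg$epochs[phase])) {
      vidx <- if (is.null(val_indices)) sample.int(np, n_val) else val_indices
      tidx <- setdiff(seq_len(np), vidx)
      tidx <- tidx[sample.int(length(tidx))]
      tr_loss <- 0
      for (j in tidx) {
        pr <- pairs[[j]]
        fw <- munet_forward(model, pr$input, train = TRUE)
        l <- masked_loss(fw$out, pr$target, pr$mask, tcfg$loss)
        if (!is.finite(l))
          stop("training diverged: non-finite loss at epoch ",
               epoch_global + 1L, " (try a lower learning rate)")
        g <- masked_loss_grad(fw$out, pr$target, pr$mask, tcfg$loss)
        grads <- munet_backward(model, fw, g)
        upd <- adam_step(model$params, grads, model$opt, lr)
        model$params <- upd$params; model$opt <- upd$opt
        if (model$config$use_batchnorm) {
          for (i in seq_len(model$config$depth)) {
            bn <- fw$cache[[i]]$bn
            model$bn_stats[[i]]$mean <-
              (1 - bn_momentum) * model$bn_stats[[i]]$mean + bn_momentum * bn$mean
            model$bn_stats[[i]]$var <-
              (1 - bn_momentum) * model$bn_stats[[i]]$var + bn_momentum * bn$var
          }
        }
        tr_loss <- tr_loss + l
      }
      val_loss <- mean(vapply(vidx, function(j) {
        pr <- pairs[[j]]
        fw <- munet_forward(model, pr$input, train = FALSE, keep_cache = FALSE)
        masked_loss(fw$out, pr$target, pr$mask, tcfg$loss)
      }, numeric(1)))
      epoch_global <- epoch_global + 1L
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch_global, lr = lr,
                   train_loss = tr_loss / length(tidx), val_loss = val_loss)
    }
  }
  new_log <- do.call(rbind, log_rows)
  model$training_log <- if (is.null(model$training_log)) new_log
                        else rbind(model$training_log, new_log)
  model
}

#' Predict the residual for a single block
#' @param model an `n2a_denoiser`.
#' @param block 3D or 4D standardized input block.
#' @return Residual block with `output_channels` channels.
#' @export
predict_residual <- function(model, block) {
  if (length(dim(block)) == 3L) dim(block) <- c(dim(block), 1L)
  munet_forward(model, block, train = FALSE, keep_cache = FALSE)$out
}

#' Denoise a whole volume blockwise
#'
#' Standardizes the volume, predicts a residual for every block of the grid,
#' adds each residual back onto its input block (`denoised = input +
#' residual`), reassembles the blocks with overlap averaging, and inverts
#' the standardization.
#'
#' @param model an `n2a_denoiser` (or an oracle from [oracle_denoiser()],
#'   which bypasses the block machinery).
#' @param volume the noisy volume.
#' @param mask the brain mask (carried for interface symmetry; inference
#'   itself is unmasked).
#' @param params standardization parameters shared with training.
#' @param grid block grid from [plan_blocks()].
#' @return The denoised volume.
#' @export
denoise_volume <- function(model, volume, mask, params, grid) {
  volume <- as_volume(volume)
  sv <- standardize(volume, params)
  blocks <- extract_blocks(sv, grid)
  den <- lapply(blocks, function(b) b + predict_residual(model, b))
  out <- assemble_blocks(den, grid, voxel_size = volume$voxel_size)
  out <- standardize(out, params, inverse = TRUE)
  vol_like(vol_data4(out), volume)
}

#' Save a denoiser checkpoint
#'
#' Stores parameters, configuration, optimizer state, seeds, and the
#' training log in a single RDS file; the training log is additionally
#' written as CSV next to it.
#'
#' @param model an `n2a_denoiser`.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_denoiser <- function(model, path) {
  saveRDS(model, path)
  if (!is.null(model$training_log))
    utils::write.csv(model$training_log,
                     sub("\\.rds$", "_log.csv", path), row.names = FALSE)
  invisible(path)
}

#' Load a denoiser checkpoint
#' @param path path written by [save_denoiser()].
#' @return An `n2a_denoiser`.
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "n2a_denoiser")) stop("not a denoiser checkpoint")
  model
}
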