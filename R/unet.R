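#' 3D U-Net configuration
#'
#' An encoder-decoder with skip connections mapping a cubic patch to an
#' equally-sized output (voxel-wise restoration). `depth` is the number of
#' down/up resolution steps; each encoder level applies two 3x3x3
#' convolutions + ReLU and halves the grid, a two-conv bottleneck sits at
#' the bottom, and each decoder level upsamples (nearest), concatenates the
#' encoder skip and applies two convolutions; a final 1x1x1 convolution
#' produces the single-channel output.
#'
#' The `"full"` preset (depth 3, 32 base channels, 64-voxel patches) is
#' the full-scale configuration; the `"desk"` preset (depth 2, 8 channels,
#' 32-voxel patches) trains in minutes on one CPU and is what the test
#' suite uses.
#'
#' @param depth number of pooling steps (>= 1).
#' @param base_channels channels of the first encoder level.
#' @param patch_vox training patch edge; must be divisible by
#'   `pool_factor^depth`.
#' @param pool_factor grid reduction per level (fixed 2).
#' @return a `unet_config`.
#' @export
unet_config <- function(depth = 3, base_channels = 32, patch_vox = 64,
                        pool_factor = 2) {
  if (patch_vox %% pool_factor^depth != 0)
    stop(sprintf("patch_vox (%d) must be divisible by pool_factor^depth (%d)",
                 patch_vox, pool_factor^depth), call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 patch_vox = as.integer(patch_vox),
                 pool_factor = as.integer(pool_factor),
                 conv_kernel = 3L),
            class = "unet_config")
}

#' @rdname unet_config
#' @param preset `"full"` or `"desk"`.
#' @export
unet_preset <- function(preset = c("full", "desk")) {
  preset <- match.arg(preset)
  if (preset == "full") unet_config(3, 32, 64) else unet_config(2, 8, 32)
}

#' Training configuration
#'
#' @param loss `"L2"` (default) or `"L1"`.
#' @param learning_rate Adam step size.
#' @param iterations optimizer steps (>= 1).
#' @param batch_size patches per step.
#' @param seed controls weight init, batch order and the validation split.
#' @param validation_fraction fraction of pairs held out in \[0, 1).
#' @return a `training_config`.
#' @export
training_config <- function(loss = c("L2", "L1"), learning_rate = 1e-3,
                            iterations = 300, batch_size = 4, seed = 1,
                            validation_fraction = 0.1) {
  loss <- match.arg(loss)
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("`validation_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(loss = loss, learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "training_config")
}

# ---- architecture -----------------------------------------------------------

# conv layer table for a config: name, cin, cout, kernel
unet_layers <- function(cfg) {
  d <- cfg$depth; B <- cfg$base_channels
  ch <- B * 2^(seq_len(d) - 1)             # encoder level channels
  cb <- B * 2^d                            # bottleneck channels
  rows <- list()
  cin <- 1L
  for (l in seq_len(d)) {
    rows[[length(rows) + 1]] <- list(name = sprintf("enc%d_a", l), cin = cin, cout = ch[l], k = 3L)
    rows[[length(rows) + 1]] <- list(name = sprintf("enc%d_b", l), cin = ch[l], cout = ch[l], k = 3L)
    cin <- ch[l]
  }
  rows[[length(rows) + 1]] <- list(name = "bot_a", cin = cin, cout = cb, k = 3L)
  rows[[length(rows) + 1]] <- list(name = "bot_b", cin = cb, cout = cb, k = 3L)
  up <- cb
  for (l in rev(seq_len(d))) {
    rows[[length(rows) + 1]] <- list(name = sprintf("dec%d_a", l), cin = up + ch[l], cout = ch[l], k = 3L)
    rows[[length(rows) + 1]] <- list(name = sprintf("dec%d_b", l), cin = ch[l], cout = ch[l], k = 3L)
    up <- ch[l]
  }
  rows[[length(rows) + 1]] <- list(name = "out", cin = up, cout = 1L, k = 1L)
  rows
}

#' Build an untrained U-Net
#'
#' Initializes all convolution weights (He-normal, deterministic per seed)
#' for the given configuration.
#'
#' @param cfg a [unet_config()].
#' @param seed init seed.
#' @return a `unet_network`: config + named weight list.
#' @export
build_network <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "unet_config"))
  layers <- unet_layers(cfg)
  weights <- with_seed(seed, {
    out <- list()
    for (ly in layers) {
      fan_in <- ly$k^3 * ly$cin
      sd <- if (ly$name == "out") sqrt(1 / fan_in) else sqrt(2 / fan_in)
      out[[ly$name]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$cout, sd = sd), fan_in, ly$cout),
        b = rep(0, ly$cout), k = ly$k)
    }
    out
  })
  structure(list(config = cfg, weights = weights), class = "unet_network")
}

#' Number of trainable parameters
#' @param net a `unet_network` or `trained_restorer`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  w <- if (inherits(net, "trained_restorer")) net$weights else net$weights
  sum(vapply(w, function(p) length(p$W) + length(p$b), 0))
}

# ---- pooling / upsampling index caches --------------------------------------

pool_indices <- function(vd) {
  D <- vd[1]; H <- vd[2]; W <- vd[3]
  hd <- D %/% 2L; hh <- H %/% 2L; hw <- W %/% 2L
  base_i <- seq(1L, D, 2L); base_j <- seq(1L, H, 2L); base_k <- seq(1L, W, 2L)
  lin <- function(i, j, k) {
    outer(outer(i, (j - 1L) * D, `+`), (k - 1L) * D * H, `+`)
  }
  corners <- vector("list", 8)
  c_id <- 1L
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    corners[[c_id]] <- as.vector(lin(base_i + di, base_j + dj, base_k + dk))
    c_id <- c_id + 1L
  }
  list(corners = corners, out_dim = c(hd, hh, hw))
}

upsample_indices <- function(vd) {
  # vd = coarse dims; returns gather index of length prod(2*vd)
  D <- vd[1]; H <- vd[2]; W <- vd[3]
  i <- rep(seq_len(D), each = 2L)
  j <- rep(seq_len(H), each = 2L)
  k <- rep(seq_len(W), each = 2L)
  as.vector(outer(outer(i, (j - 1L) * D, `+`), (k - 1L) * D * H, `+`))
}

avg_pool <- function(x, vd) {
  px <- pool_indices(vd)
  acc <- x[px$corners[[1]], , drop = FALSE]
  for (c_id in 2:8) acc <- acc + x[px$corners[[c_id]], , drop = FALSE]
  list(y = acc / 8, out_dim = px$out_dim)
}

avg_pool_grad <- function(dy, vd) {
  px <- pool_indices(vd)
  dx <- matrix(0, prod(vd), ncol(dy))
  g <- dy / 8
  for (c_id in 1:8) dx[px$corners[[c_id]], ] <- g
  dx
}

upsample_nearest <- function(x, vd) {
  x[upsample_indices(vd), , drop = FALSE]
}

upsample_grad <- function(dy, vd) {
  # sum the 2x2x2 fine-grid block feeding each coarse voxel
  px <- pool_indices(2L * vd)
  acc <- dy[px$corners[[1]], , drop = FALSE]
  for (c_id in 2:8) acc <- acc + dy[px$corners[[c_id]], , drop = FALSE]
  acc
}

# ---- forward / backward -----------------------------------------------------

conv_fwd <- function(x, vd, p) {
  cpp_conv3_forward(x, as.integer(vd), p$W, p$b, p$k)
}

# forward pass on one sample; x: (N x 1) matrix, vd: dims
unet_forward <- function(weights, cfg, x, vd, keep_cache = FALSE) {
  d <- cfg$depth
  cache <- list(dims = list(), inputs = list(), relu = list(), skips = list())
  cur <- x; cur_vd <- vd
  run_conv <- function(name, act) {
    if (keep_cache) {
      cache$inputs[[name]] <<- cur
      cache$dims[[name]] <<- cur_vd
    }
    y <- conv_fwd(cur, cur_vd, weights[[name]])
    if (act) {
      if (keep_cache) cache$relu[[name]] <<- y > 0
      y[y < 0] <- 0
    }
    cur <<- y
  }
  for (l in seq_len(d)) {
    run_conv(sprintf("enc%d_a", l), TRUE)
    run_conv(sprintf("enc%d_b", l), TRUE)
    cache$skips[[l]] <- cur
    pooled <- avg_pool(cur, cur_vd)
    if (keep_cache) cache$dims[[sprintf("pool%d", l)]] <- cur_vd
    cur <- pooled$y; cur_vd <- pooled$out_dim
  }
  run_conv("bot_a", TRUE)
  run_conv("bot_b", TRUE)
  for (l in rev(seq_len(d))) {
    if (keep_cache) cache$dims[[sprintf("up%d", l)]] <- cur_vd
    cur <- upsample_nearest(cur, cur_vd)
    cur_vd <- 2L * cur_vd
    nskip <- ncol(cache$skips[[l]])
    cur <- cbind(cur, cache$skips[[l]])
    if (keep_cache) cache$dims[[sprintf("cat%d", l)]] <- nskip
    run_conv(sprintf("dec%d_a", l), TRUE)
    run_conv(sprintf("dec%d_b", l), TRUE)
  }
  run_conv("out", FALSE)
  list(y = cur, cache = if (keep_cache) cache else NULL)
}

# backward pass; dy: gradient at the output; returns named list of grads
unet_backward <- function(weights, cfg, cache, dy) {
  d <- cfg$depth
  grads <- list()
  back_conv <- function(name, dcur, through_relu) {
    if (through_relu) dcur <- dcur * cache$relu[[name]]
    g <- cpp_conv3_backward(cache$inputs[[name]], as.integer(cache$dims[[name]]),
                            weights[[name]]$W, dcur, weights[[name]]$k)
    grads[[name]] <<- list(W = g$dw, b = as.vector(g$db))
    g$dx
  }
  dcur <- back_conv("out", dy, FALSE)
  dskip <- vector("list", d)
  for (l in seq_len(d)) {
    dcur <- back_conv(sprintf("dec%d_b", l), dcur, TRUE)
    dcur <- back_conv(sprintf("dec%d_a", l), dcur, TRUE)
    nskip <- cache$dims[[sprintf("cat%d", l)]]
    nc <- ncol(dcur)
    dskip[[l]] <- dcur[, (nc - nskip + 1):nc, drop = FALSE]
    dup <- dcur[, 1:(nc - nskip), drop = FALSE]
    dcur <- upsample_grad(dup, cache$dims[[sprintf("up%d", l)]])
  }
  dcur <- back_conv("bot_b", dcur, TRUE)
  dcur <- back_conv("bot_a", dcur, TRUE)
  for (l in rev(seq_len(d))) {
    dcur <- avg_pool_grad(dcur, cache$dims[[sprintf("pool%d", l)]])
    dcur <- dcur + dskip[[l]]
    dcur <- back_conv(sprintf("enc%d_b", l), dcur, TRUE)
    dcur <- back_conv(sprintf("enc%d_a", l), dcur, TRUE)
  }
  grads
}

# ---- training ---------------------------------------------------------------

#' Train the restoration network
#'
#' Supervised voxel-wise regression from low-quality to high-quality
#' volumes with the Adam optimizer. Pairs should be normalized (the pair
#' factories do this by default); all pairs must share one shape. Training
#' is deterministic given `tcfg$seed`.
#'
#' @param pairs non-empty list of [training_pair()]s.
#' @param ucfg a [unet_config()]; the pair shape must be divisible by
#'   `pool_factor^depth`.
#' @param tcfg a [training_config()].
#' @param verbose print progress every 50 iterations.
#' @return a `trained_restorer` with elements `weights`, `config`,
#'   `normalization` (`"zscore"` tag), `history` (tibble: iteration, loss,
#'   val_loss) and `n_train`/`n_val`.
#' @export
train_restorer <- function(pairs, ucfg, tcfg, verbose = FALSE) {
  if (length(pairs) == 0) stop("need at least one training pair", call. = FALSE)
  shapes <- vapply(pairs, function(p) paste(dim(p$input_vol$values), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("training pairs have mismatched shapes: ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  vd <- dim(pairs[[1]]$input_vol$values)
  if (any(vd %% ucfg$pool_factor^ucfg$depth != 0))
    stop("pair shape must be divisible by pool_factor^depth", call. = FALSE)
  net <- build_network(ucfg, seed = tcfg$seed)
  n <- length(pairs)
  n_val <- floor(n * tcfg$validation_fraction)
  idx <- with_seed(tcfg$seed + 1L, sample.int(n))
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)
  if (length(train_idx) == 0) stop("no training pairs left after split", call. = FALSE)
  xs <- lapply(pairs, function(p) matrix(as.vector(p$input_vol$values), ncol = 1))
  ys <- lapply(pairs, function(p) matrix(as.vector(p$target_vol$values), ncol = 1))

  adam <- lapply(net$weights, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- tcfg$learning_rate
  history <- numeric(tcfg$iterations)
  val_hist <- rep(NA_real_, tcfg$iterations)
  batch_order <- with_seed(tcfg$seed + 2L, {
    n_draw <- tcfg$iterations * tcfg$batch_size
    reps <- ceiling(n_draw / length(train_idx))
    ord <- unlist(lapply(seq_len(reps), function(i) sample(train_idx)))
    ord[seq_len(n_draw)]
  })
  eval_loss <- function(i) {
    fw <- unet_forward(net$weights, ucfg, xs[[i]], vd)
    if (tcfg$loss == "L2") mean((fw$y - ys[[i]])^2) else mean(abs(fw$y - ys[[i]]))
  }
  for (it in seq_len(tcfg$iterations)) {
    batch <- batch_order[((it - 1) * tcfg$batch_size + 1):(it * tcfg$batch_size)]
    gacc <- NULL
    loss <- 0
    for (i in batch) {
      fw <- unet_forward(net$weights, ucfg, xs[[i]], vd, keep_cache = TRUE)
      resid <- fw$y - ys[[i]]
      if (tcfg$loss == "L2") {
        loss <- loss + mean(resid^2)
        dy <- 2 * resid / length(resid)
      } else {
        loss <- loss + mean(abs(resid))
        dy <- sign(resid) / length(resid)
      }
      g <- unet_backward(net$weights, ucfg, fw$cache, dy)
      if (is.null(gacc)) gacc <- g
      else for (nm in names(g)) {
        gacc[[nm]]$W <- gacc[[nm]]$W + g[[nm]]$W
        gacc[[nm]]$b <- gacc[[nm]]$b + g[[nm]]$b
      }
    }
    loss <- loss / length(batch)
    bc1 <- 1 - b1^it; bc2 <- 1 - b2^it
    for (nm in names(net$weights)) {
      gW <- gacc[[nm]]$W / length(batch)
      gb <- gacc[[nm]]$b / length(batch)
      a <- adam[[nm]]
      a$mW <- b1 * a$mW + (1 - b1) * gW
      a$vW <- b2 * a$vW + (1 - b2) * gW^2
      a$mb <- b1 * a$mb + (1 - b1) * gb
      a$vb <- b2 * a$vb + (1 - b2) * gb^2
      adam[[nm]] <- a
      net$weights[[nm]]$W <- net$weights[[nm]]$W -
        lr * (a$mW / bc1) / (sqrt(a$vW / bc2) + eps)
      net$weights[[nm]]$b <- net$weights[[nm]]$b -
        lr * (a$mb / bc1) / (sqrt(a$vb / bc2) + eps)
    }
    history[it] <- loss
    if (length(val_idx) > 0 && (it %% 25 == 0 || it == tcfg$iterations))
      val_hist[it] <- mean(vapply(val_idx, eval_loss, 0))
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d/%d  loss %.5f  val %.5f", it, tcfg$iterations,
                      loss, val_hist[it]))
  }
  structure(list(weights = net$weights, config = ucfg,
                 normalization = "zscore",
                 training = tcfg,
                 history = tibble::tibble(iteration = seq_len(tcfg$iterations),
                                          loss = history, val_loss = val_hist),
                 n_train = length(train_idx), n_val = length(val_idx),
                 format_version = "tomorest-model-1"),
            class = "trained_restorer")
}

#' @export
print.trained_restorer <- function(x, ...) {
  cat(sprintf("<trained_restorer> depth %d, base %d, %d parameters\n",
              x$config$depth, x$config$base_channels, n_parameters(x)))
  cat(sprintf("  %d iterations, final loss %.5f (%d train / %d val pairs)\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              x$n_train, x$n_val))
  invisible(x)
}

#' Predict one patch with a network
#'
#' Pure function of (weights, input): deterministic across calls.
#'
#' @param model a `trained_restorer` (or `unet_network`).
#' @param patch numeric 3D array with dims divisible by
#'   `pool_factor^depth`.
#' @return restored array of the same shape.
#' @export
predict_patch <- function(model, patch) {
  cfg <- model$config
  vd <- dim(patch)
  if (any(vd %% cfg$pool_factor^cfg$depth != 0))
    stop("patch dims must be divisible by pool_factor^depth", call. = FALSE)
  fw <- unet_forward(model$weights, cfg, matrix(as.vector(patch), ncol = 1), vd)
  array(fw$y, vd)
}

#' Save / load a trained restorer
#'
#' Single-file checkpoint (weights + config + normalization tag),
#' format-versioned.
#'
#' @param model a `trained_restorer`.
#' @param path file path.
#' @return `load_restorer` returns the `trained_restorer`.
#' @export
save_restorer <- function(model, path) {
  stopifnot(inherits(model, "trained_restorer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_restorer
#' @export
load_restorer <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_restorer") ||
      !identical(model$format_version, "tomorest-model-1"))
    stop("not a tomorest model checkpoint", call. = FALSE)
  model
}
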