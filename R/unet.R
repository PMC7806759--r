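#' 1D U-Net architecture configuration
#'
#' Hyperparameter bundle for the delineation network: an encoder/decoder
#' with skip connections, `levels` resolution levels with
#' `blocks_per_level` convolutional blocks each, channel width doubling
#' after every downsampling step (level `l` extracts `2^l * base_width`
#' channels), a stem convolution after the input, and a final 1x1
#' convolution with sigmoid emitting 3 wave-probability channels.
#'
#' @param block_type One of `"vanilla"`, `"residual"`, `"xception"` (the
#'   last uses depthwise-separable convolutions and a residual addition).
#' @param levels Network depth L; the sweep range used for model selection
#'   is 4--7 (other values are accepted with a warning).
#' @param blocks_per_level Convolutional blocks CB per level; sweep range
#'   2--6.
#' @param base_width Channels N extracted at the top level.
#' @param kernel_size Convolution kernel length (odd; default 3).
#' @param pool_size Pooling/upsampling factor (default 2).
#' @param spatial_dropout_p Channel dropout probability inside each block's
#'   regularizer.
#' @param use_batch_norm Include batch normalization in the regularizer.
#' @param in_channels Input leads per example (1 for single-lead, number of
#'   leads for multi-lead).
#' @param out_channels Output channels (3: P, QRS, T).
#' @param seed Seed for weight initialization.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(block_type = c("vanilla", "residual", "xception"),
                        levels = 4L, blocks_per_level = 2L, base_width = 8L,
                        kernel_size = 3L, pool_size = 2L,
                        spatial_dropout_p = 0, use_batch_norm = TRUE,
                        in_channels = 1L, out_channels = 3L, seed = 1234L) {
  block_type <- match.arg(block_type)
  levels <- as.integer(levels); blocks_per_level <- as.integer(blocks_per_level)
  if (levels < 1L || blocks_per_level < 1L)
    stop("levels and blocks_per_level must be positive")
  if (levels < 4L || levels > 7L || blocks_per_level < 2L ||
      blocks_per_level > 6L)
    warning("configuration outside the model-selection sweep ",
            "(L in 4..7, CB in 2..6)")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  if (pool_size < 2L) stop("pool_size must be >= 2")
  if (spatial_dropout_p < 0 || spatial_dropout_p >= 1)
    stop("spatial_dropout_p must lie in [0, 1)")
  structure(
    list(block_type = block_type, levels = levels,
         blocks_per_level = blocks_per_level,
         base_width = as.integer(base_width),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         spatial_dropout_p = spatial_dropout_p,
         use_batch_norm = use_batch_norm,
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels), seed = as.integer(seed)),
    class = "unet_config"
  )
}

level_width <- function(config, l) config$base_width * config$pool_size^l

## ---- blocks -------------------------------------------------------------

## One regularized convolutional half: x -> NL -> R(SDo, BN) -> C. For the
## xception block C is a depthwise-separable convolution (depthwise k-tap
## followed by a pointwise 1x1).
half_init <- function(cin, cout, cfg, separable) {
  p <- list()
  s <- list()
  if (cfg$use_batch_norm) {
    p$bn <- new_bn_params(cin)
    s$bn <- new_bn_state(cin)
  }
  if (separable) {
    p$dw <- new_dwconv_params(cfg$kernel_size, cin)
    p$pw <- new_conv_params(1L, cin, cout)
  } else {
    p$conv <- new_conv_params(cfg$kernel_size, cin, cout)
  }
  list(params = p, state = s)
}

half_fwd <- function(p, s, X, training, cfg, separable, B) {
  cache <- list()
  r <- nn_relu_fwd(X); cache$relu <- r$cache; X <- r$out
  d <- nn_sdrop_fwd(X, cfg$spatial_dropout_p, training, B)
  cache$sdrop <- d$cache; X <- d$out
  if (cfg$use_batch_norm) {
    b <- nn_bn_fwd(X, p$bn$gamma, p$bn$beta, training, s$bn)
    s$bn <- b$state; cache$bn <- b$cache; X <- b$out
  }
  if (separable) {
    dw <- nn_dwconv_fwd(X, p$dw$Wd, cfg$kernel_size, B)
    cache$dw <- dw$cache
    pw <- nn_conv_fwd(dw$out, p$pw$W, p$pw$b, 1L, B)
    cache$pw <- pw$cache; X <- pw$out
  } else {
    cv <- nn_conv_fwd(X, p$conv$W, p$conv$b, cfg$kernel_size, B)
    cache$conv <- cv$cache; X <- cv$out
  }
  list(out = X, state = s, cache = cache)
}

half_bwd <- function(p, cache, dY, cfg, separable) {
  g <- list()
  if (separable) {
    pw <- nn_conv_bwd(cache$pw, dY)
    g$pw <- list(W = pw$dW, b = pw$db)
    dw <- nn_dwconv_bwd(cache$dw, pw$dx)
    g$dw <- list(Wd = dw$dWd)
    dY <- dw$dx
  } else {
    cv <- nn_conv_bwd(cache$conv, dY)
    g$conv <- list(W = cv$dW, b = cv$db)
    dY <- cv$dx
  }
  if (cfg$use_batch_norm) {
    bn <- nn_bn_bwd(cache$bn, dY)
    g$bn <- list(gamma = bn$dgamma, beta = bn$dbeta)
    dY <- bn$dx
  }
  dY <- nn_sdrop_bwd(cache$sdrop, dY)$dx
  dY <- nn_relu_bwd(cache$relu, dY)$dx
  ## order gradients to mirror half_init's parameter ordering
  ordered <- list()
  if (cfg$use_batch_norm) ordered$bn <- g$bn
  if (separable) {
    ordered$dw <- g$dw; ordered$pw <- g$pw
  } else {
    ordered$conv <- g$conv
  }
  list(dx = dY, grads = ordered)
}

#' Instantiate one convolutional block
#'
#' Builds the parameter set of a single block of the requested type:
#' `vanilla` is two regularized convolutional halves
#' `C(R(N(C(R(N(x))))))`; `residual` adds the block input pointwise;
#' `xception` replaces the convolutions with depthwise-separable ones and
#' also adds the input. When input and output widths differ, residual and
#' xception blocks insert a 1x1 projection on the skip path.
#'
#' @param block_type `"vanilla"`, `"residual"` or `"xception"`.
#' @param cin,cout Input/output channel counts.
#' @param config A [unet_config()].
#' @return A list with `params` and `state` (batch-norm running moments).
#' @export
make_block <- function(block_type, cin, cout, config) {
  if (!block_type %in% c("vanilla", "residual", "xception"))
    stop("unknown block_type: ", block_type)
  if (cin <= 0 || cout <= 0) stop("channel counts must be positive")
  sep <- block_type == "xception"
  h1 <- half_init(cin, cout, config, sep)
  h2 <- half_init(cout, cout, config, sep)
  p <- list(type = block_type, h1 = h1$params, h2 = h2$params)
  s <- list(h1 = h1$state, h2 = h2$state)
  if (block_type != "vanilla" && cin != cout) {
    p$proj <- new_conv_params(1L, cin, cout)
  }
  list(params = p, state = s)
}

block_fwd <- function(p, s, X, training, cfg, B = 1L) {
  sep <- p$type == "xception"
  cache <- list()
  h1 <- half_fwd(p$h1, s$h1, X, training, cfg, sep, B)
  s$h1 <- h1$state; cache$h1 <- h1$cache
  h2 <- half_fwd(p$h2, s$h2, h1$out, training, cfg, sep, B)
  s$h2 <- h2$state; cache$h2 <- h2$cache
  out <- h2$out
  if (p$type != "vanilla") {
    if (!is.null(p$proj)) {
      pr <- nn_conv_fwd(X, p$proj$W, p$proj$b, 1L, B)
      cache$proj <- pr$cache
      out <- out + pr$out
    } else {
      out <- out + X
    }
  }
  list(out = out, state = s, cache = cache)
}

block_bwd <- function(p, cache, dY, cfg) {
  sep <- p$type == "xception"
  g <- list(type = NULL)
  h2 <- half_bwd(p$h2, cache$h2, dY, cfg, sep)
  h1 <- half_bwd(p$h1, cache$h1, h2$dx, cfg, sep)
  dX <- h1$dx
  g$h1 <- h1$grads; g$h2 <- h2$grads
  if (p$type != "vanilla") {
    if (!is.null(p$proj)) {
      pr <- nn_conv_bwd(cache$proj, dY)
      g$proj <- list(W = pr$dW, b = pr$db)
      dX <- dX + pr$dx
    } else {
      dX <- dX + dY
    }
  }
  list(dx = dX, grads = g)
}

## ---- full network -------------------------------------------------------

#' Build a 1D U-Net delineation model
#'
#' Instantiates the network with seeded He initialization: a stem
#' convolution to `base_width` channels, `levels` encoder levels of
#' `blocks_per_level` blocks with max-pool downsampling and width doubling,
#' a mirrored decoder with nearest-neighbour upsampling, width-halving
#' convolution and encoder-skip concatenation, and a final 1x1 convolution
#' with sigmoid to 3 channels. Output length equals input length (zero
#' padding keeps resolution), provided the input length is divisible by
#' `pool_size^(levels - 1)`.
#'
#' @param config A [unet_config()].
#' @return An untrained model of class `ecg_unet`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(config$seed)
  L <- config$levels; CB <- config$blocks_per_level
  params <- list(); state <- list()
  params$stem <- new_conv_params(config$kernel_size, config$in_channels,
                                 config$base_width)
  params$enc <- vector("list", L); state$enc <- vector("list", L)
  for (l in seq_len(L)) {
    w <- level_width(config, l - 1L)
    w_prev <- if (l == 1L) config$base_width else level_width(config, l - 2L)
    blocks_p <- vector("list", CB); blocks_s <- vector("list", CB)
    for (i in seq_len(CB)) {
      cin <- if (i == 1L) w_prev else w
      blk <- make_block(config$block_type, cin, w, config)
      blocks_p[[i]] <- blk$params; blocks_s[[i]] <- blk$state
    }
    params$enc[[l]] <- blocks_p; state$enc[[l]] <- blocks_s
  }
  n_dec <- L - 1L
  params$dec <- vector("list", n_dec); state$dec <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    l <- L - 1L - i           # 0-based target level
    w <- level_width(config, l)
    w_below <- level_width(config, l + 1L)
    upconv <- new_conv_params(config$pool_size, w_below, w)
    blocks_p <- vector("list", CB); blocks_s <- vector("list", CB)
    for (j in seq_len(CB)) {
      cin <- if (j == 1L) 2L * w else w
      blk <- make_block(config$block_type, cin, w, config)
      blocks_p[[j]] <- blk$params; blocks_s[[j]] <- blk$state
    }
    params$dec[[i]] <- list(upconv = upconv, blocks = blocks_p)
    state$dec[[i]] <- list(blocks = blocks_s)
  }
  params$head <- new_conv_params(1L, config$base_width, config$out_channels)
  ## start the output near a low wave-occupancy prior: avoids the early
  ## all-ones collapse of low-coverage channels under the Jaccard loss,
  ## where saturated sigmoids would stall the gradient
  params$head$b <- rep(log(0.1 / 0.9), config$out_channels)
  structure(
    list(config = config, params = params, state = state,
         trained = FALSE, history = NULL, control = NULL),
    class = "ecg_unet"
  )
}

check_input_length <- function(config, T) {
  need <- config$pool_size^(config$levels - 1L)
  if (T %% need != 0)
    stop("input length ", T, " is not divisible by pool_size^(levels-1) = ",
         need, "; level ", config$levels, " cannot be reached")
}

## Full forward pass on the row-blocked matrix layout. M: (T*B) x
## in_channels. Returns probabilities (T*B) x 3, updated state and caches.
unet_fwd_mat <- function(model, M, B, training = FALSE) {
  cfg <- model$config; p <- model$params; s <- model$state
  if (ncol(M) != cfg$in_channels)
    stop("input must have ", cfg$in_channels, " channel column(s)")
  check_input_length(cfg, nrow(M) %/% B)
  L <- cfg$levels; CB <- cfg$blocks_per_level
  cache <- list(B = B)
  st <- nn_conv_fwd(M, p$stem$W, p$stem$b, cfg$kernel_size, B)
  cache$stem <- st$cache
  x <- st$out
  enc_out <- vector("list", L)
  cache$pool <- vector("list", L)
  cache$enc <- vector("list", L)
  for (l in seq_len(L)) {
    if (l > 1L) {
      pl <- nn_maxpool_fwd(x, cfg$pool_size, B)
      cache$pool[[l]] <- pl$cache
      x <- pl$out
    }
    bc <- vector("list", CB)
    for (i in seq_len(CB)) {
      bf <- block_fwd(p$enc[[l]][[i]], s$enc[[l]][[i]], x, training, cfg, B)
      s$enc[[l]][[i]] <- bf$state; bc[[i]] <- bf$cache
      x <- bf$out
    }
    cache$enc[[l]] <- bc
    enc_out[[l]] <- x
  }
  n_dec <- L - 1L
  cache$dec <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    lev <- L - i                 # 1-based level of the skip source
    dc <- list()
    up <- nn_upsample_fwd(x, cfg$pool_size, B)
    dc$up <- up$cache
    uc <- nn_conv_fwd(up$out, p$dec[[i]]$upconv$W, p$dec[[i]]$upconv$b,
                      cfg$pool_size, B)
    dc$upconv <- uc$cache
    cc <- nn_concat_fwd(enc_out[[lev]], uc$out)
    dc$concat <- cc$cache
    x <- cc$out
    bc <- vector("list", CB)
    for (j in seq_len(CB)) {
      bf <- block_fwd(p$dec[[i]]$blocks[[j]], s$dec[[i]]$blocks[[j]], x,
                      training, cfg, B)
      s$dec[[i]]$blocks[[j]] <- bf$state; bc[[j]] <- bf$cache
      x <- bf$out
    }
    dc$blocks <- bc
    cache$dec[[i]] <- dc
  }
  hd <- nn_conv_fwd(x, p$head$W, p$head$b, 1L, B)
  cache$head <- hd$cache
  sg <- nn_sigmoid_fwd(hd$out)
  cache$sigmoid <- sg$cache
  list(out = sg$out, state = s, cache = cache)
}

## Array-facing wrapper. X: (T, in_channels, B); returns (T, 3, B).
unet_fwd <- function(model, X, training = FALSE) {
  d <- dim(X)
  if (length(d) != 3L || d[2] != model$config$in_channels)
    stop("input must be (time, ", model$config$in_channels,
         " channel(s), batch)")
  res <- unet_fwd_mat(model, tensor_to_mat(X), d[3], training)
  res$out <- mat_to_tensor(res$out, d[1], model$config$out_channels, d[3])
  res
}

## Full backward pass from dL/d(probabilities). dOut may be a (T, 3, B)
## array or the matching row-blocked matrix. Returns gradients shaped
## exactly like model$params.
unet_bwd <- function(model, cache, dOut) {
  cfg <- model$config; p <- model$params
  if (length(dim(dOut)) == 3L) dOut <- tensor_to_mat(dOut)
  L <- cfg$levels; CB <- cfg$blocks_per_level
  g <- list()
  dY <- nn_sigmoid_bwd(cache$sigmoid, dOut)$dx
  hd <- nn_conv_bwd(cache$head, dY)
  g$head <- list(W = hd$dW, b = hd$db)
  dY <- hd$dx
  n_dec <- L - 1L
  g$dec <- vector("list", n_dec)
  dskip <- vector("list", L)
  for (i in rev(seq_len(n_dec))) {
    lev <- L - i
    dc <- cache$dec[[i]]
    blocks_g <- vector("list", CB)
    for (j in rev(seq_len(CB))) {
      bb <- block_bwd(p$dec[[i]]$blocks[[j]], dc$blocks[[j]], dY, cfg)
      blocks_g[[j]] <- bb$grads
      dY <- bb$dx
    }
    sp <- nn_concat_bwd(dc$concat, dY)
    dskip[[lev]] <- sp$dA
    uc <- nn_conv_bwd(dc$upconv, sp$dB)
    g$dec[[i]] <- list(upconv = list(W = uc$dW, b = uc$db),
                       blocks = blocks_g)
    dY <- nn_upsample_bwd(dc$up, uc$dx)$dx
  }
  g$enc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) dY <- dY + dskip[[l]]
    blocks_g <- vector("list", CB)
    for (i in rev(seq_len(CB))) {
      bb <- block_bwd(p$enc[[l]][[i]], cache$enc[[l]][[i]], dY, cfg)
      blocks_g[[i]] <- bb$grads
      dY <- bb$dx
    }
    g$enc[[l]] <- blocks_g
    if (l > 1L) dY <- nn_maxpool_bwd(cache$pool[[l]], dY)$dx
  }
  st <- nn_conv_bwd(cache$stem, dY)
  g$stem <- list(W = st$dW, b = st$db)
  ## order must mirror model$params for flattening
  g[c("stem", "enc", "dec", "head")]
}

## ---- summaries and prediction ------------------------------------------

#' Summarize a U-Net architecture
#'
#' @param config A [unet_config()] or an `ecg_unet` model.
#' @param input_length Window length used to tabulate per-level tensor
#'   sizes.
#' @return A list with a per-level table (`levels`) and the total
#'   `n_params`.
#' @export
model_summary <- function(config, input_length = 512L) {
  if (inherits(config, "ecg_unet")) {
    model <- config; config <- model$config
  } else {
    model <- build_unet(config)
  }
  L <- config$levels
  lens <- input_length / config$pool_size^(0:(L - 1L))
  tab <- data.frame(level = 0:(L - 1L),
                    length = lens,
                    channels = level_width(config, 0:(L - 1L)))
  list(levels = tab, n_params = count_params(model$params),
       config = config)
}

count_params <- function(params) length(flatten_params(params))

numeric_params <- function(params) {
  strip <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, logical(1))]
    if (!is.null(names(x))) x <- x[names(x) != "type"]
    lapply(x, strip)
  }
  strip(params)
}

flatten_params <- function(params) unlist(numeric_params(params),
                                          use.names = FALSE)

## Write a flat numeric vector back into the params structure (in the same
## depth-first order used by flatten_params).
unflatten_params <- function(params, flat) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        if (!is.null(names(x)) && identical(names(x)[nm], "type")) next
        if (is.null(x[[nm]])) next
        x[[nm]] <- fill(x[[nm]])
      }
      return(x)
    }
    k <- length(x)
    vals <- flat[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(x)) matrix(vals, nrow(x), ncol(x)) else vals
  }
  out <- fill(params)
  if (pos != length(flat)) stop("parameter vector length mismatch")
  out
}

#' Predict wave probability masks for a record
#'
#' Runs the network in inference mode over a record, tiling it into
#' overlapping windows and averaging probabilities on the overlaps.
#' Records shorter than one window are zero-padded and the output cropped.
#'
#' @param object A (trained) `ecg_unet` model.
#' @param record An [ecg_record()], or a bare numeric matrix
#'   (samples x leads) with `fs` supplied.
#' @param strategy `"single_lead"` (one mask per lead, each lead fed
#'   independently) or `"multi_lead"` (all leads stacked as input channels,
#'   one mask).
#' @param window Window length in samples (divisible by
#'   `pool_size^(levels-1)`).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @param fs Sampling frequency when `record` is a bare matrix.
#' @param ... Unused.
#' @return For `"multi_lead"`, a probabilistic [seg_mask()]; for
#'   `"single_lead"`, a named list of masks, one per lead.
#' @export
predict.ecg_unet <- function(object, record,
                             strategy = c("single_lead", "multi_lead"),
                             window = 512L, overlap = 0.5, fs = NULL, ...) {
  strategy <- match.arg(strategy)
  if (inherits(record, "ecg_record")) {
    sig <- record$signal; fs <- record$fs
  } else {
    sig <- as.matrix(record)
    if (is.null(fs)) stop("fs required for a bare signal matrix")
  }
  ## same per-lead z-normalization as applied during training
  sig <- normalize_lead_matrix(sig)
  check_input_length(object$config, window)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (strategy == "multi_lead") {
    if (ncol(sig) != object$config$in_channels)
      stop("model expects ", object$config$in_channels,
           " input channels, record has ", ncol(sig), " leads")
    return(predict_tiled(object, sig, window, overlap, fs))
  }
  if (object$config$in_channels != 1L)
    stop("single_lead prediction requires a 1-channel model")
  masks <- lapply(seq_len(ncol(sig)), function(l)
    predict_tiled(object, sig[, l, drop = FALSE], window, overlap, fs))
  names(masks) <- colnames(sig)
  masks
}

predict_tiled <- function(model, sig, window, overlap, fs) {
  n <- nrow(sig)
  pad <- 0L
  if (n < window) {
    pad <- window - n
    sig <- rbind(sig, matrix(0, pad, ncol(sig)))
    message("record shorter than window; padded by ", pad, " samples")
    n <- nrow(sig)
  }
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, max(n - window + 1L, 1L), by = stride)
  if (starts[length(starts)] + window - 1L < n)
    starts <- c(starts, n - window + 1L)
  acc <- matrix(0, n, model$config$out_channels)
  cov <- rep(0, n)
  for (s0 in starts) {
    idx <- s0:(s0 + window - 1L)
    pr <- unet_fwd_mat(model, sig[idx, , drop = FALSE], 1L,
                       training = FALSE)$out
    acc[idx, ] <- acc[idx, ] + pr
    cov[idx] <- cov[idx] + 1
  }
  prob <- acc / cov
  if (pad > 0L) prob <- prob[seq_len(nrow(prob) - pad), , drop = FALSE]
  seg_mask(prob, fs)
}

#' @export
print.ecg_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ecg_unet> %s blocks, L=%d, CB=%d, N=%d (%s)\n",
              cfg$block_type, cfg$levels, cfg$blocks_per_level,
              cfg$base_width,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  kernel=%d pool=%d SDo=%.2f BN=%s in=%d out=%d\n",
              cfg$kernel_size, cfg$pool_size, cfg$spatial_dropout_p,
              cfg$use_batch_norm, cfg$in_channels, cfg$out_channels))
  cat(sprintf("  parameters: %d\n", count_params(x$params)))
  if (!is.null(x$history))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                utils::tail(x$history$loss, 1), nrow(x$history)))
  invisible(x)
}

#' @export
summary.ecg_unet <- function(object, input_length = 512L, ...) {
  ms <- model_summary(object, input_length)
  print(object)
  cat("  per-level tensor schedule (window ", input_length, "):\n", sep = "")
  print(ms$levels, row.names = FALSE)
  invisible(ms)
}

#' @export
coef.ecg_unet <- function(object, ...) flatten_params(object$params)

#' @export
plot.ecg_unet <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history to plot")
  }
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training Jaccard loss",
                 main = "ecg_unet training history", ...)
  invisible(x)
}
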