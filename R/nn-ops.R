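## Primitive differentiable operations for the 1D U-Net. Activations are
## stored as (T*B) x C matrices: batch element b occupies the contiguous
## row block (b-1)*T + 1 .. b*T, channels are columns. This keeps every
## operation a plain matrix op (BLAS products, column means) with no array
## permutations in the hot path. Each forward returns list(out, cache);
## each backward consumes (cache, dY) and returns list(dx, <grads>).

## (T, C, B) array <-> row-blocked matrix
tensor_to_mat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(1, 3, 2)), d[1] * d[3], d[2])
}

mat_to_tensor <- function(M, T, C, B) {
  aperm(array(M, c(T, B, C)), c(1, 3, 2))
}

## Row shift within each batch block: output row t (of block b) takes input
## row t + o of the same block, zero where t + o falls outside the block.
shift_rows <- function(M, o, B) {
  if (o == 0) return(M)
  N <- nrow(M); T <- N %/% B
  Y <- matrix(0, N, ncol(M))
  if (o > 0) {
    Y[1:(N - o), ] <- M[(o + 1):N, ]
    bad <- as.vector(outer((T - o + 1L):T, (0:(B - 1L)) * T, "+"))
  } else {
    oo <- -o
    Y[(oo + 1):N, ] <- M[1:(N - oo), ]
    bad <- as.vector(outer(1:oo, (0:(B - 1L)) * T, "+"))
  }
  Y[bad, ] <- 0
  Y
}

conv_offsets <- function(k) (1:k) - (floor((k - 1) / 2) + 1L)

col_bcast <- function(v, N) rep(v, each = N)

nn_conv_fwd <- function(M, W, b, k, B) {
  N <- nrow(M); Cin <- ncol(M)
  offs <- conv_offsets(k)
  if (k == 1L) {
    Xcol <- M
  } else {
    Xcol <- matrix(0, N, k * Cin)
    for (j in seq_len(k)) {
      Xcol[, ((j - 1) * Cin + 1):(j * Cin)] <- shift_rows(M, offs[j], B)
    }
  }
  Y <- Xcol %*% W + col_bcast(b, N)
  list(out = Y, cache = list(Xcol = Xcol, W = W, k = k, Cin = Cin, B = B))
}

nn_conv_bwd <- function(cache, dY) {
  k <- cache$k; Cin <- cache$Cin; B <- cache$B
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(cache$W)
  if (k == 1L) {
    dX <- dXcol
  } else {
    offs <- conv_offsets(k)
    dX <- matrix(0, nrow(dY), Cin)
    for (j in seq_len(k)) {
      dX <- dX + shift_rows(
        dXcol[, ((j - 1) * Cin + 1):(j * Cin), drop = FALSE], -offs[j], B)
    }
  }
  list(dx = dX, dW = dW, db = db)
}

## Depthwise k-tap convolution: one filter per input channel.
nn_dwconv_fwd <- function(M, Wd, k, B) {
  N <- nrow(M); C <- ncol(M)
  offs <- conv_offsets(k)
  Y <- matrix(0, N, C)
  shifts <- vector("list", k)
  for (j in seq_len(k)) {
    Ms <- shift_rows(M, offs[j], B)
    shifts[[j]] <- Ms
    Y <- Y + Ms * col_bcast(Wd[j, ], N)
  }
  list(out = Y, cache = list(shifts = shifts, Wd = Wd, k = k, B = B))
}

nn_dwconv_bwd <- function(cache, dY) {
  k <- cache$k; B <- cache$B
  N <- nrow(dY); C <- ncol(dY)
  offs <- conv_offsets(k)
  dWd <- matrix(0, k, C)
  dX <- matrix(0, N, C)
  for (j in seq_len(k)) {
    dWd[j, ] <- colSums(cache$shifts[[j]] * dY)
    dX <- dX + shift_rows(dY * col_bcast(cache$Wd[j, ], N), -offs[j], B)
  }
  list(dx = dX, dWd = dWd)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## Batch normalization per channel over (time, batch).
nn_bn_fwd <- function(M, gamma, beta, training, state) {
  N <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv_sd <- 1 / sqrt(va + BN_EPS)
  xhat <- (M - col_bcast(mu, N)) * col_bcast(inv_sd, N)
  out <- xhat * col_bcast(gamma, N) + col_bcast(beta, N)
  list(out = out, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    training = training))
}

nn_bn_bwd <- function(cache, dY) {
  N <- nrow(dY)
  xhat <- cache$xhat
  dYx <- dY * xhat
  dgamma <- colSums(dYx)
  dbeta <- colSums(dY)
  scale <- col_bcast(cache$gamma * cache$inv_sd, N)
  if (cache$training) {
    dX <- scale * (dY - col_bcast(dbeta / N, N) -
                     xhat * col_bcast(dgamma / N, N))
  } else {
    dX <- scale * dY
  }
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(M) {
  mask <- M > 0
  list(out = M * mask, cache = mask)
}

nn_relu_bwd <- function(cache, dY) list(dx = dY * cache)

nn_sigmoid_fwd <- function(M) {
  out <- 1 / (1 + exp(-M))
  list(out = out, cache = out)
}

nn_sigmoid_bwd <- function(cache, dY) list(dx = dY * cache * (1 - cache))

#' Spatial (channel-wise) dropout
#'
#' During training each feature channel of each batch element is zeroed
#' independently with probability `p` across its entire temporal extent,
#' and surviving channels are rescaled by `1/(1-p)`; at inference the
#' input passes through unchanged.
#'
#' @param X A (time, channels, batch) array (a matrix is treated as one
#'   batch element).
#' @param p Drop probability in `[0, 1)`.
#' @param training Apply dropout (TRUE) or the identity (FALSE).
#' @return An array of the same shape.
#' @export
spatial_dropout <- function(X, p, training = TRUE) {
  was_mat <- is.matrix(X)
  if (was_mat) X <- array(X, c(dim(X), 1L))
  d <- dim(X)
  M <- tensor_to_mat(X)
  out <- nn_sdrop_fwd(M, p, training, B = d[3])$out
  out <- mat_to_tensor(out, d[1], d[2], d[3])
  if (was_mat) out <- out[, , 1]
  out
}

nn_sdrop_fwd <- function(M, p, training, B) {
  if (p < 0 || p >= 1) stop("dropout probability must lie in [0, 1)")
  if (!training || p == 0) return(list(out = M, cache = NULL))
  N <- nrow(M); C <- ncol(M); T <- N %/% B
  keep <- matrix(stats::runif(C * B) >= p, C, B) / (1 - p)
  ## expand to rows: block b rows get keep[, b]
  mask <- matrix(t(keep)[rep(seq_len(B), each = T), ], N, C)
  list(out = M * mask, cache = mask)
}

nn_sdrop_bwd <- function(cache, dY) {
  if (is.null(cache)) return(list(dx = dY))
  list(dx = dY * cache)
}

## Row indices of the s-th phase of a `size`-fold downsampling, per block.
pool_phase_idx <- function(T, B, size, s) {
  as.vector(outer(seq(s, T, by = size), (0:(B - 1L)) * T, "+"))
}

## Max pooling over non-overlapping windows of `size` along time.
nn_maxpool_fwd <- function(M, size, B) {
  N <- nrow(M); T <- N %/% B
  if (T %% size != 0)
    stop("input length ", T, " not divisible by pool size ", size)
  phases <- lapply(seq_len(size), function(s)
    pool_phase_idx(T, B, size, s))
  out <- M[phases[[1]], , drop = FALSE]
  argmax <- matrix(1L, nrow(out), ncol(out))
  for (s in 2:size) {
    cand <- M[phases[[s]], , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    argmax[better] <- s
  }
  list(out = out, cache = list(argmax = argmax, size = size, T = T, B = B,
                               phases = phases))
}

nn_maxpool_bwd <- function(cache, dY) {
  dX <- matrix(0, cache$T * cache$B, ncol(dY))
  for (s in seq_len(cache$size)) {
    Ds <- dY
    Ds[cache$argmax != s] <- 0
    dX[cache$phases[[s]], ] <- Ds
  }
  list(dx = dX)
}

## Nearest-neighbour upsampling by an integer factor along time.
nn_upsample_fwd <- function(M, size, B) {
  N <- nrow(M); T <- N %/% B
  ## output row (b, t_out) takes input row (b, ceil(t_out / size))
  idx <- as.vector(outer(rep(seq_len(T), each = size),
                         (0:(B - 1L)) * T, "+"))
  list(out = M[idx, , drop = FALSE],
       cache = list(size = size, T = T, B = B))
}

nn_upsample_bwd <- function(cache, dY) {
  T <- cache$T; B <- cache$B; size <- cache$size
  To <- T * size
  dX <- matrix(0, T * B, ncol(dY))
  for (s in seq_len(size)) {
    idx <- as.vector(outer(seq(s, To, by = size), (0:(B - 1L)) * To, "+"))
    dX <- dX + dY[idx, , drop = FALSE]
  }
  list(dx = dX)
}

nn_concat_fwd <- function(A, Bm) {
  list(out = cbind(A, Bm), cache = c(ncol(A), ncol(Bm)))
}

nn_concat_bwd <- function(cache, dY) {
  ca <- cache[1]; cb <- cache[2]
  list(dA = dY[, seq_len(ca), drop = FALSE],
       dB = dY[, ca + seq_len(cb), drop = FALSE])
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

new_conv_params <- function(k, cin, cout) {
  list(W = he_init(k * cin, cout, k * cin), b = rep(0, cout))
}

new_dwconv_params <- function(k, c) {
  list(Wd = matrix(stats::rnorm(k * c, 0, sqrt(2 / k)), k, c))
}

new_bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

new_bn_state <- function(c) list(mean = rep(0, c), var = rep(1, c))
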