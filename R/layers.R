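# Internal layer primitives. Tensors are R arrays dim (H, W, C, N); the
# channel axis is third so per-channel statistics reduce via two cheap
# reshapes instead of an aperm.

same_ceil_pad <- function(inside, k, stride) {
  out <- ceiling(inside / stride)
  total <- max((out - 1L) * stride + k - inside, 0L)
  total %/% 2L # TF-style SAME: smaller pad before, larger after
}

conv_fwd <- function(x, w, kh, kw, stride, bias = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  pt <- same_ceil_pad(H, kh, stride); pl <- same_ceil_pad(W, kw, stride)
  Hout <- ceiling(H / stride); Wout <- ceiling(W / stride)
  Nk <- ncol(w)
  if (kh == 1L && kw == 1L && stride == 1L) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
    y <- xm %*% w
    cols <- xm
  } else {
    cols <- .cpp_im2col(x, H, W, C, N, kh, kw, stride, pt, pl)
    y <- cols %*% w
  }
  if (!is.null(bias)) y <- sweep(y, 2, bias, "+")
  dim(y) <- c(Hout, Wout, N, Nk)
  list(y = aperm(y, c(1, 2, 4, 3)), cols = cols,
       geom = c(H, W, C, N, kh, kw, stride, pt, pl, Hout, Wout))
}

conv_bwd <- function(cache, w, gy) {
  g <- cache$geom
  H <- g[1]; W <- g[2]; C <- g[3]; N <- g[4]; kh <- g[5]; kw <- g[6]
  stride <- g[7]; pt <- g[8]; pl <- g[9]; Hout <- g[10]; Wout <- g[11]
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = dim(gy)[3])
  gw <- crossprod(cache$cols, gym)
  gbias <- .colSums(gym, nrow(gym), ncol(gym))
  gcols <- gym %*% t(w)
  if (kh == 1L && kw == 1L && stride == 1L) {
    dim(gcols) <- c(H, W, N, C)
    gx <- aperm(gcols, c(1, 2, 4, 3))
  } else {
    gx <- .cpp_col2im(gcols, H, W, C, N, kh, kw, stride, pt, pl)
  }
  list(gx = gx, gw = gw, gbias = gbias)
}

dwconv_fwd <- function(x, w, stride) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]
  pt <- same_ceil_pad(d[1], kh, stride); pl <- same_ceil_pad(d[2], kw, stride)
  y <- .cpp_dwconv_fwd(x, d[1], d[2], d[3], d[4], w, kh, kw, stride, pt, pl)
  list(y = y, x = x, geom = c(d, kh, kw, stride, pt, pl))
}

dwconv_bwd <- function(cache, w, gy) {
  g <- cache$geom
  .cpp_dwconv_bwd(cache$x, g[1], g[2], g[3], g[4], w, g[5], g[6], g[7],
                  g[8], g[9], gy)
}

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rmean = rep(0, channels), rvar = rep(1, channels))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

act_code <- function(kind) switch(kind, linear = 0L, relu = 1L, relu6 = 2L)

# Fused (optional batch-norm) + activation forward: y = act(z * a[c] + b[c]).
# With bn = NULL the affine is the identity, only the activation applies.
norm_act_fwd <- function(z, bn, act, training = FALSE) {
  d <- dim(z); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (!is.null(bn)) {
    if (training) {
      st <- .cpp_channel_stats(z, HW, C, N)
      mu <- st$mean; v <- st$var
      bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
      bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * v
    } else {
      mu <- bn$rmean; v <- bn$rvar
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    a <- bn$gamma * invstd
    b <- bn$beta - mu * a
  } else {
    mu <- invstd <- NULL
    a <- rep(1, C); b <- rep(0, C)
  }
  y <- .cpp_bnact_fwd(z, HW, C, N, a, b, act_code(act))
  list(y = y, z = z, mu = mu, invstd = invstd, a = a, b = b, bn = bn)
}

# Backward through activation then (optional) batch norm. Returns the
# gradient at the convolution output plus BN parameter gradients.
norm_act_bwd <- function(cache, bn, act, gy, training = TRUE) {
  d <- dim(cache$z); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gz <- .cpp_bnact_bwd(cache$z, HW, C, N, cache$a, cache$b, gy,
                       act_code(act))
  if (is.null(bn))
    return(list(gx = gz, ggamma = NULL, gbeta = NULL))
  r <- .cpp_bn_bwd(cache$z, HW, C, N, cache$mu, cache$invstd, bn$gamma, gz,
                   training)
  list(gx = r$gx, ggamma = r$ggamma, gbeta = r$gbeta)
}
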