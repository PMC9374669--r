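#' Build a trainable detection network from a specification
#'
#' Allocates weights for every layer of `spec` with seeded truncated-normal
#' initialization (sd 0.03, clipped at 2 sd), batch-norm scale 1 / shift 0,
#' running statistics mean 0 / variance 1. Convolutions carry no bias (batch
#' norm follows each one); a layer without batch norm — the final grid conv —
#' carries a bias initialized to zero.
#'
#' @param spec a [network_spec()].
#' @param rng_seed integer seed; the same seed always yields identical
#'   initial weights. The caller's RNG state is left untouched.
#' @return an object of class `wce_network`.
#' @export
build_network <- function(spec, rng_seed = 1L) {
  validate_network_spec(spec)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(rng_seed)
  n_layers <- length(spec$layers)
  layers <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    ls <- spec$layers[[k]]
    act <- if (k == n_layers) "linear" else spec$activation
    if (ls$kind == "standard_conv") {
      kh <- ls$conv_kernel[1]; kw <- ls$conv_kernel[2]
      cin <- ls$conv_kernel[3]; cout <- ls$conv_kernel[4]
      layers[[k]] <- list(
        type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
        stride = ls$stride,
        w = matrix(trunc_normal(kh * kw * cin * cout), ncol = cout),
        bias = if (!ls$followed_by_bn) rep(0, cout),
        bn = if (ls$followed_by_bn) bn_init(cout),
        act = act)
    } else {
      kh <- ls$depthwise_kernel[1]; kw <- ls$depthwise_kernel[2]
      cin <- ls$depthwise_kernel[3]; cout <- ls$pointwise_out
      layers[[k]] <- list(
        type = "dwsep", kh = kh, kw = kw, cin = cin, cout = cout,
        stride = ls$stride,
        dw = array(trunc_normal(kh * kw * cin), dim = c(kh, kw, cin)),
        bn1 = if (ls$followed_by_bn) bn_init(cin),
        pw = matrix(trunc_normal(cin * cout), ncol = cout),
        bn2 = if (ls$followed_by_bn) bn_init(cout),
        act = act)
    }
  }
  structure(list(spec = spec, spec_hash = spec_hash(spec), layers = layers,
                 version = "initial"),
            class = "wce_network")
}

trunc_normal <- function(n, sd = 0.03, clip = 2) {
  lo <- stats::pnorm(-clip); hi <- stats::pnorm(clip)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

#' Run the detector on one frame
#'
#' @param network a `wce_network`.
#' @param image numeric array (H, W, 3) with values in \[0, 1\], H and W
#'   matching the spec's input shape (240 x 240 for the canonical net).
#' @return the output feature map, e.g. a (4, 4, 15) array of raw grid
#'   activations for the canonical net: per cell, 3 anchors x (score, x, y,
#'   w, h) logits. Decode with [decode_grid()].
#' @export
forward <- function(network, image) {
  stopifnot(inherits(network, "wce_network"))
  d <- dim(image)
  want <- network$spec$input_shape
  if (length(d) != 3 || d[1] != want[2] || d[2] != want[1] || d[3] != want[3])
    stop("input shape ", paste(d, collapse = "x"), " does not match spec ",
         paste(want, collapse = "x"))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must lie in [0, 1]")
  dim(image) <- c(d, 1L)
  out <- net_forward_batch(network, image, training = FALSE)$out
  array(out, dim = dim(out)[1:3])
}

# Batched forward over x (H, W, C, N). With keep_cache = TRUE, returns the
# per-layer intermediates needed for backpropagation; with training = TRUE,
# batch statistics are used for BN (and running stats updated in the
# returned network).
net_forward_batch <- function(network, x, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(network$layers))
  for (k in seq_along(network$layers)) {
    l <- network$layers[[k]]
    if (l$type == "conv") {
      cv <- conv_fwd(x, l$w, l$kh, l$kw, l$stride, l$bias)
      na <- norm_act_fwd(cv$y, l$bn, l$act, training)
      if (training && !is.null(l$bn))
        network$layers[[k]]$bn[c("rmean", "rvar")] <- na$bn[c("rmean", "rvar")]
      y <- na$y
      if (keep_cache)
        caches[[k]] <- list(conv = cv[c("cols", "geom")],
                            na = na[c("z", "mu", "invstd", "a", "b")])
    } else {
      dv <- dwconv_fwd(x, l$dw, l$stride)
      na1 <- norm_act_fwd(dv$y, l$bn1, l$act, training)
      if (training && !is.null(l$bn1))
        network$layers[[k]]$bn1[c("rmean", "rvar")] <-
          na1$bn[c("rmean", "rvar")]
      pv <- conv_fwd(na1$y, l$pw, 1L, 1L, 1L)
      na2 <- norm_act_fwd(pv$y, l$bn2, l$act, training)
      if (training && !is.null(l$bn2))
        network$layers[[k]]$bn2[c("rmean", "rvar")] <-
          na2$bn[c("rmean", "rvar")]
      y <- na2$y
      if (keep_cache)
        caches[[k]] <- list(dw = dv[c("x", "geom")],
                            na1 = na1[c("z", "mu", "invstd", "a", "b")],
                            pw = pv[c("cols", "geom")],
                            na2 = na2[c("z", "mu", "invstd", "a", "b")])
    }
    x <- y
  }
  list(out = x, caches = caches, network = network)
}

# Backprop `gout` (gradient at the network output) through cached layers.
# Returns per-layer gradients mirroring the parameter structure.
net_backward <- function(network, caches, gout, training = TRUE) {
  n <- length(network$layers)
  grads <- vector("list", n)
  g <- gout
  for (k in rev(seq_len(n))) {
    l <- network$layers[[k]]
    cc <- caches[[k]]
    if (l$type == "conv") {
      nb <- norm_act_bwd(cc$na, l$bn, l$act, g, training)
      gr <- list(gamma = nb$ggamma, beta = nb$gbeta)
      cb <- conv_bwd(cc$conv, l$w, nb$gx)
      gr$w <- cb$gw
      if (!is.null(l$bias)) gr$bias <- cb$gbias
      grads[[k]] <- gr
      g <- cb$gx
    } else {
      nb2 <- norm_act_bwd(cc$na2, l$bn2, l$act, g, training)
      gr <- list(gamma2 = nb2$ggamma, beta2 = nb2$gbeta)
      pb <- conv_bwd(cc$pw, l$pw, nb2$gx)
      gr$pw <- pb$gw
      nb1 <- norm_act_bwd(cc$na1, l$bn1, l$act, pb$gx, training)
      gr$gamma1 <- nb1$ggamma; gr$beta1 <- nb1$gbeta
      db <- dwconv_bwd(cc$dw, l$dw, nb1$gx)
      gr$dw <- db$gw
      grads[[k]] <- gr
      g <- db$gx
    }
  }
  grads
}

#' Count trainable parameters
#'
#' @param network a `wce_network`.
#' @param include_bn count batch-norm scale and shift (2 per normalized
#'   channel)? Running statistics are never counted.
#' @return integer scalar. The canonical 240-px network has 3,222,351
#'   parameters with BN (3,200,463 without); both round to 3.2M.
#' @export
count_parameters <- function(network, include_bn = TRUE) {
  tot <- 0
  for (l in network$layers) {
    if (l$type == "conv") {
      tot <- tot + length(l$w) + length(l$bias)
      if (include_bn && !is.null(l$bn)) tot <- tot + 2 * l$cout
    } else {
      tot <- tot + length(l$dw) + length(l$pw)
      if (include_bn) {
        if (!is.null(l$bn1)) tot <- tot + 2 * l$cin
        if (!is.null(l$bn2)) tot <- tot + 2 * l$cout
      }
    }
  }
  as.integer(tot)
}

#' INT8 deployment footprint in bytes
#'
#' One byte per trainable parameter (batch norm included), the storage model
#' of the INT8-quantized onboard deployment. No quantized inference is
#' simulated; this is accounting only.
#'
#' @param network a `wce_network`.
#' @return bytes (numeric scalar).
#' @export
int8_footprint <- function(network) {
  as.numeric(count_parameters(network, include_bn = TRUE))
}

#' Save / load network weights
#'
#' Single-file checkpoint embedding the spec and its hash; loading checks the
#' hash against `expect_spec` (or the embedded spec of `onto`) and errors on
#' mismatch, so weights can never be applied to an incompatible architecture.
#'
#' @param network a `wce_network`.
#' @param path checkpoint file path.
#' @param expect_spec optional `wce_network_spec` the checkpoint must match.
#' @return `load_checkpoint` returns the restored `wce_network`.
#' @export
save_checkpoint <- function(network, path) {
  saveRDS(list(format = "wcepolyp-checkpoint-1", spec_hash = network$spec_hash,
               spec = network$spec, layers = network$layers,
               version = network$version), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expect_spec = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "wcepolyp-checkpoint-1"))
    stop("not a wcepolyp checkpoint: ", path)
  if (!is.null(expect_spec) && !identical(spec_hash(expect_spec), obj$spec_hash))
    stop("checkpoint spec hash ", obj$spec_hash,
         " does not match the expected spec ", spec_hash(expect_spec))
  structure(list(spec = obj$spec, spec_hash = obj$spec_hash,
                 layers = obj$layers, version = obj$version),
            class = "wce_network")
}

#' @export
print.wce_network <- function(x, ...) {
  cat("<wce_network> ", length(x$layers), " layers, ",
      format(count_parameters(x), big.mark = ","), " parameters (",
      sprintf("%.1f", count_parameters(x) / 1e6), "M), INT8 ",
      sprintf("%.1f", int8_footprint(x) / 1e6), " MB, version ",
      x$version, "\n", sep = "")
  invisible(x)
}
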