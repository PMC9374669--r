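#' Layer specification for the onboard detector
#'
#' A layer is either a standard convolution (`kind = "standard_conv"`, kernel
#' \eqn{w_k \times h_k \times c_k \times n_k}) or a depthwise-separable pair
#' (`kind = "depthwise_separable"`: a per-channel \eqn{w_k \times h_k} spatial
#' filter followed by a 1x1 pointwise channel mix). The stride (1 or 2)
#' applies to the spatial step; the pointwise step always has stride 1.
#'
#' @param index layer position, 1-based.
#' @param kind `"standard_conv"` or `"depthwise_separable"`.
#' @param conv_kernel integer c(kh, kw, c_in, n_out) for a standard conv.
#' @param depthwise_kernel integer c(kh, kw, c_in) for the depthwise step.
#' @param pointwise_out integer, output channels of the pointwise step.
#' @param stride 1 or 2.
#' @param followed_by_bn logical; whether batch norm follows the layer's
#'   convolution step(s). The final layer of the canonical net has no BN and
#'   carries a bias instead.
#' @return an object of class `wce_layer_spec`.
#' @export
layer_spec <- function(index, kind,
                       conv_kernel = NULL, depthwise_kernel = NULL,
                       pointwise_out = NULL, stride = 1L,
                       followed_by_bn = TRUE) {
  kind <- match.arg(kind, c("standard_conv", "depthwise_separable"))
  if (!stride %in% c(1L, 2L))
    stop("layer ", index, ": stride must be 1 or 2, got ", stride)
  if (kind == "standard_conv") {
    if (is.null(conv_kernel) || !is.null(depthwise_kernel) || !is.null(pointwise_out))
      stop("layer ", index, ": standard_conv requires conv_kernel only")
    stopifnot(length(conv_kernel) == 4, all(conv_kernel >= 1))
  } else {
    if (is.null(depthwise_kernel) || is.null(pointwise_out) || !is.null(conv_kernel))
      stop("layer ", index,
           ": depthwise_separable requires depthwise_kernel + pointwise_out")
    stopifnot(length(depthwise_kernel) == 3, all(depthwise_kernel >= 1),
              pointwise_out >= 1)
  }
  structure(list(index = as.integer(index), kind = kind,
                 conv_kernel = if (!is.null(conv_kernel)) as.integer(conv_kernel),
                 depthwise_kernel = if (!is.null(depthwise_kernel)) as.integer(depthwise_kernel),
                 pointwise_out = if (!is.null(pointwise_out)) as.integer(pointwise_out),
                 stride = as.integer(stride),
                 followed_by_bn = isTRUE(followed_by_bn)),
            class = "wce_layer_spec")
}

layer_out_channels <- function(layer) {
  if (layer$kind == "standard_conv") layer$conv_kernel[4] else layer$pointwise_out
}

layer_in_channels <- function(layer) {
  if (layer$kind == "standard_conv") layer$conv_kernel[3] else layer$depthwise_kernel[3]
}

#' Network specification
#'
#' An ordered list of [layer_spec()]s plus the input geometry, activation and
#' padding convention. Validation checks the channel chain (each layer's
#' kernel input channels must equal the previous layer's output channels) and
#' that all inferred spatial sizes are positive.
#'
#' @param layers list of `wce_layer_spec`.
#' @param input_shape integer c(width, height, channels); the capsule camera
#'   delivers 240 x 240 x 3.
#' @param activation activation between layers; `"relu6"` (default, the
#'   INT8-friendly clipped ReLU) or `"relu"` or `"linear"`. The final layer is
#'   always linear (its outputs are raw box/score logits).
#' @param padding_mode only `"same_ceil"` is supported: SAME padding with
#'   ceiling division, so spatial size maps in -> ceil(in / stride)
#'   (e.g. 15 -> 8 at stride 2).
#' @return an object of class `wce_network_spec`.
#' @export
network_spec <- function(layers, input_shape = c(240L, 240L, 3L),
                         activation = "relu6", padding_mode = "same_ceil") {
  activation <- match.arg(activation, c("relu6", "relu", "linear"))
  padding_mode <- match.arg(padding_mode, "same_ceil")
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  spec <- structure(list(layers = layers,
                         input_shape = as.integer(input_shape),
                         activation = activation,
                         padding_mode = padding_mode),
                    class = "wce_network_spec")
  validate_network_spec(spec)
  spec
}

#' Validate a network specification
#'
#' @param spec a `wce_network_spec`.
#' @return the spec, invisibly; errors name the offending layer index.
#' @export
validate_network_spec <- function(spec) {
  stopifnot(inherits(spec, "wce_network_spec"))
  ch <- spec$input_shape[3]
  for (layer in spec$layers) {
    cin <- layer_in_channels(layer)
    if (cin != ch)
      stop("layer ", layer$index, ": kernel expects ", cin,
           " input channels but preceding output has ", ch, call. = FALSE)
    ch <- layer_out_channels(layer)
  }
  sizes <- infer_shapes(spec)
  invisible(spec)
}

#' Per-layer output shapes under same-ceiling padding
#'
#' @param spec a `wce_network_spec`.
#' @return list of integer c(w, h, c), one per layer, the layer output sizes.
#' @export
infer_shapes <- function(spec) {
  w <- spec$input_shape[1]; h <- spec$input_shape[2]
  out <- vector("list", length(spec$layers))
  for (k in seq_along(spec$layers)) {
    layer <- spec$layers[[k]]
    w <- as.integer(ceiling(w / layer$stride))
    h <- as.integer(ceiling(h / layer$stride))
    if (w < 1 || h < 1)
      stop("layer ", layer$index, ": non-positive spatial size", call. = FALSE)
    out[[k]] <- c(w, h, layer_out_channels(layer))
  }
  out
}

#' The canonical 15-layer capsule detector architecture
#'
#' Standard 3x3 conv (stride 2) into a MobileNet-style stack of thirteen
#' depthwise-separable layers, closed by a 1x1 conv emitting the 4 x 4 x 15
#' detection grid (3 anchors x 5 box elements per cell). One printed filter
#' shape in the source table (layer 4's pointwise output) conflicts with its
#' printed output size; the output-size column is authoritative, so layer 4's
#' pointwise step emits 128 channels.
#'
#' @param input_size frame side in pixels (240 for the capsule camera).
#' @param width_multiplier scales every internal channel count (MobileNet's
#'   alpha); 1 reproduces the canonical network. Channels are rounded to at
#'   least 1. The 15 output channels are never scaled.
#' @param activation passed to [network_spec()].
#' @details With `input_size` below 240 the stride-2 ladder would shrink the
#'   grid below 4 x 4; trailing stride-2 layers are demoted to stride 1 (from
#'   the last backwards) until the output grid is at least 4 x 4. At 240 all
#'   six stride-2 layers are kept and the grid is exactly 4 x 4.
#' @return a `wce_network_spec`.
#' @export
canonical_network_spec <- function(input_size = 240L, width_multiplier = 1,
                                   activation = "relu6") {
  ch <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  # (kind, out_channels, stride) ladder of the canonical rows L1..L15
  plan <- list(
    list("conv", 32L, 2L),
    list("dw", 64L, 1L), list("dw", 128L, 2L), list("dw", 128L, 1L),
    list("dw", 256L, 2L), list("dw", 256L, 1L), list("dw", 512L, 2L),
    list("dw", 512L, 1L), list("dw", 512L, 1L), list("dw", 512L, 1L),
    list("dw", 512L, 1L), list("dw", 512L, 1L),
    list("dw", 1024L, 2L), list("dw", 1024L, 2L),
    list("conv15", 15L, 1L))
  # demote trailing stride-2 layers when the input is too small for a 4x4 grid
  strides <- vapply(plan, function(p) p[[3]], integer(1))
  grid_after <- function(ss) {
    s <- input_size
    for (st in ss) s <- ceiling(s / st)
    s
  }
  while (grid_after(strides) < 4 && any(strides == 2L))
    strides[max(which(strides == 2L))] <- 1L
  layers <- vector("list", 15L)
  cin <- 3L
  for (k in seq_len(15L)) {
    p <- plan[[k]]
    cout <- if (p[[1]] == "conv15") 15L else ch(p[[2]])
    layers[[k]] <- switch(p[[1]],
      conv = layer_spec(k, "standard_conv",
                        conv_kernel = c(3L, 3L, cin, cout), stride = strides[k]),
      conv15 = layer_spec(k, "standard_conv",
                          conv_kernel = c(1L, 1L, cin, cout), stride = strides[k],
                          followed_by_bn = FALSE),
      dw = layer_spec(k, "depthwise_separable",
                      depthwise_kernel = c(3L, 3L, cin), pointwise_out = cout,
                      stride = strides[k]))
    cin <- cout
  }
  network_spec(layers, input_shape = c(input_size, input_size, 3L),
               activation = activation)
}

#' Read / write a network specification as JSON
#'
#' One object per layer with fields `kind`, `kernel`, `stride`, `bn`; the
#' bundled `extdata/table1_network.json` reproduces the canonical
#' architecture.
#'
#' @param spec a `wce_network_spec`.
#' @param path file path.
#' @return `read_network_spec` returns a validated `wce_network_spec`.
#' @export
write_network_spec <- function(spec, path) {
  layers <- lapply(spec$layers, function(l) {
    if (l$kind == "standard_conv")
      list(kind = l$kind, kernel = l$conv_kernel, stride = l$stride,
           bn = l$followed_by_bn)
    else
      list(kind = l$kind, depthwise = l$depthwise_kernel,
           pointwise_out = l$pointwise_out, stride = l$stride,
           bn = l$followed_by_bn)
  })
  obj <- list(input_shape = spec$input_shape, activation = spec$activation,
              padding_mode = spec$padding_mode, layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(seq_along(obj$layers), function(k) {
    l <- obj$layers[[k]]
    if (l$kind == "standard_conv")
      layer_spec(k, l$kind, conv_kernel = unlist(l$kernel),
                 stride = l$stride, followed_by_bn = l$bn)
    else
      layer_spec(k, l$kind, depthwise_kernel = unlist(l$depthwise),
                 pointwise_out = l$pointwise_out, stride = l$stride,
                 followed_by_bn = l$bn)
  })
  network_spec(layers, input_shape = unlist(obj$input_shape),
               activation = obj$activation, padding_mode = obj$padding_mode)
}

#' @export
print.wce_network_spec <- function(x, ...) {
  shapes <- infer_shapes(x)
  cat("<wce_network_spec> ", length(x$layers), " layers, input ",
      paste(x$input_shape, collapse = "x"), ", activation ", x$activation, "\n",
      sep = "")
  for (k in seq_along(x$layers)) {
    l <- x$layers[[k]]
    desc <- if (l$kind == "standard_conv")
      paste0("conv ", paste(l$conv_kernel, collapse = "x"))
    else
      paste0("dw ", paste(l$depthwise_kernel, collapse = "x"), " + pw 1x1x",
             l$depthwise_kernel[3], "x", l$pointwise_out)
    cat(sprintf("  L%-2d %-28s S%d -> %s\n", k, desc, l$stride,
                paste(shapes[[k]], collapse = "x")))
  }
  invisible(x)
}

spec_hash <- function(spec) {
  digest::digest(list(lapply(spec$layers, unclass), spec$input_shape,
                      spec$activation, spec$padding_mode), algo = "xxhash64")
}
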