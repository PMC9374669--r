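#' Detection-head configuration
#'
#' @param S_t confidence threshold in \[0, 1\]; a frame is significant when
#'   at least one box has score `S_p >= S_t` (inclusive). Default 0.65, the
#'   deployed operating point.
#' @param nms_iou overlap threshold for non-maximum suppression; boxes with
#'   IoU at or above it against a higher-scoring box are suppressed.
#' @param anchors 3 x 2 matrix of (w, h) box priors in pixels. The defaults
#'   (24, 60, 120 square) span small-to-large polyps at 240 px.
#' @param image_size frame side in pixels the decoded coordinates refer to.
#' @return an object of class `wce_head_config`.
#' @export
head_config <- function(S_t = 0.65, nms_iou = 0.5,
                        anchors = cbind(c(24, 60, 120), c(24, 60, 120)),
                        image_size = 240L) {
  anchors <- as.matrix(anchors)
  stopifnot(S_t >= 0, S_t <= 1, nms_iou >= 0, nms_iou <= 1,
            nrow(anchors) == 3, ncol(anchors) == 2, all(anchors > 0),
            image_size >= 1)
  structure(list(S_t = S_t, nms_iou = nms_iou, anchors = anchors,
                 image_size = as.integer(image_size)),
            class = "wce_head_config")
}

#' Construct a set of bounding boxes
#'
#' Boxes use the upper-left-corner convention throughout: `(x, y)` is the
#' 0-based top-left corner, `w`/`h` extend right/down, all in pixels.
#'
#' @param x,y,w,h,score equal-length numeric vectors (`w`, `h` > 0;
#'   `score` in \[0, 1\], default 1 for ground truth).
#' @return a data.frame with columns x, y, w, h, score.
#' @export
bounding_boxes <- function(x = numeric(), y = numeric(), w = numeric(),
                           h = numeric(), score = rep(1, length(x))) {
  stopifnot(all(w > 0), all(h > 0), all(score >= 0), all(score <= 1))
  data.frame(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w),
             h = as.numeric(h), score = as.numeric(score))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
logit <- function(p) log(p / (1 - p))

#' Decode the detection grid into proposal boxes
#'
#' Each grid cell holds 3 anchored proposals of 5 elements in channel order
#' (score, x, y, w, h): the score and the center offsets pass through a
#' sigmoid (so the center stays inside the cell), width/height scale the
#' anchor priors exponentially. A 4 x 4 x 15 grid therefore yields exactly
#' 48 proposals. Decoded boxes are clipped to the frame; the pre-clip
#' center/size are kept in columns `cx, cy, bw, bh` so the decoding is
#' invertible (see `encode_boxes`).
#'
#' @param grid numeric array (g, g, 15); rows index y, columns x.
#' @param config a [head_config()].
#' @return a data.frame of g*g*3 proposals with columns x, y, w, h, score,
#'   cell_row, cell_col, anchor, cx, cy, bw, bh.
#' @export
decode_grid <- function(grid, config = head_config()) {
  d <- dim(grid)
  if (length(d) != 3 || d[3] != 15L)
    stop("grid must have 3 x 5 = 15 channels, got ",
         if (length(d) == 3) d[3] else "a non-3d array")
  g1 <- d[1]; g2 <- d[2]
  cell_h <- config$image_size / g1
  cell_w <- config$image_size / g2
  rows <- rep(seq_len(g1), times = g2)
  cols <- rep(seq_len(g2), each = g1)
  out <- vector("list", 3L)
  for (a in 1:3) {
    base <- (a - 1L) * 5L
    ts <- as.vector(grid[, , base + 1L])
    tx <- as.vector(grid[, , base + 2L])
    ty <- as.vector(grid[, , base + 3L])
    tw <- as.vector(grid[, , base + 4L])
    th <- as.vector(grid[, , base + 5L])
    cx <- (cols - 1 + sigmoid(tx)) * cell_w
    cy <- (rows - 1 + sigmoid(ty)) * cell_h
    bw <- config$anchors[a, 1] * exp(tw)
    bh <- config$anchors[a, 2] * exp(th)
    x1 <- pmax(cx - bw / 2, 0); y1 <- pmax(cy - bh / 2, 0)
    x2 <- pmin(cx + bw / 2, config$image_size)
    y2 <- pmin(cy + bh / 2, config$image_size)
    out[[a]] <- data.frame(x = x1, y = y1, w = x2 - x1, h = y2 - y1,
                           score = sigmoid(ts), cell_row = rows,
                           cell_col = cols, anchor = a,
                           cx = cx, cy = cy, bw = bw, bh = bh)
  }
  res <- do.call(rbind, out)
  res[res$w > 0 & res$h > 0, , drop = FALSE]
}

# Inverse of decode_grid on its own output: recover the raw grid activations
# from the pre-clip center/size columns.
encode_boxes <- function(boxes, config = head_config(), grid_size = 4L) {
  cell_w <- config$image_size / grid_size
  cell_h <- config$image_size / grid_size
  data.frame(
    ts = logit(boxes$score),
    tx = logit(boxes$cx / cell_w - (boxes$cell_col - 1)),
    ty = logit(boxes$cy / cell_h - (boxes$cell_row - 1)),
    tw = log(boxes$bw / config$anchors[boxes$anchor, 1]),
    th = log(boxes$bh / config$anchors[boxes$anchor, 2]))
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes: numeric c(x, y, w, h) or one-row data.frames with those
#'   columns.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes, 1 iff identical.
#' @export
iou <- function(a, b) {
  a <- as_box_vec(a); b <- as_box_vec(b)
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

as_box_vec <- function(b) {
  if (is.data.frame(b)) as.numeric(c(b$x[1], b$y[1], b$w[1], b$h[1]))
  else as.numeric(b[1:4])
}

# All-pairs IoU between two box data.frames (rows of A x rows of B).
iou_matrix <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(matrix(0, nrow(A), nrow(B)))
  ax1 <- A$x; ax2 <- A$x + A$w; ay1 <- A$y; ay2 <- A$y + A$h
  bx1 <- B$x; bx2 <- B$x + B$w; by1 <- B$y; by2 <- B$y + B$h
  ix <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  iy <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- ix * iy
  inter / (outer(A$w * A$h, B$w * B$h, "+") - inter)
}

#' Keep proposals whose confidence meets the threshold
#'
#' The condition is inclusive: `S_p >= S_t` survives.
#'
#' @param proposals box data.frame with a `score` column.
#' @param S_t threshold in \[0, 1\].
#' @return the surviving rows.
#' @export
confidence_filter <- function(proposals, S_t) {
  stopifnot(S_t >= 0, S_t <= 1)
  proposals[proposals$score >= S_t, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scoring remaining box (ties broken by lower
#' row index) and discards boxes overlapping it with IoU at or above
#' `nms_iou`. The surviving set is returned sorted by descending score, so
#' the top survivor is always the argmax of `S_p`.
#'
#' @param proposals box data.frame.
#' @param nms_iou suppression threshold in \[0, 1\].
#' @return surviving rows, sorted by descending score.
#' @export
nms <- function(proposals, nms_iou = 0.5) {
  n <- nrow(proposals)
  if (n == 0) return(proposals)
  ord <- order(-proposals$score, seq_len(n))
  alive <- rep(TRUE, n)
  keep <- integer()
  M <- iou_matrix(proposals, proposals)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[M[i, ] >= nms_iou] <- FALSE
  }
  proposals[keep, , drop = FALSE]
}

#' Classify a frame from its surviving detections
#'
#' @param detections confidence-filtered box data.frame.
#' @return `"significant"` if at least one box survives, else
#'   `"insignificant"` (an insignificant frame is deleted onboard; a
#'   significant one is transmitted).
#' @export
classify_frame <- function(detections) {
  if (nrow(detections) >= 1) "significant" else "insignificant"
}

#' Full detection pipeline for one frame
#'
#' forward -> decode -> confidence filter -> NMS.
#'
#' @param network a `wce_network`.
#' @param image (H, W, 3) array in \[0, 1\].
#' @param config a [head_config()].
#' @param apply_threshold filter at `config$S_t` before NMS? Set FALSE to
#'   keep the full ranked list (as evaluation does).
#' @return box data.frame of detections.
#' @export
detect_polyps <- function(network, image, config = head_config(),
                          apply_threshold = TRUE) {
  props <- decode_grid(forward(network, image), config)
  if (apply_threshold) props <- confidence_filter(props, config$S_t)
  nms(props, config$nms_iou)
}
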