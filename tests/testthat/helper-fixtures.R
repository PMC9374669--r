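# Shared fixtures and independent oracles. Oracles are deliberately written
# in a different style from the package code paths they check.

# Tiny 3-layer spec on an 8x8 input: fast to build/run in unit tests.
tiny_spec <- function(input = 8L) {
  network_spec(list(
    layer_spec(1, "standard_conv", conv_kernel = c(3, 3, 3, 4), stride = 2),
    layer_spec(2, "depthwise_separable", depthwise_kernel = c(3, 3, 4),
               pointwise_out = 6, stride = 2),
    layer_spec(3, "standard_conv", conv_kernel = c(1, 1, 6, 15), stride = 1,
               followed_by_bn = FALSE)),
    input_shape = c(input, input, 3L))
}

# Canonical architecture rows as printed (with the L4 pointwise resolved to
# the output-size column): kernel tuples only, summed by plain arithmetic.
table1_param_oracle <- function(include_bn = TRUE) {
  dw <- function(c) 3 * 3 * c
  pw <- function(cin, cout) cin * cout
  rows <- list(
    c(conv = 3 * 3 * 3 * 32, bn = 32),
    c(dwp = dw(32) + pw(32, 64), bn = 32 + 64),
    c(dwp = dw(64) + pw(64, 128), bn = 64 + 128),
    c(dwp = dw(128) + pw(128, 128), bn = 128 + 128), # output column wins
    c(dwp = dw(128) + pw(128, 256), bn = 128 + 256),
    c(dwp = dw(256) + pw(256, 256), bn = 256 + 256),
    c(dwp = dw(256) + pw(256, 512), bn = 256 + 512),
    c(dwp = dw(512) + pw(512, 512), bn = 512 + 512),
    c(dwp = dw(512) + pw(512, 512), bn = 512 + 512),
    c(dwp = dw(512) + pw(512, 512), bn = 512 + 512),
    c(dwp = dw(512) + pw(512, 512), bn = 512 + 512),
    c(dwp = dw(512) + pw(512, 512), bn = 512 + 512),
    c(dwp = dw(512) + pw(512, 1024), bn = 512 + 1024),
    c(dwp = dw(1024) + pw(1024, 1024), bn = 1024 + 1024),
    c(conv = 1 * 1 * 1024 * 15 + 15, bn = 0)) # final conv has bias, no BN
  weights <- sum(vapply(rows, `[[`, numeric(1), 1))
  bn <- 2 * sum(vapply(rows, `[[`, numeric(1), "bn"))
  if (include_bn) weights + bn else weights
}

# Independent greedy-NMS reference: repeated argmax over a working copy.
nms_reference <- function(boxes, thr) {
  work <- boxes
  work$.orig <- seq_len(nrow(work))
  kept <- integer()
  while (nrow(work) > 0) {
    best <- which(work$score == max(work$score))[1]
    kept <- c(kept, work$.orig[best])
    b <- work[best, ]
    drop <- vapply(seq_len(nrow(work)), function(i)
      iou(work[i, ], b) >= thr, logical(1))
    work <- work[!drop, , drop = FALSE]
  }
  boxes[kept, , drop = FALSE]
}

# Independent detection-matching reference: explicit loops, scalar iou().
match_reference <- function(dets, gts, thr) {
  ord <- order(dets$score, decreasing = TRUE)
  used <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- iou(dets[i, ], gts[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= thr) { tp[k] <- TRUE; used[best_j] <- TRUE }
  }
  list(tp = tp, fn = nrow(gts) - sum(tp))
}

# All-point PR integration done the slow way: precision envelope evaluated
# at each distinct recall level.
ap_reference <- function(tp_in_rank_order, n_gt) {
  n <- length(tp_in_rank_order)
  prec <- cumsum(tp_in_rank_order) / seq_len(n)
  rec <- cumsum(tp_in_rank_order) / n_gt
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n)) {
    dr <- rec[k] - prev_r
    if (dr > 0) {
      ap <- ap + dr * max(prec[k:n])
      prev_r <- rec[k]
    }
  }
  ap
}

rand_boxes <- function(n, S = 240, rng_max_side = 80) {
  w <- runif(n, 5, rng_max_side)
  h <- runif(n, 5, rng_max_side)
  bounding_boxes(x = runif(n, 0, S - w), y = runif(n, 0, S - h), w = w,
                 h = h, score = runif(n))
}

# Small balanced frame list over several patients, tiny images (fast).
make_tiny_frames <- function(n_patients = 5, per_patient = 8, size = 24,
                             seed = 99) {
  cfg <- synth_config(n_patients = n_patients,
                      frames_per_patient = per_patient,
                      frame_size = size, seed = seed)
  generate_dataset(cfg)
}
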