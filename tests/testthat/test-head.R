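test_that("decode_grid: 48 proposals, channel check, score squashing limits", {
  grid <- array(rnorm(4 * 4 * 15), dim = c(4, 4, 15))
  props <- decode_grid(grid, head_config())
  expect_equal(nrow(props), 48)
  expect_true(all(props$score >= 0 & props$score <= 1))
  expect_true(all(props$x >= 0 & props$y >= 0 &
                    props$x + props$w <= 240 & props$y + props$h <= 240))
  expect_error(decode_grid(array(0, dim = c(4, 4, 14))), "15 channels")
  # hugely negative raw scores squash to ~0 and never pass a positive S_t
  neg <- array(-50, dim = c(4, 4, 15))
  dn <- decode_grid(neg, head_config())
  expect_true(all(dn$score < 1e-12))
  expect_equal(nrow(confidence_filter(dn, 0.01)), 0)
})

test_that("an activated cell decodes inside its own 60-px cell region", {
  grid <- array(0, dim = c(4, 4, 15))
  grid[2, 3, 1] <- 8 # anchor 1 score at cell row 2, col 3
  props <- decode_grid(grid, head_config())
  top <- props[which.max(props$score), ]
  expect_equal(c(top$cell_row, top$cell_col), c(2, 3))
  # center offsets are sigmoid(0) = 0.5 of the way into the cell
  expect_true(top$cx >= 120 && top$cx < 180)
  expect_true(top$cy >= 60 && top$cy < 120)
  expect_equal(top$cx, 150)
  expect_equal(top$cy, 90)
})

test_that("decode then re-encode recovers the raw grid to 1e-6", {
  set.seed(31)
  cfg <- head_config()
  for (rep in 1:5) {
    raw <- array(rnorm(4 * 4 * 15, sd = 1.5), dim = c(4, 4, 15))
    props <- decode_grid(raw, cfg)
    enc <- wcepolyp:::encode_boxes(props, cfg, grid_size = 4)
    for (i in seq_len(nrow(props))) {
      a <- props$anchor[i]; r <- props$cell_row[i]; cc <- props$cell_col[i]
      base <- (a - 1) * 5
      expect_equal(enc$ts[i], raw[r, cc, base + 1], tolerance = 1e-6)
      expect_equal(enc$tx[i], raw[r, cc, base + 2], tolerance = 1e-6)
      expect_equal(enc$ty[i], raw[r, cc, base + 3], tolerance = 1e-6)
      expect_equal(enc$tw[i], raw[r, cc, base + 4], tolerance = 1e-6)
      expect_equal(enc$th[i], raw[r, cc, base + 5], tolerance = 1e-6)
    }
  }
})

test_that("iou: hand case, identity, disjointness, symmetry, translation", {
  a <- bounding_boxes(0, 0, 10, 10)
  b <- bounding_boxes(5, 5, 10, 10)
  expect_equal(iou(a, b), 25 / 175)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_boxes(20, 20, 5, 5)), 0)
  set.seed(5)
  for (i in 1:50) {
    p <- rand_boxes(1); q <- rand_boxes(1)
    v <- iou(p, q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(q, p))
    # joint translation leaves IoU unchanged
    dx <- runif(1, -30, 30); dy <- runif(1, -30, 30)
    p2 <- p; p2$x <- p2$x + dx; p2$y <- p2$y + dy
    q2 <- q; q2$x <- q2$x + dx; q2$y <- q2$y + dy
    expect_equal(iou(p2, q2), v, tolerance = 1e-12)
    expect_true((v == 1) == all(unlist(p[1:4]) == unlist(q[1:4])))
  }
})

test_that("confidence filter is inclusive at the threshold", {
  boxes <- bounding_boxes(c(0, 20, 40), c(0, 20, 40), rep(5, 3), rep(5, 3),
                          score = c(0.6, 0.65, 0.7))
  kept <- confidence_filter(boxes, 0.65)
  expect_equal(sort(kept$score), c(0.65, 0.7))
  expect_equal(nrow(confidence_filter(boxes, 0)), 3)
  expect_equal(nrow(confidence_filter(boxes[0, ], 0.5)), 0)
})

test_that("nms: overlapping boxes collapse to the top scorer", {
  b <- bounding_boxes(c(10, 12, 11), c(10, 12, 9), c(40, 40, 42),
                      c(40, 40, 40), score = c(0.9, 0.8, 0.7))
  out <- nms(b, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)
  # disjoint boxes all survive, sorted by score
  d <- bounding_boxes(c(0, 100, 200), c(0, 100, 200), rep(20, 3), rep(20, 3),
                      score = c(0.2, 0.9, 0.5))
  expect_equal(nms(d, 0.5)$score, c(0.9, 0.5, 0.2))
  expect_equal(nrow(nms(d[0, ], 0.5)), 0)
})

test_that("nms ties break to the lower box index", {
  b <- bounding_boxes(c(0, 1), c(0, 1), c(30, 30), c(30, 30),
                      score = c(0.8, 0.8))
  out <- nms(b, 0.3)
  expect_equal(rownames(out), "1")
})

test_that("nms agrees with the independent greedy reference on random sets", {
  set.seed(1234)
  for (rep in 1:300) {
    n <- sample(0:8, 1)
    boxes <- rand_boxes(n, S = 120, rng_max_side = 60)
    thr <- runif(1, 0.2, 0.8)
    got <- nms(boxes, thr)
    want <- nms_reference(boxes, thr)
    expect_equal(got[order(as.numeric(rownames(got))), ],
                 want[order(as.numeric(rownames(want))), ])
  }
})

test_that("top-1 survivor is stable under filter/nms order", {
  set.seed(77)
  for (rep in 1:50) {
    boxes <- rand_boxes(sample(1:10, 1))
    st <- runif(1, 0, max(boxes$score))
    a <- nms(confidence_filter(boxes, st), 0.5)
    b <- confidence_filter(nms(boxes, 0.5), st)
    if (nrow(a) > 0 || nrow(b) > 0)
      expect_equal(a[1, ], b[1, ])
  }
})

test_that("frame classification is monotone in surviving boxes", {
  expect_equal(classify_frame(bounding_boxes(0, 0, 5, 5, 0.9)), "significant")
  expect_equal(classify_frame(bounding_boxes()), "insignificant")
  expect_equal(classify_frame(rand_boxes(48)), "significant")
})
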