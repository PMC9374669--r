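test_that("balance_dataset pairs every polyp frame with one normal", {
  ds <- generate_dataset(synth_config(n_patients = 4, frames_per_patient = 12,
                                      polyp_prevalence = 0.4, frame_size = 16,
                                      seed = 3))
  lab <- vapply(ds, `[[`, character(1), "label")
  polyp <- ds[lab == "polyp"]; normal <- ds[lab == "normal"]
  bal <- balance_dataset(polyp, normal, seed = 1)
  expect_length(bal, 2 * length(polyp))
  labs <- vapply(bal, `[[`, character(1), "label")
  expect_equal(sum(labs == "polyp"), sum(labs == "normal"))
  expect_length(balance_dataset(list(), normal), 0)
  expect_error(balance_dataset(polyp, polyp[1:2]), "normal frames")
  # 3 polyp + pool of 10 -> 6 frames, 3 of each class
  six <- balance_dataset(polyp[1:3], normal[1:10], seed = 2)
  expect_length(six, 6)
  expect_equal(sum(vapply(six, `[[`, character(1), "label") == "polyp"), 3)
})

test_that("augment multiplies counts and keeps class and boxes", {
  ds <- make_tiny_frames(3, 6, size = 24, seed = 7)
  out <- augment(ds, factor = 4, seed = 9)
  expect_length(out, length(ds) * 4)
  for (i in seq_along(ds)) {
    src <- ds[[i]]
    for (v in 1:4) {
      a <- out[[(i - 1) * 4 + v]]
      expect_equal(a$label, src$label) # never flips class
      expect_equal(a$patient_id, src$patient_id)
      if (src$label == "polyp") expect_gte(nrow(a$boxes), 1)
      d <- dim(a$pixels)
      if (nrow(a$boxes) > 0)
        expect_true(all(a$boxes$x >= 0 & a$boxes$y >= 0 &
                          a$boxes$x + a$boxes$w <= d[2] &
                          a$boxes$y + a$boxes$h <= d[1]))
    }
    # the first variant is the original
    expect_identical(out[[(i - 1) * 4 + 1]]$pixels, src$pixels)
  }
  # factor 1 is the identity
  expect_identical(lapply(augment(ds, 1, seed = 1), `[[`, "pixels"),
                   lapply(ds, `[[`, "pixels"))
})

test_that("the tenfold bookkeeping reproduces 1528 -> 15280 exactly", {
  # miniature frames: the protocol arithmetic is size-independent
  polyp <- replicate(764, NULL, simplify = FALSE)
  set.seed(1)
  proto_p <- generate_frame(TRUE, 0, size = 16)
  proto_n <- generate_frame(FALSE, 0, size = 16)
  polyp <- rep(list(proto_p), 764)
  normal <- rep(list(proto_n), 800)
  bal <- balance_dataset(polyp, normal, seed = 4)
  expect_length(bal, 1528)
  aug <- augment(bal, factor = 10, seed = 4)
  expect_length(aug, 15280)
  labs <- vapply(aug, `[[`, character(1), "label")
  expect_equal(sum(labs == "polyp"), 7640)
  expect_equal(sum(labs == "normal"), 7640)
})

test_that("split_by_patient: disjoint patients, balanced val/test, seeded", {
  ds <- make_tiny_frames(12, 10, size = 16, seed = 21)
  sp <- split_by_patient(ds, seed = 5)
  parts <- lapply(sp[c("train", "validation", "test")], function(fr)
    unique(vapply(fr, `[[`, character(1), "patient_id")))
  expect_length(intersect(parts$train, parts$validation), 0)
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$validation, parts$test), 0)
  for (p in c("validation", "test")) {
    lab <- vapply(sp[[p]], `[[`, character(1), "label")
    expect_lte(abs(sum(lab == "polyp") - sum(lab == "normal")), 1)
  }
  # roughly 80/10/10 by images (patient granularity limits precision)
  expect_gt(length(sp$train) / length(ds), 0.6)
  sp2 <- split_by_patient(ds, seed = 5)
  expect_identical(lapply(sp2$train, `[[`, "patient_id"),
                   lapply(sp$train, `[[`, "patient_id"))
  expect_error(split_by_patient(ds[1:5][vapply(ds[1:5], `[[`, character(1),
                                               "patient_id") == "P001"]),
               "3 distinct patients")
})

test_that("patient disjointness holds across seeds (property)", {
  ds <- make_tiny_frames(8, 6, size = 16, seed = 31)
  pids <- vapply(ds, `[[`, character(1), "patient_id")
  for (seed in 1:10) {
    sp <- split_by_patient(ds, seed = seed)
    parts <- lapply(sp[c("train", "validation", "test")], function(fr)
      unique(vapply(fr, `[[`, character(1), "patient_id")))
    expect_equal(sum(lengths(parts)), length(unique(unlist(parts))))
  }
})

test_that("degenerate single-class parts cannot be balanced", {
  ds <- generate_dataset(synth_config(n_patients = 4, frames_per_patient = 3,
                                      polyp_prevalence = 0, frame_size = 16,
                                      seed = 2))
  expect_error(split_by_patient(ds, seed = 1), "only normal")
})

test_that("training: loss decreases, lr 0 is a null update, seeds reproduce", {
  ds <- generate_dataset(synth_config(n_patients = 6, frames_per_patient = 34,
                                      frame_size = 32, seed = 15))
  split <- split_by_patient(ds, seed = 15)
  spec <- canonical_network_spec(32L, 0.125)
  hc <- head_config(anchors = cbind(c(24, 60, 120), c(24, 60, 120)) * 32 / 240,
                    image_size = 32)
  net <- build_network(spec, 15)

  cfg <- train_config(batch_size = 20, epochs = 5, seed = 15, patience = 10)
  fit <- train_detector(net, split, cfg, head = hc)
  # smoothed early trend strictly decreasing
  tl <- fit$history$train_loss
  sm <- stats::filter(tl, rep(1 / 2, 2), sides = 1)[-1]
  expect_true(all(diff(sm[1:3]) < 0))
  expect_equal(nrow(fit$history), 5)

  # identical config + seed -> identical history and weights
  fit2 <- train_detector(net, split, cfg, head = hc)
  expect_identical(fit2$history, fit$history)
  expect_identical(fit2$network$layers, fit$network$layers)

  # learning rate 0 leaves every trainable tensor untouched
  fit0 <- train_detector(net, split,
                         train_config(batch_size = 20, epochs = 1,
                                      step_size = 0, seed = 15),
                         head = hc)
  for (k in seq_along(net$layers))
    for (s in wcepolyp:::param_slots(net$layers[[k]]))
      expect_identical(wcepolyp:::get_slot(fit0$network$layers[[k]], s),
                       wcepolyp:::get_slot(net$layers[[k]], s))
})
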