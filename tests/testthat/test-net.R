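test_that("canonical spec reproduces the reference shape trace", {
  spec <- canonical_network_spec()
  shapes <- infer_shapes(spec)
  expected <- list(
    c(120, 120, 32), c(120, 120, 64), c(60, 60, 128), c(60, 60, 128),
    c(30, 30, 256), c(30, 30, 256), c(15, 15, 512), c(15, 15, 512),
    c(15, 15, 512), c(15, 15, 512), c(15, 15, 512), c(15, 15, 512),
    c(8, 8, 1024), c(4, 4, 1024), c(4, 4, 15))
  expect_equal(lapply(shapes, as.numeric), expected)
})

test_that("infer_shapes: stride-1 layers keep spatial size, 15 -> 8 at stride 2", {
  spec <- network_spec(list(
    layer_spec(1, "depthwise_separable", depthwise_kernel = c(3, 3, 3),
               pointwise_out = 8, stride = 1),
    layer_spec(2, "depthwise_separable", depthwise_kernel = c(3, 3, 8),
               pointwise_out = 16, stride = 2)),
    input_shape = c(15L, 15L, 3L))
  sh <- infer_shapes(spec)
  expect_equal(sh[[1]], c(15L, 15L, 8L))
  expect_equal(sh[[2]], c(8L, 8L, 16L))
})

test_that("channel-chain violations are rejected naming the layer", {
  layers <- canonical_network_spec()$layers
  layers[[3]] <- layer_spec(3, "depthwise_separable",
                            depthwise_kernel = c(3, 3, 32), # L2 emits 64
                            pointwise_out = 128, stride = 2)
  expect_error(network_spec(layers), "layer 3")
})

test_that("parameter accounting matches the independent per-layer oracle", {
  net <- build_network(canonical_network_spec(), rng_seed = 1)
  expect_identical(count_parameters(net, include_bn = TRUE),
                   as.integer(table1_param_oracle(TRUE)))
  expect_identical(count_parameters(net, include_bn = FALSE),
                   as.integer(table1_param_oracle(FALSE)))
  # the printed 3.2M holds whether or not BN scale/shift are counted
  expect_equal(round(count_parameters(net, TRUE) / 1e6, 1), 3.2)
  expect_equal(round(count_parameters(net, FALSE) / 1e6, 1), 3.2)
  # seeds never change the count
  net2 <- build_network(canonical_network_spec(), rng_seed = 77)
  expect_identical(count_parameters(net2), count_parameters(net))
})

test_that("toy conv layer: 864 weights + 64 BN = 928, footprint 928 bytes", {
  spec <- network_spec(list(
    layer_spec(1, "standard_conv", conv_kernel = c(3, 3, 3, 32), stride = 2)),
    input_shape = c(8L, 8L, 3L))
  net <- build_network(spec, 1)
  expect_identical(count_parameters(net, TRUE), 928L)
  expect_identical(count_parameters(net, FALSE), 864L)
  expect_equal(int8_footprint(net), 928)
})

test_that("INT8 footprint is one byte per parameter; empty net is 0", {
  net <- build_network(tiny_spec(), 5)
  expect_equal(int8_footprint(net), count_parameters(net, TRUE))
  empty <- structure(list(layers = list()), class = "wce_network")
  expect_identical(count_parameters(empty), 0L)
  expect_equal(int8_footprint(empty), 0)
})

test_that("depthwise-separable layers undercut standard convs, ratio <= k^2", {
  for (l in canonical_network_spec()$layers) {
    if (l$kind != "depthwise_separable") next
    k <- l$depthwise_kernel[1]
    cin <- l$depthwise_kernel[3]
    n <- l$pointwise_out
    sep <- k * k * cin + cin * n
    std <- k * k * cin * n
    expect_lt(sep, std)
    expect_lte(std / sep, k^2)
  }
})

test_that("building twice with one seed is bit-identical; seeds differ", {
  a <- build_network(tiny_spec(), 42)
  b <- build_network(tiny_spec(), 42)
  expect_identical(a$layers, b$layers)
  c <- build_network(tiny_spec(), 43)
  expect_false(identical(a$layers, c$layers))
})

test_that("forward: output geometry, shape errors, zero propagation, determinism", {
  net <- build_network(tiny_spec(), 7)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  out <- forward(net, img)
  expect_equal(dim(out), c(2, 2, 15))
  expect_identical(out, forward(net, img))
  expect_error(forward(net, array(0.5, dim = c(9, 9, 3))), "shape")
  expect_error(forward(net, img + 10), "0, 1")
  # zero weights + BN identity in inference mode propagate zeros
  zero <- net
  for (k in seq_along(zero$layers)) {
    l <- zero$layers[[k]]
    for (s in wcepolyp:::param_slots(l)) {
      if (s %in% c("bn.gamma", "bn1.gamma", "bn2.gamma")) next
      v <- wcepolyp:::get_slot(l, s)
      v[] <- 0
      l <- wcepolyp:::set_slot(l, s, v)
    }
    zero$layers[[k]] <- l
  }
  expect_equal(max(abs(forward(zero, img))), 0)
})

test_that("full canonical forward maps 240x240x3 to a 4x4x15 grid", {
  net <- build_network(canonical_network_spec(), 1)
  img <- array(runif(240 * 240 * 3), dim = c(240, 240, 3))
  out <- forward(net, img)
  expect_equal(dim(out), c(4, 4, 15))
  expect_equal(nrow(decode_grid(out)), 48)
})

test_that("spec JSON round-trips and the bundled file is the canonical net", {
  spec <- canonical_network_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_identical(wcepolyp:::spec_hash(back), wcepolyp:::spec_hash(spec))
  bundled <- system.file("extdata", "table1_network.json",
                         package = "wcepolyp")
  expect_identical(wcepolyp:::spec_hash(read_network_spec(bundled)),
                   wcepolyp:::spec_hash(spec))
})

test_that("checkpoints round-trip and refuse a mismatched spec", {
  net <- build_network(tiny_spec(), 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path, expect_spec = tiny_spec())
  expect_identical(back$layers, net$layers)
  expect_error(load_checkpoint(path, expect_spec = canonical_network_spec()),
               "hash")
})

test_that("reduced-size canonical specs keep a >= 4x4 grid", {
  for (sz in c(64L, 96L, 120L)) {
    sh <- infer_shapes(canonical_network_spec(sz, 0.25))
    expect_gte(sh[[15]][1], 4)
    expect_equal(sh[[15]][3], 15)
  }
})
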