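# The network engine: reference R implementation vs the compiled
# workspace, finite-difference gradient checks, and optimizer behavior.

make_tiny_net <- function(head = "l2norm", seed = 1L, out_dim = 8L) {
  speckfew:::nn_build(input_size = 20L, conv1_out_channels = 3L,
                      conv2_out_channels = 4L, fc_hidden = 10L,
                      out_dim = out_dim, head = head, seed = seed)
}

ws_from_net <- function(net, capacity = 6L) {
  a <- net$arch
  ws <- speckfew:::cpp_ws_create(a$input_size, a$C1, a$C2, a$fc_hidden,
                                 a$out_dim, a$head == "l2norm", capacity)
  speckfew:::cpp_ws_set_params(ws, net$params)
  speckfew:::cpp_ws_set_state(ws, net$state)
  ws
}

test_that("compiled forward matches the reference R implementation", {
  net <- make_tiny_net()
  set.seed(2)
  X <- matrix(rnorm(400 * 5), 400, 5)
  ref <- speckfew:::nn_forward(net, X, training = FALSE)
  ws <- ws_from_net(net)
  out <- speckfew:::cpp_ws_forward(ws, X, FALSE)
  expect_equal(out, ref$out, tolerance = 1e-12)
  # training mode too (batch statistics path)
  ref_t <- speckfew:::nn_forward(net, X, training = TRUE)
  out_t <- speckfew:::cpp_ws_forward(ws, X, TRUE)
  expect_equal(out_t, ref_t$out, tolerance = 1e-12)
  expect_equal(speckfew:::cpp_ws_get_state(ws)$bn1_mean,
               matrix(ref_t$state$bn1_mean), tolerance = 1e-12)
})

test_that("compiled backward matches the reference gradients", {
  net <- make_tiny_net()
  set.seed(3)
  X <- matrix(rnorm(400 * 5), 400, 5)
  G <- matrix(rnorm(8 * 5), 8, 5)
  ref_fw <- speckfew:::nn_forward(net, X, training = TRUE)
  ref_gr <- speckfew:::nn_backward(net, ref_fw, G)
  ws <- ws_from_net(net)
  invisible(speckfew:::cpp_ws_forward(ws, X, TRUE))
  speckfew:::cpp_ws_backward(ws, G)
  cg <- speckfew:::cpp_ws_get_grads(ws)
  for (nm in names(ref_gr)) {
    expect_equal(as.vector(cg[[nm]]), as.vector(ref_gr[[nm]]),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("analytic gradients agree with finite differences", {
  net <- make_tiny_net(seed = 4L)
  set.seed(5)
  X <- matrix(rnorm(400 * 4), 400, 4)
  G <- matrix(rnorm(8 * 4) * 0.1, 8, 4)   # d(loss)/d(out) of linear loss
  loss_of <- function(params) {
    n2 <- net
    n2$params <- params
    fw <- speckfew:::nn_forward(n2, X, training = TRUE)
    sum(fw$out * G)
  }
  fw <- speckfew:::nn_forward(net, X, training = TRUE)
  gr <- speckfew:::nn_backward(net, fw, G)
  eps <- 1e-6
  for (nm in c("conv1_W", "conv2_W", "bn1_gamma", "bn2_beta", "fc1_W",
               "fc2_W", "fc2_b")) {
    w <- net$params[[nm]]
    picks <- speckfew:::with_seed(10, sample.int(length(w), min(4L, length(w))))
    for (k in picks) {
      p_hi <- net$params; p_hi[[nm]][k] <- w[k] + eps
      p_lo <- net$params; p_lo[[nm]][k] <- w[k] - eps
      num <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3,
                   label = paste(nm, k))
    }
  }
})

test_that("the sigmoid head bounds outputs and trains on pre-activations", {
  net <- make_tiny_net(head = "sigmoid", out_dim = 1L)
  set.seed(6)
  X <- matrix(rnorm(400 * 4), 400, 4)
  fw <- speckfew:::nn_forward(net, X)
  expect_true(all(fw$out >= 0 & fw$out <= 1))
  ws <- ws_from_net(net)
  expect_equal(speckfew:::cpp_ws_forward(ws, X, FALSE), fw$out,
               tolerance = 1e-12)
})

test_that("Adam with zero learning rate leaves parameters unchanged", {
  net <- make_tiny_net()
  ws <- ws_from_net(net)
  set.seed(7)
  X <- matrix(rnorm(400 * 4), 400, 4)
  invisible(speckfew:::cpp_ws_forward(ws, X, TRUE))
  speckfew:::cpp_ws_backward(ws, matrix(rnorm(8 * 4), 8, 4))
  speckfew:::cpp_ws_adam_step(ws, 0, 0.9, 0.999, 1e-8)
  after <- speckfew:::cpp_ws_get_params(ws)
  expect_equal(as.vector(after$conv1_W), as.vector(net$params$conv1_W))
  expect_equal(as.vector(after$fc1_W), as.vector(net$params$fc1_W))
  # and a positive learning rate moves them
  speckfew:::cpp_ws_adam_step(ws, 1e-3, 0.9, 0.999, 1e-8)
  moved <- speckfew:::cpp_ws_get_params(ws)
  expect_gt(max(abs(as.vector(moved$fc1_W) - as.vector(net$params$fc1_W))), 0)
})

test_that("workspace rejects oversized batches and wrong input sizes", {
  net <- make_tiny_net()
  ws <- ws_from_net(net, capacity = 3L)
  expect_error(speckfew:::cpp_ws_forward(ws, matrix(0, 400, 5), FALSE),
               "capacity")
  expect_error(speckfew:::cpp_ws_forward(ws, matrix(0, 100, 2), FALSE),
               "input_size")
})
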