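# Minimal CNN engine. Convolutions are GEMMs over im2col patch matrices
# (patch extraction, its adjoint, pooling and ReLU run in compiled code,
# see src/kernels.cpp); batch norm, the fully connected layers and Adam run
# on R's BLAS/vector ops. Two heads: unit-L2-normalisation (embedder on the
# hypersphere) and sigmoid (binary baseline). Written from scratch because
# the embedding network and its training are the heart of the method.

KERNEL <- 5L

conv_out <- function(s) s - KERNEL + 1L

# Spatial size chain for a square input; errors below the minimum size.
net_size_chain <- function(input_size) {
  s1 <- conv_out(input_size)
  p1 <- s1 %/% 2L
  s2 <- conv_out(p1)
  p2 <- s2 %/% 2L
  if (s1 < 2L || s2 < 2L || p2 < 1L) {
    stop("input_size ", input_size, " is too small for two valid 5x5 ",
         "convolutions each followed by 2x2 pooling; minimum input_size is 16",
         call. = FALSE)
  }
  list(s1 = s1, p1 = p1, s2 = s2, p2 = p2)
}

## ---- batch norm -------------------------------------------------------

bn_eps <- 1e-5

bn_forward <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1) {
  if (training) {
    M <- ncol(x)
    mu <- .rowMeans(x, nrow(x), M)
    v <- .rowMeans(x * x, nrow(x), M) - mu * mu
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + bn_eps)
    xhat <- cpp_row_affine(x, mu, inv, rep(1, nrow(x)), numeric(nrow(x)))
    y <- cpp_row_affine(x, mu, inv, gamma, beta)
    ub <- if (M > 1L) M / (M - 1) else 1
    list(y = y, xhat = xhat, inv = inv,
         rmean = (1 - momentum) * rmean + momentum * mu,
         rvar = (1 - momentum) * rvar + momentum * v * ub)
  } else {
    inv <- 1 / sqrt(rvar + bn_eps)
    list(y = cpp_row_affine(x, rmean, inv, gamma, beta),
         rmean = rmean, rvar = rvar)
  }
}

bn_backward <- function(dy, cache, gamma) {
  M <- ncol(dy)
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- (cache$inv / M) * (M * dxhat - rowSums(dxhat) - xhat * dgamma)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- network ----------------------------------------------------------

# head: "l2norm" (unit-hypersphere embedder) or "sigmoid" (binary baseline)
nn_build <- function(input_size = 96L, conv1_out_channels = 32L,
                     conv2_out_channels = 32L, fc_hidden = 512L,
                     out_dim = 128L, head = c("l2norm", "sigmoid"),
                     init_mean = 0, init_std = 0.2, seed = 1L) {
  head <- match.arg(head)
  input_size <- as.integer(input_size)
  ch <- net_size_chain(input_size)
  C1 <- as.integer(conv1_out_channels)
  C2 <- as.integer(conv2_out_channels)
  flat <- C2 * ch$p2 * ch$p2
  params <- with_seed(seed, {
    gw <- function(nr, nc) matrix(stats::rnorm(nr * nc, init_mean, init_std), nr, nc)
    list(
      conv1_W = gw(C1, KERNEL * KERNEL),
      conv1_b = numeric(C1),
      bn1_gamma = rep(1, C1), bn1_beta = numeric(C1),
      conv2_W = gw(C2, KERNEL * KERNEL * C1),
      conv2_b = numeric(C2),
      bn2_gamma = rep(1, C2), bn2_beta = numeric(C2),
      fc1_W = gw(fc_hidden, flat), fc1_b = numeric(fc_hidden),
      fc2_W = gw(out_dim, fc_hidden), fc2_b = numeric(out_dim)
    )
  })
  state <- list(bn1_mean = numeric(C1), bn1_var = rep(1, C1),
                bn2_mean = numeric(C2), bn2_var = rep(1, C2))
  arch <- list(input_size = input_size, C1 = C1, C2 = C2,
               fc_hidden = as.integer(fc_hidden), out_dim = as.integer(out_dim),
               head = head, chain = ch, flat = flat,
               init_mean = init_mean, init_std = init_std, seed = as.integer(seed))
  net <- list(params = params, state = state, arch = arch)
  class(net) <- "speckle_net"
  net
}

# X: (S*S) x N matrix of preprocessed images. Returns out (out_dim x N);
# with training = TRUE also the caches needed for a backward pass and the
# updated batch-norm running statistics.
nn_forward <- function(net, X, training = FALSE) {
  p <- net$params
  s <- net$state
  a <- net$arch
  ch <- a$chain
  N <- ncol(X)
  stopifnot(nrow(X) == a$input_size^2)
  X <- as.matrix(X)

  cols1 <- cpp_im2col(X, 1L, a$input_size, a$input_size, KERNEL)
  Z1 <- p$conv1_W %*% cols1 + p$conv1_b
  A1 <- cpp_relu(Z1)
  dim(A1) <- dim(Z1)
  bn1 <- bn_forward(A1, p$bn1_gamma, p$bn1_beta, s$bn1_mean, s$bn1_var, training)
  P1 <- cpp_pool_fw(bn1$y, a$C1, ch$s1, ch$s1, N)
  X2 <- matrix(P1$out, a$C1 * ch$p1 * ch$p1, N)

  cols2 <- cpp_im2col(X2, a$C1, ch$p1, ch$p1, KERNEL)
  Z2 <- p$conv2_W %*% cols2 + p$conv2_b
  A2 <- cpp_relu(Z2)
  dim(A2) <- dim(Z2)
  bn2 <- bn_forward(A2, p$bn2_gamma, p$bn2_beta, s$bn2_mean, s$bn2_var, training)
  P2 <- cpp_pool_fw(bn2$y, a$C2, ch$s2, ch$s2, N)
  flat <- matrix(P2$out, a$flat, N)

  H1 <- p$fc1_W %*% flat + p$fc1_b
  H1r <- cpp_relu(H1)
  dim(H1r) <- dim(H1)
  E <- p$fc2_W %*% H1r + p$fc2_b

  if (a$head == "l2norm") {
    nrm <- pmax(sqrt(colSums(E * E)), 1e-12)
    out <- sweep(E, 2L, nrm, `/`)
  } else {
    out <- 1 / (1 + exp(-E))
    nrm <- NULL
  }

  res <- list(out = out)
  if (training) {
    res$state <- list(bn1_mean = bn1$rmean, bn1_var = bn1$rvar,
                      bn2_mean = bn2$rmean, bn2_var = bn2$rvar)
    bn1$y <- NULL
    bn2$y <- NULL
    res$cache <- list(cols1 = cols1, Z1 = Z1, bn1 = bn1, P1 = P1,
                      cols2 = cols2, Z2 = Z2, bn2 = bn2, P2 = P2,
                      flat = flat, H1 = H1, H1r = H1r, nrm = nrm, N = N)
  }
  res
}

# dout: gradient of the loss w.r.t. the network output (out_dim x N).
# For the sigmoid head the caller supplies d(loss)/d(pre-sigmoid input)
# directly, which is numerically stabler for cross-entropy.
# Returns the gradient list matching net$params by name.
nn_backward <- function(net, fw, dout) {
  p <- net$params
  a <- net$arch
  ch <- a$chain
  cc <- fw$cache
  N <- cc$N

  if (a$head == "l2norm") {
    out <- fw$out
    s <- colSums(out * dout)
    dE <- sweep(dout - sweep(out, 2L, s, `*`), 2L, cc$nrm, `/`)
  } else {
    dE <- dout
  }

  dW_fc2 <- tcrossprod(dE, cc$H1r)
  db_fc2 <- rowSums(dE)
  dH1r <- crossprod(p$fc2_W, dE)
  dH1 <- cpp_relu_bw(dH1r, cc$H1)
  dim(dH1) <- dim(dH1r)
  dW_fc1 <- tcrossprod(dH1, cc$flat)
  db_fc1 <- rowSums(dH1)
  dflat <- crossprod(p$fc1_W, dH1)

  dBN2y <- matrix(cpp_pool_bw(dflat, cc$P2$which, a$C2, ch$s2, ch$s2, N),
                  a$C2, ch$s2 * ch$s2 * N)
  bn2g <- bn_backward(dBN2y, cc$bn2, p$bn2_gamma)
  dZ2 <- cpp_relu_bw(bn2g$dx, cc$Z2)
  dim(dZ2) <- dim(bn2g$dx)
  dW_c2 <- tcrossprod(dZ2, cc$cols2)
  db_c2 <- rowSums(dZ2)
  dcols2 <- crossprod(p$conv2_W, dZ2)
  dX2 <- cpp_col2im(dcols2, a$C1, ch$p1, ch$p1, KERNEL, N)

  dBN1y <- matrix(cpp_pool_bw(dX2, cc$P1$which, a$C1, ch$s1, ch$s1, N),
                  a$C1, ch$s1 * ch$s1 * N)
  bn1g <- bn_backward(dBN1y, cc$bn1, p$bn1_gamma)
  dZ1 <- cpp_relu_bw(bn1g$dx, cc$Z1)
  dim(dZ1) <- dim(bn1g$dx)
  dW_c1 <- tcrossprod(dZ1, cc$cols1)
  db_c1 <- rowSums(dZ1)

  list(conv1_W = dW_c1, conv1_b = db_c1,
       bn1_gamma = bn1g$dgamma, bn1_beta = bn1g$dbeta,
       conv2_W = dW_c2, conv2_b = db_c2,
       bn2_gamma = bn2g$dgamma, bn2_beta = bn2g$dbeta,
       fc1_W = dW_fc1, fc1_b = db_fc1,
       fc2_W = dW_fc2, fc2_b = db_fc2)
}

## ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
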