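test_that("focal loss matches its closed-form values", {
  # gamma = 0, alpha = 0.5: plain weighted cross entropy
  expect_equal(focal_loss(0.5, 1, focal_loss_params(0.5, 0)), 0.5 * log(2),
               tolerance = 1e-12)
  # hand-evaluated point
  expect_equal(focal_loss(0.9, 1, focal_loss_params(0.25, 2)),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-10)
  expect_equal(focal_loss(0.9, 1, focal_loss_params(0.25, 2)),
               2.6341e-4, tolerance = 1e-3)
  # confident predictions cost nothing
  for (g in c(0, 1, 2.5)) {
    expect_lt(focal_loss(1 - 1e-7, 1, focal_loss_params(0.3, g)), 1e-6)
    expect_lt(focal_loss(1 - 1e-7, 0, focal_loss_params(0.3, g)), 1e-6)
  }
  expect_error(focal_loss(0.5, 2), "labels")
})

test_that("focal loss reduces to alpha-weighted CE at gamma zero", {
  set.seed(1)
  for (rep in 1:20) {
    p <- runif(8, 0.01, 0.99)
    y <- rbinom(8, 1, 0.5)
    a <- runif(1, 0.05, 0.95)
    fl <- focal_loss(p, y, focal_loss_params(a, 0))
    at <- ifelse(y == 1, a, 1 - a)
    expect_equal(fl, mean(-at * log(p)), tolerance = 1e-12)
  }
})

test_that("focal loss is bounded by weighted CE and decreasing in p_t", {
  p <- seq(0.02, 0.98, by = 0.02)
  for (g in c(0.5, 1, 2)) {
    fl <- vapply(p, function(pt)
      focal_loss(pt, 1, focal_loss_params(0.25, g)), 0)
    ce <- -0.25 * log(p)
    expect_true(all(fl <= ce + 1e-12))
    expect_true(all(diff(fl) < 0))
    expect_true(all(fl >= 0))
  }
})

test_that("logit-mode focal loss agrees with probability mode", {
  set.seed(2)
  logits <- matrix(rnorm(12), 6, 2)
  y <- c(1, 0, 1, 1, 0, 1)
  p <- exp(logits) / rowSums(exp(logits))
  pt <- ifelse(y == 1, p[, 2], p[, 1])
  pars <- focal_loss_params(0.25, 2)
  expect_equal(focal_loss(logits, y, pars), focal_loss(pt, y, pars),
               tolerance = 1e-12)
})

test_that("training loss gradient matches finite differences", {
  set.seed(3)
  z <- matrix(rnorm(10), 2, 5)
  y <- c(0, 1, 1, 0, 1)
  for (loss in c("ce", "focal")) {
    r <- hsivigor:::loss_and_grad(z, y, loss)
    eps <- 1e-6
    for (i in c(1, 4, 9)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      num <- (hsivigor:::loss_and_grad(zp, y, loss)$loss -
                hsivigor:::loss_and_grad(zm, y, loss)$loss) / (2 * eps)
      expect_equal(r$dlogits[i], num, tolerance = 1e-5)
    }
  }
})

test_that("wavelength attention obeys its exact special cases", {
  C <- 6; r <- 2
  set.seed(4)
  W0 <- matrix(rnorm(C / r * C), C / r, C)
  W1 <- matrix(rnorm(C * C / r), C, C / r)
  # zero input, zero biases: attention is exactly 0.5 and output zero
  x0 <- array(0, c(C, 3, 3, 2))
  res <- wa_forward(x0, W0, W1)
  expect_true(all(res$attention == 0.5))
  expect_true(all(res$output == 0))
  # spatially constant input: max and avg branches coincide
  xc <- array(rep(1:C, 3 * 3 * 2), c(C, 3, 3, 2))
  res_c <- wa_forward(xc, W0, W1)
  h <- pmax(W0 %*% 1:C, 0)
  expect_equal(res_c$attention[, 1],
               as.numeric(1 / (1 + exp(-2 * (W1 %*% h)))), tolerance = 1e-12)
})

test_that("wavelength attention equals the brute-force oracle", {
  set.seed(5)
  for (trial in 1:100) {
    C <- sample(seq(4, 16, by = 2), 1)
    r <- sample(c(2, 4), 1)
    if (C %% r != 0) r <- 2
    H <- sample(2:4, 1); N <- sample(1:3, 1)
    x <- array(rnorm(C * H * H * N), c(C, H, H, N))
    W0 <- matrix(rnorm(C / r * C, sd = 0.5), C / r, C)
    W1 <- matrix(rnorm(C * C / r, sd = 0.5), C, C / r)
    b0 <- rnorm(C / r, sd = 0.2)
    b1 <- rnorm(C, sd = 0.2)
    got <- wa_forward(x, W0, W1, b0, b1)
    want <- wa_reference(x, W0, W1, b0, b1)
    expect_equal(got$attention, want$attention, tolerance = 1e-10)
    expect_equal(got$output, want$output, tolerance = 1e-10)
  }
})

test_that("network builders satisfy their shape contracts", {
  net <- net_config(60, width = 8, input_size = 32)
  m <- build_waresnet(net, wa_config(60, 6), seed = 1)
  x <- hsivigor:::samples_to_batch(synth_dataset(
    synth_config(n_seeds = 2, n_channels = 60, seed = 1))$samples)
  lg <- hsivigor:::model_forward(m, x)
  expect_equal(dim(lg), c(2L, 2L))
  lg2 <- hsivigor:::model_forward(m, x)
  expect_identical(lg, lg2)  # eval-mode determinism
  # full-sensor configuration: bottleneck width 176 / 16 = 11
  wa176 <- hsivigor:::nn_wa(176, 16)
  expect_equal(dim(wa176$W0), c(11L, 176L))
  expect_equal(dim(wa176$W1), c(176L, 11L))
  expect_error(wa_config(60, 16), "divisible")
  expect_error(net_config(60, input_size = 8), "input_size")
  small <- array(0, c(60, 8, 8, 1))
  expect_error(hsivigor:::model_forward(m, small), "below the minimum")
})

test_that("attention parameters account for the whole model difference", {
  C <- 24; r <- 4
  net <- net_config(C, width = 8, input_size = 16)
  m_wa <- build_waresnet(net, wa_config(C, r), seed = 1)
  m_bb <- build_resnet18_baseline(net, seed = 1)
  extra <- count_parameters(m_wa) - count_parameters(m_bb)
  expect_equal(extra, 2 * (C * C / r) + C + C / r)
})

test_that("attention forced open reduces to the plain baseline", {
  net <- net_config(12, width = 8, input_size = 16)
  m_wa <- build_waresnet(net, wa_config(12, 4), seed = 2)
  m_bb <- build_resnet18_baseline(net, seed = 3)
  # copy backbone weights (the attention model's parameter list is the
  # baseline's prefixed with the four attention tensors)
  ps_wa <- hsivigor:::model_params(m_wa)
  ps_bb <- hsivigor:::model_params(m_bb)
  off <- length(ps_wa) - length(ps_bb)
  expect_equal(off, 4L)
  for (i in seq_along(ps_bb)) {
    src <- ps_wa[[i + off]]
    dst <- ps_bb[[i]]
    dst$env[[dst$par]] <- src$env[[src$par]]
  }
  # saturate the gate: huge positive bias makes every attention weight ~1
  m_wa$layers$wa$W0[] <- 0
  m_wa$layers$wa$W1[] <- 0
  m_wa$layers$wa$b1[] <- 20
  set.seed(4)
  x <- array(runif(12 * 16 * 16 * 3), c(12, 16, 16, 3))
  expect_equal(hsivigor:::model_forward(m_wa, x),
               hsivigor:::model_forward(m_bb, x), tolerance = 1e-7)
})

test_that("attention extraction is bounded and gated models demand it", {
  net <- net_config(12, width = 8, input_size = 16)
  m <- build_waresnet(net, wa_config(12, 4), seed = 5)
  x <- array(runif(12 * 16 * 16 * 4), c(12, 16, 16, 4))
  att <- get_attention(m, x)
  expect_length(att, 12)
  expect_true(all(att > 0 & att < 1))
  # zero input, zero biases: exactly one half everywhere
  att0 <- get_attention(m, array(0, c(12, 16, 16, 2)))
  expect_true(all(att0 == 0.5))
  base <- build_resnet18_baseline(net, seed = 5)
  expect_error(get_attention(base, x), "without a wavelength-attention")
})

test_that("gradients reach the attention weights", {
  net <- net_config(12, width = 8, input_size = 16)
  m <- build_waresnet(net, wa_config(12, 4), seed = 6)
  set.seed(6)
  x <- array(runif(12 * 16 * 16 * 4), c(12, 16, 16, 4))
  lg <- hsivigor:::model_forward(m, x, training = TRUE)
  r <- hsivigor:::loss_and_grad(lg, c(0, 1, 0, 1), "focal")
  hsivigor:::model_backward(m, r$dlogits)
  expect_gt(max(abs(m$layers$wa$gW0)), 0)
  expect_gt(max(abs(m$layers$wa$gW1)), 0)
})

test_that("backpropagation matches finite differences end to end", {
  net <- net_config(6, width = 8, input_size = 16)
  m <- build_waresnet(net, wa_config(6, 2), seed = 7)
  set.seed(7)
  x <- array(rnorm(6 * 16 * 16 * 2), c(6, 16, 16, 2))
  y <- c(0, 1)
  loss_at <- function() {
    lg <- hsivigor:::model_forward(m, x)
    hsivigor:::loss_and_grad(lg, y, "focal")$loss
  }
  lg <- hsivigor:::model_forward(m, x)
  r <- hsivigor:::loss_and_grad(lg, y, "focal")
  hsivigor:::model_backward(m, r$dlogits)
  ps <- hsivigor:::model_params(m)
  eps <- 1e-5
  for (k in c(1, 3, 5, 20, length(ps))) {
    p <- ps[[k]]
    g <- p$env[[p$grad]]
    i <- which.max(abs(g))
    orig <- p$env[[p$par]][i]
    p$env[[p$par]][i] <- orig + eps
    lp <- loss_at()
    p$env[[p$par]][i] <- orig - eps
    lm <- loss_at()
    p$env[[p$par]][i] <- orig
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("checkpoints restore models exactly", {
  net <- net_config(8, width = 8, input_size = 16)
  m <- build_waresnet(net, wa_config(8, 4), seed = 8)
  set.seed(8)
  x <- array(runif(8 * 16 * 16 * 3), c(8, 16, 16, 3))
  before <- hsivigor:::model_forward(m, x)
  path <- file.path(withr::local_tempdir(), "model.ckpt")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(hsivigor:::model_forward(m2, x), before)
})
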