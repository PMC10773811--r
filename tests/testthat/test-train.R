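make_tiny_parts <- function(seed = 1, n = 40, effect = 0.3) {
  ds <- synth_dataset(tiny_synth(n = n, seed = seed, effect = effect))
  list(parts = split_parts(ds, seed = seed), truth = ds$truth)
}

test_that("disabled augmentation is the identity", {
  ds <- synth_dataset(tiny_synth(n = 2, seed = 1))
  cfg <- train_config(rotate_degrees = 0, hflip_prob = 0,
                      scale_range = c(1, 1))
  s <- ds$samples[[1]]
  expect_identical(augment_sample(s, cfg)$cube, s$cube)
})

test_that("two horizontal flips cancel", {
  ds <- synth_dataset(tiny_synth(n = 2, seed = 2))
  cfg <- train_config(rotate_degrees = 0, hflip_prob = 1,
                      scale_range = c(1, 1))
  s <- ds$samples[[1]]
  twice <- augment_sample(augment_sample(s, cfg), cfg)
  expect_equal(twice$cube, s$cube, tolerance = 1e-12)
})

test_that("augmentation never touches labels or the spectral axis", {
  ds <- synth_dataset(tiny_synth(n = 4, seed = 3))
  cfg <- train_config()
  set.seed(3)
  for (i in 1:250) {
    s <- ds$samples[[(i %% 4) + 1]]
    a <- augment_sample(s, cfg)
    expect_identical(a$label, s$label)
    expect_identical(dim(a$cube), dim(s$cube))
  }
  # right-angle rotations permute pixels exactly: values are preserved
  cfg90 <- train_config(rotate_degrees = 90, hflip_prob = 0,
                        scale_range = c(1, 1))
  s <- ds$samples[[1]]
  r <- augment_sample(s, cfg90)
  expect_equal(sort(as.vector(r$cube)), sort(as.vector(s$cube)))
})

test_that("evaluation metrics match the standard confusion formulas", {
  pred <- c(rep(1, 90), rep(1, 10), rep(0, 5), rep(0, 20))
  labs <- c(rep(1, 90), rep(0, 10), rep(1, 5), rep(0, 20))
  r <- hsivigor:::eval_report(pred, labs)
  expect_equal(unname(r$confusion), c(90, 10, 5, 20))
  expect_equal(r$accuracy, 110 / 125)
  expect_equal(r$positive$precision, 0.90)
  expect_equal(r$positive$recall, 90 / 95, tolerance = 1e-10)
  expect_equal(r$positive$f1,
               2 * 0.9 * (90 / 95) / (0.9 + 90 / 95), tolerance = 1e-10)
  perfect <- hsivigor:::eval_report(labs, labs)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro$f1, 1)
  # degenerate all-positive predictor on an 80/20 set
  labs2 <- c(rep(1, 80), rep(0, 20))
  allpos <- hsivigor:::eval_report(rep(1, 100), labs2)
  expect_equal(allpos$accuracy, 0.8)
  expect_equal(allpos$macro$precision, 0.4)
  expect_equal(allpos$macro$recall, 0.5)
})

test_that("metrics agree with a brute-force recount", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 60
    pred <- rbinom(n, 1, 0.6)
    labs <- rbinom(n, 1, 0.7)
    r <- hsivigor:::eval_report(pred, labs)
    cnt <- table(factor(pred, c(0, 1)), factor(labs, c(0, 1)))
    expect_equal(unname(r$confusion["TP"]), unname(cnt["1", "1"]))
    expect_equal(unname(r$confusion["TN"]), unname(cnt["0", "0"]))
    expect_equal(r$accuracy, mean(pred == labs))
    prec1 <- sum(pred == 1 & labs == 1) / sum(pred == 1)
    rec1 <- sum(pred == 1 & labs == 1) / sum(labs == 1)
    expect_equal(r$positive$precision, prec1)
    expect_equal(r$positive$recall, rec1)
    expect_equal(r$positive$f1, 2 * prec1 * rec1 / (prec1 + rec1))
  }
})

test_that("training is deterministic given the seed", {
  tp <- make_tiny_parts(seed = 5)
  cfg <- train_config(epochs = 3, batch_size = 16, seed = 5)
  net <- tiny_net()
  m1 <- build_waresnet(net, wa_config(8, 4), seed = 5)
  h1 <- train_model(m1, tp$parts$train, tp$parts$val, cfg)$history
  m2 <- build_waresnet(net, wa_config(8, 4), seed = 5)
  h2 <- train_model(m2, tp$parts$train, tp$parts$val, cfg)$history
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 3)
  expect_equal(h1$epoch, 1:3)
})

test_that("training fits separable data and the loss descends", {
  tp <- make_tiny_parts(seed = 6, n = 60, effect = 0.3)
  cfg <- train_config(epochs = 15, batch_size = 16, seed = 6, loss = "focal")
  m <- build_resnet18_baseline(tiny_net(), seed = 6)
  # validate on the training set so the returned checkpoint is the epoch
  # that fits the training data best
  fit <- train_model(m, tp$parts$train, tp$parts$train, cfg)
  expect_lt(fit$history$train_loss[15], fit$history$train_loss[1])
  pred <- predict_labels(fit$model, tp$parts$train)
  expect_gte(mean(pred == label_of(tp$parts$train)), 0.99)
})

test_that("checkpoint round trips reproduce evaluations exactly", {
  tp <- make_tiny_parts(seed = 7)
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 7)
  m <- build_waresnet(tiny_net(), wa_config(8, 4), seed = 7)
  fit <- train_model(m, tp$parts$train, tp$parts$val, cfg)
  r1 <- evaluate_model(fit$model, tp$parts$test)
  path <- file.path(withr::local_tempdir(), "ck")
  save_model(fit$model, path)
  r2 <- evaluate_model(load_model(path), tp$parts$test)
  expect_identical(r1, r2)
})

test_that("the ablation produces four labelled arms", {
  tp <- make_tiny_parts(seed = 8, n = 40)
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 8)
  abl <- run_ablation(tp$parts, cfg, tiny_net(), wa_config(8, 4))
  expect_equal(nrow(abl$summary), 4)
  expect_setequal(abl$summary$arm,
                  c("resnet18_ce", "focal_resnet18", "waresnet_ce",
                    "focal_waresnet"))
  expect_length(abl$reports, 4)
  # single-class split is rejected
  broken <- tp$parts
  broken$val <- broken$val[label_of(broken$val) == 1]
  expect_error(run_ablation(broken, cfg, tiny_net(), wa_config(8, 4)),
               "both classes")
})
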