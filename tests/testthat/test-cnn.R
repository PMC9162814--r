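test_that("conv and pool output-length rules match direct substitution", {
  expect_equal(conv_output_length(151, 5, 0, 1), 147L)
  expect_equal(conv_output_length(10, 10, 0, 1), 1L)
  expect_error(conv_output_length(10, 3, 0, 2), "invalid conv spec")
  expect_equal(pool_output_length(146, 2, 2), 73L)
  expect_equal(pool_output_length(7, 7, 1), 1L)
  expect_error(pool_output_length(10, 4, 4), "invalid pool spec")
  expect_error(conv_output_length(4, 5, 0, 1), "longer")
})

test_that("a zero-weight residual block is the identity map", {
  model <- build_model(101, seed = 51)
  rb <- model$layers[[which(vapply(model$layers, `[[`, character(1),
                                   "type") == "resblock")[1]]]
  rb$conv1$W[] <- 0; rb$conv1$b[] <- 0
  rb$conv2$W[] <- 0; rb$conv2$b[] <- 0
  x <- array(rnorm(3 * 48 * 32), c(3, 48, 32))
  expect_equal(residual_block(x, rb), x)
})

test_that("residual output equals input plus the inner transform", {
  model <- build_model(101, seed = 52)
  rb <- model$layers[[3]]
  set.seed(53)
  x <- array(rnorm(2 * 48 * 32), c(2, 48, 32))
  y <- residual_block(x, rb)
  # independent two-step recomputation: inner forward, then add
  pad <- function(a, p) {
    d <- dim(a)
    out <- array(0, c(d[1], d[2] + 2 * p, d[3]))
    out[, (p + 1):(p + d[2]), ] <- a
    out
  }
  conv_ref <- function(a, W, b, F, cin, cout, relu) {
    ap <- pad(a, (F - 1) / 2)
    d <- dim(a)
    out <- array(0, c(d[1], d[2], cout))
    # weight rows are ordered (tap, channel) with channel fastest
    Wt <- aperm(array(W, c(cin, F, cout)), c(2, 1, 3))
    for (n in seq_len(d[1])) for (p in seq_len(d[2])) {
      patch <- ap[n, p:(p + F - 1), , drop = FALSE]
      for (co in seq_len(cout)) {
        out[n, p, co] <- sum(patch[1, , ] * Wt[, , co]) + b[co]
      }
    }
    if (relu) out * (out > 0) else out
  }
  h1 <- conv_ref(x, rb$conv1$W, rb$conv1$b, 5, 32, 32, TRUE)
  h2 <- conv_ref(h1, rb$conv2$W, rb$conv2$b, 5, 32, 32, FALSE)
  expect_equal(y, x + h2, tolerance = 1e-10)
  expect_equal(y - h2, x, tolerance = 1e-10)
})

test_that("models build for all three studied input lengths with exact shapes", {
  for (L in c(101L, 151L, 201L)) {
    model <- build_model(L, seed = 54)
    types <- vapply(model$layers, `[[`, character(1), "type")
    n_convs <- sum(types == "conv") + 2L * sum(types == "resblock")
    expect_equal(n_convs, 6L)
    expect_equal(sum(types == "pool"), 3L)
    expect_equal(sum(types == "fc"), 1L)
    obs <- observed_shapes(model, batch_size = 2)
    expect_equal(obs$observed_length, obs$out_length)
  }
})

test_that("forward pass returns per-row probabilities summing to one", {
  model <- build_model(151, seed = 55)
  x <- matrix(rnorm(4 * 151), 4)
  p <- predict_proba(model, x)
  expect_length(p, 4)
  expect_true(all(p >= 0 & p <= 1))
  # duplicate rows give identical probabilities
  x2 <- rbind(x[1, ], x[1, ])
  p2 <- predict_proba(model, x2)
  expect_equal(p2[1], p2[2])
  expect_error(predict_proba(model, matrix(0, 2, 101)), "input length")
})

test_that("training on separable synthetic windows reaches high accuracy", {
  toy <- get_toy_model()
  final_acc <- tail(toy$history$accuracy, 1)
  expect_gte(final_acc, 0.95)
  # decreasing loss trend: median of last 5 below median of first 5
  lo <- toy$history$loss
  expect_lt(median(tail(lo, 5)), median(head(lo, 5)))
  expect_lt(tail(lo, 1), lo[1])
})

test_that("a held-out R-centred clean window scores above 0.5", {
  toy <- get_toy_model()
  out <- generate_clean_ecg(synthetic_config(duration_s = 20,
                                             mean_hr_bpm = 85, seed = 321))
  idx <- out$annotation$indices
  idx <- idx[idx >= 50 & idx < length(out$signal$samples) - 50]
  pos <- extract_window(out$signal, idx[3], 50)
  p <- predict_proba(toy$model, normalize_segments(matrix(pos, 1)))
  expect_gt(p, 0.5)
  neg <- extract_window(out$signal, idx[3] + 90L, 50)
  pn <- predict_proba(toy$model, normalize_segments(matrix(neg, 1)))
  expect_lt(pn, 0.5)
})

test_that("training rejects single-class datasets and honours epoch count", {
  toy <- get_toy_model()
  ds <- toy$dataset
  one_class <- list(x = ds$x[ds$label == "R", ],
                    label = droplevels(ds$label[ds$label == "R"]))
  model <- build_model(101, seed = 56)
  expect_error(train_model(model, one_class, train_config(epochs = 1)),
               "both classes")
  sub <- list(x = ds$x[1:40, ], label = ds$label[1:40])
  tr <- train_model(model, sub, train_config(epochs = 1, seed = 2))
  expect_equal(nrow(tr$history), 1)
  expect_named(tr$history, c("epoch", "loss", "accuracy"))
})

test_that("build errors name the offending layer on an invalid chain", {
  expect_error(build_model(8), "layer conv")
})
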