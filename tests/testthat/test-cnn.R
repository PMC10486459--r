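# small configurations keep the unit tests fast; the architecture is the
# same as the default (conv + LRN + pool twice, two locally connected
# layers, FC + sigmoid)
small_cnn <- function(seed = 1L, epochs = 5L)
  cnn_config(conv_channels = c(3L, 6L), lc_channels = c(6L, 6L),
             fc_units = 6L, epochs = epochs, batch_size = 32L,
             learning_rate = 0.05, seed = seed)

test_that("forward pass respects range, shape and seeding contracts", {
  m <- build_cnn(small_cnn(seed = 7L))
  z <- predict(m, array(0, c(1, 32, 32)))
  expect_length(z, 1)
  expect_true(is.finite(z) && z >= 0 && z <= 1)
  batch <- array(rnorm(9 * 32 * 32), c(9, 32, 32))
  s <- predict(m, batch)
  expect_length(s, 9)
  expect_true(all(s >= 0 & s <= 1))
  # same seed, same initial parameters; different seed differs
  m2 <- build_cnn(small_cnn(seed = 7L))
  expect_identical(m$params, m2$params)
  m3 <- build_cnn(small_cnn(seed = 8L))
  expect_false(identical(m$params, m3$params))
  expect_error(build_cnn(cnn_config(conv_kernel = 4L)),
               class = "bcsurv_construction_error")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- cnn_config(conv_channels = c(2L, 3L), lc_channels = c(3L, 3L),
                    fc_units = 4L, seed = 42L)
  m <- build_cnn(cfg)
  set.seed(9)
  x <- array(rnorm(4 * 32 * 32), c(4, 32, 32))
  y <- c(1, 0, 1, 0)
  loss_fn <- function(mm) {
    p <- bcsurv:::cnn_forward(mm, x)$prob
    -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
  }
  cache <- bcsurv:::cnn_forward(m, x, keep_cache = TRUE)
  gr <- bcsurv:::cnn_backward(m, cache, y)
  eps <- 1e-5
  set.seed(17)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]),
                1e-4 * max(1e-3, abs(num) + abs(gr[[nm]][i])))
    }
  }
})

test_that("zero epochs return the seeded initialisation unchanged", {
  m <- build_cnn(small_cnn())
  x <- array(rnorm(20 * 32 * 32), c(20, 32, 32))
  y <- rep(c(0, 1), 10)
  m0 <- train_cnn(m, list(x = x, y = y), list(x = x, y = y), epochs = 0L)
  expect_identical(m0$params, m$params)
  expect_error(train_cnn(m, list(x = x, y = rep(1, 20)),
                         list(x = x, y = y)),
               class = "bcsurv_training_error")
})

test_that("the CNN learns linearly separable hybrid patterns", {
  # class 1 = brighter pre (left) half; majority of seeds reach
  # training ROI AUC > 0.95 within 20 epochs
  passed <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 140
    x <- array(rnorm(n * 32 * 32, sd = 0.3), c(n, 32, 32))
    y <- rep(c(0, 1), length.out = n)
    for (i in which(y == 1)) x[i, , 1:16] <- x[i, , 1:16] + 0.8
    m <- build_cnn(small_cnn(seed = s, epochs = 20L))
    m <- train_cnn(m, list(x = x[1:100, , ], y = y[1:100]),
                   list(x = x[101:140, , ], y = y[101:140]))
    bcsurv:::auc_mw(predict(m, x[1:100, , ]), y[1:100]) > 0.95
  }, TRUE)
  expect_gte(mean(passed), 0.6)
})

test_that("permuted labels keep validation AUC in the null band", {
  set.seed(7)
  n <- 120
  x <- array(rnorm(n * 32 * 32, sd = 0.3), c(n, 32, 32))
  y_true <- rep(c(0, 1), length.out = n)
  for (i in which(y_true == 1)) x[i, , 1:16] <- x[i, , 1:16] + 0.8
  aucs <- vapply(1:10, function(s) {
    set.seed(200 + s)
    y <- sample(y_true)   # break the image-label link
    m <- build_cnn(small_cnn(seed = s, epochs = 2L))
    m <- train_cnn(m, list(x = x[1:80, , ], y = y[1:80]),
                   list(x = x[81:120, , ], y = y[81:120]))
    bcsurv:::auc_mw(predict(m, x[81:120, , ]), y[81:120])
  }, 0)
  # mean of 10 null AUCs at n=40 (~20/20): sd of one AUC ~ 0.093, with
  # best-epoch selection adding a small upward bias; allow 4 sd of the mean
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("case scores aggregate ROI likelihoods as configured", {
  m <- build_cnn(small_cnn())
  fake <- structure(list(config = m$config, geometry = m$geometry,
                         params = m$params, trained = TRUE),
                    class = "roi_cnn")
  x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
  sc <- score_case(fake, x, "mean", "p1")
  expect_s3_class(sc, "case_score")
  expect_equal(sc$case_likelihood, mean(sc$roi_scores))
  expect_gte(sc$case_likelihood, min(sc$roi_scores))
  expect_lte(sc$case_likelihood, max(sc$roi_scores))
  one <- score_case(fake, x[1, , , drop = FALSE], "mean")
  expect_equal(one$case_likelihood, one$roi_scores[1])
  mx <- score_case(fake, x, "max")
  expect_equal(mx$case_likelihood, max(mx$roi_scores))
  expect_error(score_case(fake, array(0, c(0, 32, 32))),
               class = "bcsurv_scoring_error")
})
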