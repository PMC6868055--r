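test_that("the network outputs probability vectors of the right width", {
  m <- build_cnn(cnn_config(4), seed = 1)
  withr::with_seed(2, img <- array(sample(0:65535, 50 * 50 * 3 * 3, TRUE),
                                   c(50, 50, 3, 3)))
  p <- predict_proba(m, img)
  expect_equal(dim(p), c(3, 4))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # identical seeds give identical initial parameters
  expect_identical(build_cnn(cnn_config(4), seed = 7)$params,
                   build_cnn(cnn_config(4), seed = 7)$params)
  expect_error(cnn_config(4, filters = c(8, 16, 64)), "8, 16, 32")
})

test_that("backpropagation matches numerical gradients", {
  kf <- asNamespace("kinetoforge")
  m <- build_cnn(cnn_config(3), seed = 2)
  withr::with_seed(3, img <- array(sample(0:65535, 50 * 50 * 3 * 4, TRUE),
                                   c(50, 50, 3, 4)))
  x <- kf$images_to_input(img)
  y <- c(1L, 2L, 3L, 1L)
  gr <- kf$cnn_grads(m, x, y, 4L)
  eps <- 1e-5
  withr::with_seed(4, {
    for (nm in c("W1", "g2", "be3", "W3", "Wf")) {
      i <- sample(length(m$params[[nm]]), 1L)
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (kf$cnn_grads(mp, x, y, 4L)$loss -
                kf$cnn_grads(mm, x, y, 4L)$loss) / (2 * eps)
      expect_equal(gr$grads[[nm]][i], num, tolerance = 1e-5)
    }
  })
})

test_that("split_dataset produces exact stratified 56/24/20 partitions", {
  labels <- rep("x", 100)
  sp <- split_dataset(labels, seed = 1)
  expect_length(sp$train, 56L)
  expect_length(sp$validation, 24L)
  expect_length(sp$test, 20L)
  withr::with_seed(5, {
    for (n in sample(50:5000, 5)) {
      lab <- sample(c("a", "b", "c"), n, TRUE)
      s <- split_dataset(lab, seed = n)
      all_ix <- c(s$train, s$validation, s$test)
      expect_equal(sort(all_ix), seq_len(n))
      expect_equal(anyDuplicated(all_ix), 0L)
    }
  })
  expect_identical(split_dataset(labels, seed = 3),
                   split_dataset(labels, seed = 3))
  expect_error(split_dataset(c("a", rep("b", 50)), seed = 1), "class")
})

test_that("balance_classes downsamples to the smallest class", {
  labels <- rep(c("nuf2", "cse4"), c(5920, 4416))
  keep <- balance_classes(labels, seed = 1)
  expect_equal(as.integer(table(labels[keep])), c(4416L, 4416L))
  expect_equal(anyDuplicated(keep), 0L)
  balanced <- rep(c("a", "b"), each = 10)
  expect_length(balance_classes(balanced, seed = 1), 20L)
  expect_identical(balance_classes(labels, seed = 2),
                   balance_classes(labels, seed = 2))
})

test_that("training overfits a tiny labelled set and logs validation", {
  withr::with_seed(6, {
    n <- 40
    imgs <- array(0L, c(50, 50, 3, n))
    y <- rep(c("left", "right"), each = n / 2)
    for (i in seq_len(n)) {
      ctr <- if (y[i] == "left") c(22, 18) else c(28, 33)
      rr <- matrix(seq_len(50), 50, 50); cc <- t(rr)
      m <- 400 + 25000 * exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / 16) +
        rnorm(2500, sd = 100)
      imgs[, , 2, i] <- as.integer(pmax(pmin(m, 65535), 0))
    }
  })
  sp <- split_dataset(y, seed = 2)
  model <- build_cnn(cnn_config(2), seed = 3)
  tc <- train_config(max_epochs = 25, batch_size = 8,
                     validation_frequency = 10, seed = 4)
  model <- train_cnn(model, imgs, y, sp, tc)
  cm_train <- evaluate_cnn(model, imgs[, , , sp$train, drop = FALSE],
                           y[sp$train])
  expect_equal(attr(cm_train, "accuracy"), 1)
  # history records one entry per validation_frequency iterations
  iters <- 25 * ceiling(length(sp$train) / 8)
  expect_equal(nrow(model$history), floor(iters / 10))
  expect_true(all(model$history$val_accuracy >= 0 &
                    model$history$val_accuracy <= 1))

  cm <- evaluate_cnn(model, imgs, y)
  expect_equal(unname(rowSums(cm)), unname(as.integer(table(y))))
  expect_equal(attr(cm, "accuracy"), sum(diag(cm)) / sum(cm))

  pred <- predict(model, imgs)
  expect_equal(length(pred), n)
  expect_setequal(levels(pred), c("left", "right"))
  # an all-zero image is classified without error
  expect_length(predict(model, array(0L, c(50, 50, 3, 1))), 1L)
})

test_that("training is reproducible under fixed seeds", {
  withr::with_seed(7, {
    imgs <- array(sample(0:65535, 50 * 50 * 3 * 24, TRUE),
                  c(50, 50, 3, 24))
    y <- rep(c("a", "b"), each = 12)
  })
  sp <- split_dataset(y, seed = 1)
  tc <- train_config(max_epochs = 2, batch_size = 8, seed = 5)
  m1 <- train_cnn(build_cnn(cnn_config(2), seed = 9), imgs, y, sp, tc)
  m2 <- train_cnn(build_cnn(cnn_config(2), seed = 9), imgs, y, sp, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})
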