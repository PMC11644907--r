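test_that("architectures build with the documented layer stacks", {
  lm <- build_model(model_config("LM-CNN", seed = 1), c(8, 14))
  ls_ <- layer_summary(lm)
  expect_equal(unname(ls_[["conv"]]), 2L)
  expect_equal(unname(ls_[["pool"]]), 1L)
  expect_equal(unname(ls_[["dropout"]]), 1L)
  expect_equal(unname(ls_[["bn"]]), 2L)
  convs <- Filter(function(l) l$type == "conv", lm$layers)
  expect_true(all(vapply(convs, `[[`, character(1), "act") == "tanh"))
  denses <- Filter(function(l) l$type == "dense", lm$layers)
  expect_equal(denses[[1]]$units, 100L)
  expect_equal(denses[[1]]$act, "relu")
  expect_equal(denses[[2]]$units, 3L)

  c3 <- build_model(model_config("CNN3", seed = 1), c(8, 14))
  l3 <- layer_summary(c3)
  expect_equal(unname(l3[["conv"]]), 1L)
  expect_equal(unname(l3[["pool"]]), 1L)
  d3 <- Filter(function(l) l$type == "dense", c3$layers)
  expect_equal(d3[[1]]$units, 256L)
  expect_false("bn" %in% names(l3))

  expect_error(build_model(model_config(), c(1, 1)), "too small")
})

test_that("model building is seed-deterministic", {
  cfg <- model_config(seed = 7)
  a <- build_model(cfg, c(8, 14))
  b <- build_model(cfg, c(8, 14))
  expect_identical(a$layers, b$layers)
  c_ <- build_model(model_config(seed = 8), c(8, 14))
  expect_false(identical(a$layers, c_$layers))
})

test_that("training contracts hold for degenerate inputs", {
  xs <- separable_grids(30, seed = 1)
  m <- build_model(model_config(epochs = 0L, seed = 1), c(8, 14))
  m0 <- train(m, xs)
  expect_identical(m0$layers, m$layers)     # untouched at 0 epochs
  expect_equal(nrow(m0$history), 0L)
  one_class <- xs[vapply(xs, attr, character(1), "label") == "RELAX"]
  expect_error(train(m, one_class), "single-class")
  bad <- xs
  attr(bad[[1]], "label") <- "JUMP"
  expect_error(train(m, bad), "outside the class set")
})

test_that("training is reproducible and loses no samples to batching", {
  xs <- separable_grids(36, seed = 2)
  cfg <- model_config(epochs = 3L, batch_size = 16L, seed = 3)
  m1 <- train(build_model(cfg, c(8, 14)), xs)
  m2 <- train(build_model(cfg, c(8, 14)), xs)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 3L)
})

test_that("prediction returns normalized probabilities in class order", {
  xs <- separable_grids(24, seed = 4)
  m <- train(build_model(model_config(epochs = 5L, seed = 4), c(8, 14)), xs)
  pr <- predict(m, xs)
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, 24), tolerance = 1e-6)
  expect_identical(colnames(pr$probabilities), c("RELAX", "LEFT", "RIGHT"))
  empty <- predict(m, list())
  expect_length(empty$labels, 0L)
  expect_error(predict(m, list(structure(matrix(0, 4, 4), label = "RELAX"))),
               "shape mismatch")
})

test_that("metrics agree with an independent label-pair oracle", {
  set.seed(6)
  classes <- c("RELAX", "LEFT", "RIGHT")
  truth <- sample(classes, 500, replace = TRUE)
  pred <- truth
  flip <- sample(500, 150)
  pred[flip] <- sample(classes, 150, replace = TRUE)
  m <- metrics_from_labels(truth, pred, classes)
  # oracle computed directly from pairs with loops
  acc_o <- mean(truth == pred)
  prec_o <- mean(vapply(classes, function(cl) {
    denom <- sum(pred == cl)
    if (denom == 0) 0 else sum(pred == cl & truth == cl) / denom
  }, numeric(1)))
  rec_o <- mean(vapply(classes, function(cl) {
    denom <- sum(truth == cl)
    if (denom == 0) 0 else sum(pred == cl & truth == cl) / denom
  }, numeric(1)))
  expect_equal(m$accuracy, acc_o, tolerance = 1e-12)
  expect_equal(m$precision, prec_o, tolerance = 1e-12)
  expect_equal(m$recall, rec_o, tolerance = 1e-12)
  expect_equal(sum(m$confusion), 500)
  expect_equal(unname(rowSums(m$confusion)),
               unname(vapply(classes, function(cl) sum(truth == cl), numeric(1))))
})

test_that("hand-built confusion cases give the expected accuracy", {
  truth <- c(rep("A", 5), rep("B", 5), rep("C", 5))
  pred <- c(rep("A", 5), rep("B", 4), "C", rep("C", 4), "B")
  m <- metrics_from_labels(truth, pred, c("A", "B", "C"))
  expect_equal(m$accuracy, 13 / 15)
  expect_equal(unname(diag(m$confusion)), c(5, 4, 4))

  perfect <- metrics_from_labels(truth, truth, c("A", "B", "C"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)
})

test_that("uniformly shuffled predictions sit at chance for 3 classes", {
  set.seed(0)
  classes <- c("RELAX", "LEFT", "RIGHT")
  truth <- rep(classes, each = 1000)
  pred <- sample(truth)
  m <- metrics_from_labels(truth, pred, classes)
  expect_equal(m$accuracy, 1 / 3, tolerance = 0.03)
})

test_that("metrics are equivariant under class-label permutation", {
  set.seed(8)
  classes <- c("A", "B", "C")
  truth <- sample(classes, 300, replace = TRUE)
  pred <- sample(classes, 300, replace = TRUE)
  m1 <- metrics_from_labels(truth, pred, classes)
  map <- c(A = "C", B = "A", C = "B")
  m2 <- metrics_from_labels(unname(map[truth]), unname(map[pred]),
                            c("C", "A", "B"))
  expect_equal(m2$accuracy, m1$accuracy)
  expect_equal(unname(diag(m2$confusion)), unname(diag(m1$confusion)))
})

test_that("grid search returns the best cell with deterministic tie-breaks", {
  xs <- separable_grids(40, shape = c(4, 4), seed = 10)
  one <- grid_search_cv(xs, batch_sizes = 16L, epoch_grid = 4L, k = 2L,
                        cfg = model_config(seed = 1), seed = 1)
  expect_equal(one$batch_size, 16L)
  expect_equal(one$epochs, 4L)

  res <- grid_search_cv(xs, batch_sizes = c(16L, 8L), epoch_grid = c(5L, 3L),
                        k = 2L, cfg = model_config(seed = 1), seed = 1)
  expect_equal(nrow(res$results), 4L)
  if (max(res$results$mean_accuracy) == 1 &&
      sum(res$results$mean_accuracy == 1) > 1) {
    # perfectly separable: ties resolve to the smallest cell
    best_rows <- res$results[res$results$mean_accuracy == 1, ]
    expect_equal(res$batch_size, min(best_rows$batch_size))
  }
  expect_error(grid_search_cv(xs, k = 40L, cfg = model_config(seed = 1)),
               "fewer samples than")
  expect_error(grid_search_cv(xs, batch_sizes = integer(0)), "empty grid")
})
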