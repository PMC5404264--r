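test_that("normalization uses training statistics only", {
  set.seed(31)
  tr <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
  te <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4)
  nz <- normalize_features(tr, te)
  expect_equal(unname(colMeans(nz$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(nz$train, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # a test row equal to the training mean maps to the origin
  nz2 <- normalize_features(tr, matrix(colMeans(tr), 1))
  expect_equal(as.numeric(nz2$test), rep(0, 4), tolerance = 1e-9)
  # constant features pass through unchanged
  trc <- cbind(tr, 7)
  nzc <- normalize_features(trc)
  expect_true(all(nzc$train[, 5] == 0))
  expect_equal(nzc$scale[5], 1, ignore_attr = TRUE)
  expect_error(normalize_features(tr[0, ]), "empty")
})

test_that("F-score matches the hand-computed two-class example", {
  x <- matrix(c(0, 2, 4, 6), ncol = 1, dimnames = list(NULL, "f"))
  y <- c("a", "a", "b", "b")
  # class means 1 and 5, grand mean 3: numerator (1-3)^2 + (5-3)^2 = 8;
  # within-class variances 2 + 2 = 4; F = 2
  r <- fscore_rank(x, y)
  expect_equal(r$fscore, 2)
  # identical class distributions score zero
  x2 <- matrix(c(1, 2, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(fscore_rank(x2, y)$fscore, 0)
  # permuting rows leaves the ranking unchanged
  set.seed(32)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yy <- rep(c("a", "b", "c"), each = 10)
  perm <- sample(30)
  expect_equal(fscore_rank(X, yy), fscore_rank(X[perm, ], yy[perm]))
  # zero within-class variance with separated means hits the Inf sentinel
  x3 <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(fscore_rank(x3, y)$fscore, Inf)
  expect_error(fscore_rank(X, rep("a", 30)), "two classes")
})

test_that("the SVM separates Gaussian blobs and fits XOR where a linear rule cannot", {
  set.seed(33)
  n <- 60
  blobs <- rbind(matrix(rnorm(2 * n), n, 2),
                 matrix(rnorm(2 * n, mean = 4), n, 2))
  colnames(blobs) <- c("f1", "f2")
  yb <- rep(c("a", "b"), each = n)
  mb <- svm_classifier(blobs, yb, grid = list(C = 2^(0:4), gamma = 2^(-3:1)),
                       seed = 1)
  expect_gte(mb$cv_accuracy, 0.95)
  # self-prediction sanity: training accuracy close to CV accuracy
  expect_gte(mean(predict(mb, blobs) == yb), mb$cv_accuracy - 0.05)
  expect_true(all(predict(mb, blobs) %in% yb))

  xor <- cbind(f1 = rep(c(0, 0, 1, 1), 50) + rnorm(200, 0, 0.1),
               f2 = rep(c(0, 1, 0, 1), 50) + rnorm(200, 0, 0.1))
  yx <- ifelse(xor(rep(c(0, 0, 1, 1), 50) > 0.5,
                   rep(c(0, 1, 0, 1), 50) > 0.5), "pos", "neg")
  mx <- svm_classifier(xor, yx, grid = list(C = 2^(0:6), gamma = 2^(-2:2)),
                       seed = 2)
  expect_gte(mean(predict(mx, xor) == yx), 0.9)
  # brute-force linear baseline: no linear rule beats chance by much
  lin <- e1071::svm(xor, factor(yx), kernel = "linear", cost = 1)
  expect_lte(mean(predict(lin, xor) == yx), 0.65)
})

test_that("hyperparameter selection is deterministic and leak-free", {
  set.seed(34)
  X <- matrix(rnorm(300), 75, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b", "c"), each = 25)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "c", 2] <- X[y == "c", 2] + 2
  g <- list(C = 2^c(-1, 3, 7), gamma = 2^c(-5, -1))
  m1 <- svm_classifier(X, y, grid = g, seed = 9)
  m2 <- svm_classifier(X, y, grid = g, seed = 9)
  expect_identical(c(m1$C, m1$gamma, m1$cv_accuracy),
                   c(m2$C, m2$gamma, m2$cv_accuracy))
  # normalization statistics recompute exactly from the training rows
  expect_equal(m1$center, colMeans(X))
  expect_equal(m1$scale, apply(X, 2, sd))
  # selected hyperparameters come from the searched grid
  expect_true(m1$C %in% g$C && m1$gamma %in% g$gamma)
  # duplicated rows predict identically
  p <- predict(m1, X[c(1, 1), ])
  expect_equal(p[1], p[2])
  expect_error(predict(m1, X[, 1:3]), "f4")
  expect_warning(svm_classifier(X[1:11, ], c(rep("a", 8), rep("b", 3)),
                                grid = g, seed = 1),
                 "reducing folds")
})

test_that("split protocols produce disjoint, reproducible folds", {
  df <- data.frame(histotype = rep(histotype_levels(), times = c(40, 30, 20, 10)),
                   case_id = paste0("case", rep(1:22, length.out = 100)))
  s1 <- make_splits(df, "random_cell_70_30", seed = 5)
  expect_length(s1, 5)
  for (sp in s1) {
    expect_equal(length(sp$train), 70)
    expect_equal(length(sp$test), 30)
    expect_length(intersect(sp$train, sp$test), 0)
    # stratification: class shares preserved in the training set
    expect_equal(unname(table(df$histotype[sp$train])[histotype_levels()]),
                 c(28, 21, 14, 7), ignore_attr = TRUE)
  }
  expect_identical(make_splits(df, "random_cell_70_30", seed = 5), s1)

  s2 <- make_splits(df, "leave_one_case_out_21_1", repetitions = 10, seed = 5)
  test_cases <- vapply(s2, `[[`, character(1), "test_case")
  expect_length(unique(test_cases), 10)
  for (sp in s2) {
    expect_length(unique(df$case_id[sp$test]), 1)
    expect_length(intersect(df$case_id[sp$train], df$case_id[sp$test]), 0)
  }
  expect_error(make_splits(df[0, ], "random_cell_70_30"), "empty")
})
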