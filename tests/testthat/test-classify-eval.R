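# Discriminant classification and evaluation: splitting, Box's M,
# generalized distances, stepwise selection, baselines, metrics.

test_that("stratified split respects class proportions and the seed", {
  ids <- sprintf("S%03d", 1:246)
  labels <- rep(c("healthy", "disease"), c(52, 194))
  sp <- split_train_test(ids, labels, fraction = 0.5, seed = 9)
  train_lab <- labels[match(sp$train, ids)]
  expect_identical(sum(train_lab == "healthy"), 26L)
  expect_identical(sum(train_lab == "disease"), 97L)
  expect_identical(sort(c(sp$train, sp$test)), sort(ids))
  sp2 <- split_train_test(ids, labels, fraction = 0.5, seed = 9)
  expect_identical(sp, sp2)
  expect_error(split_train_test(ids, labels, fraction = 1.0), "between")
  expect_error(split_train_test(ids[1:3], c("healthy", "disease", "disease"),
                                0.5, 1), "at least 2")
})

test_that("Box's M is zero for identical covariances and rejects inflated ones", {
  set.seed(41)
  x1 <- matrix(rnorm(600), ncol = 3)
  y <- factor(rep(c("a", "b"), each = 200))
  same <- box_m_test(rbind(x1, x1), y)
  expect_equal(same$m, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
  x2 <- matrix(rnorm(600, sd = 3), ncol = 3)
  diff <- box_m_test(rbind(x1, x2), y)
  expect_lt(diff$p_value, 0.001)
  expect_error(box_m_test(rbind(x1[1:2, ], x2[1:2, ]), y[c(1:2, 201:202)]),
               "more observations")
})

test_that("generalized squared distance matches hand-computed cases", {
  expect_equal(generalized_distance(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(generalized_distance(c(2, 0), c(1, 0), diag(2)), 1)
  expect_equal(generalized_distance(c(0, 0), c(0, 0), diag(4, 2),
                                    per_class = TRUE), log(16))
  # affine invariance in pooled mode: D2(Ax; Am, A S A') == D2(x; m, S)
  set.seed(50)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3, 3); A <- A + 3 * diag(3)
    S <- crossprod(matrix(rnorm(30), 10, 3)) / 9
    x <- rnorm(3); m <- rnorm(3)
    expect_equal(generalized_distance(as.vector(A %*% x), as.vector(A %*% m),
                                      A %*% S %*% t(A)),
                 generalized_distance(x, m, S), tolerance = 1e-6)
  }
})

test_that("stepwise selection finds a planted feature and shuns collinear ones", {
  set.seed(60)
  n <- 100
  x <- matrix(rnorm(2 * n * 21), 2 * n, 21,
              dimnames = list(NULL, paste0("V", 1:21)))
  x[, 1] <- x[, 1] + rep(c(0, 2), each = n)
  y <- factor(rep(c("h", "d"), each = n))
  sel <- stepwise_select(x, y)
  expect_identical(sel[1], "V1")
  # an exact duplicate of an entered variable never enters
  x2 <- cbind(x, V1dup = x[, 1])
  sel2 <- stepwise_select(x2, y)
  expect_false(all(c("V1", "V1dup") %in% sel2))
  expect_error(stepwise_select(x, y, slentry = 0), "0, 1")
})

test_that("pure-noise features are selected only at the nominal false-positive rate", {
  set.seed(61)
  n_sel <- replicate(20, {
    x <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, paste0("N", 1:20)))
    y <- factor(rep(c("h", "d"), each = 100))
    suppressWarnings(length(stepwise_select(x, y, slentry = 0.05,
                                            slstay = 0.05)))
  })
  expect_lt(mean(n_sel), 3)
})

test_that("pooled-mode SDA reproduces the closed-form linear discriminant", {
  set.seed(62)
  for (i in 1:10) {
    p <- sample(2:4, 1); n <- 60
    mu <- rnorm(p)
    xa <- matrix(rnorm(n * p), n, p)
    xb <- sweep(matrix(rnorm(n * p), n, p), 2, mu + 1, "+")
    x <- rbind(xa, xb); colnames(x) <- paste0("f", 1:p)
    y <- factor(rep(c("healthy", "disease"), each = n),
                levels = c("healthy", "disease"))
    m <- train_sda(x, y, stepwise = FALSE, homogeneity_alpha = 1e-9)
    expect_identical(m$cov_mode, "pooled")
    expect_true(all(m$g1 == 0))
    S <- ((n - 1) * cov(xa) + (n - 1) * cov(xb)) / (2 * n - 2)
    w <- solve(S, colMeans(xb) - colMeans(xa))
    mid <- (colMeans(xa) + colMeans(xb)) / 2
    margin <- sweep(x, 2, mid) %*% w
    keep <- abs(margin) > 1e-6   # decisions equal off the exact boundary
    oracle <- ifelse(margin > 0, "disease", "healthy")
    expect_identical(as.character(predict(m, x))[keep], oracle[keep])
  }
})

test_that("strongly unequal class covariances switch the model to per-class mode", {
  set.seed(63)
  xa <- matrix(rnorm(300 * 2, sd = 1), 300, 2)
  xb <- matrix(rnorm(300 * 2, sd = 3), 300, 2)
  x <- rbind(xa, xb); colnames(x) <- c("u", "v")
  y <- factor(rep(c("healthy", "disease"), each = 300),
              levels = c("healthy", "disease"))
  m <- train_sda(x, y, stepwise = FALSE)
  expect_identical(m$cov_mode, "per_class")
  expect_equal(unname(m$g1["disease"]),
               determinant(cov(xb), TRUE)$modulus[1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("baselines separate separable data and are seed-deterministic", {
  set.seed(64)
  x <- rbind(matrix(rnorm(80, sd = 0.3), 40, 2),
             matrix(rnorm(80, mean = 3, sd = 0.3), 40, 2))
  colnames(x) <- c("a", "b")
  y <- factor(rep(c("healthy", "disease"), each = 40),
              levels = c("healthy", "disease"))
  svm_fit <- train_svm_baseline(x, y, seed = 2)
  expect_identical(as.character(predict(svm_fit, x)), as.character(y))
  svm_fit2 <- train_svm_baseline(x, y, seed = 2)
  expect_identical(attr(svm_fit, "tuning"), attr(svm_fit2, "tuning"))
  llr_fit <- train_llr_baseline(x, y, seed = 2)
  pred <- predict(llr_fit, x, s = "lambda.min", type = "class")
  expect_identical(as.character(pred), as.character(y))
})

test_that("evaluation metrics follow the confusion-table identities", {
  perfect <- evaluate_predictions(rep(c("healthy", "disease"), 5),
                                  rep(c("healthy", "disease"), 5))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  truth <- rep(c("disease", "healthy"), c(10, 10))
  pred <- c(rep("disease", 9), "healthy", rep("healthy", 8), "disease",
            "disease")
  r <- evaluate_predictions(pred, truth)
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$accuracy, 0.85)
  allpos <- evaluate_predictions(rep("disease", 20), truth)
  expect_equal(c(allpos$sensitivity, allpos$specificity), c(1, 0))
  set.seed(65)
  for (i in 1:10) {
    t2 <- sample(c("healthy", "disease"), 30, replace = TRUE)
    p2 <- sample(c("healthy", "disease"), 30, replace = TRUE)
    r2 <- evaluate_predictions(p2, t2)
    cm <- r2$confusion
    expect_equal(r2$accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("model and report serialization round-trips preserve behaviour", {
  set.seed(66)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  x[51:100, 1] <- x[51:100, 1] + 2
  y <- factor(rep(c("healthy", "disease"), each = 50),
              levels = c("healthy", "disease"))
  m <- train_sda(x, y, stepwise = FALSE)
  td <- withr::local_tempdir()
  m2 <- read_sda_model(write_sda_model(m, file.path(td, "m.json")))
  newx <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict(m, newx), predict(m2, newx))
  expect_equal(m$class_means, m2$class_means, tolerance = 1e-12)

  r <- evaluate_predictions(predict(m, x), y, method = "SDA")
  r2 <- read_report(write_report(r, file.path(td, "r.json")))
  expect_equal(r$confusion, r2$confusion, ignore_attr = TRUE)
  expect_identical(r$accuracy, r2$accuracy)
})

test_that("the end-to-end pipeline is reproducible and beats chance", {
  co <- small_cohort(nh = 8, nd = 12, nb = 60, seed = 5)
  r1 <- classify_cohort(co, "quantile", use_pca = TRUE, method = "sda",
                        seed = 5)
  r2 <- classify_cohort(co, "quantile", use_pca = TRUE, method = "sda",
                        seed = 5)
  expect_identical(r1$confusion, r2$confusion)
  expect_gt(r1$accuracy, 0.6)
  cmp <- run_comparison(co, methods = "sda", seed = 5)
  expect_identical(nrow(cmp), 4L)
  expect_true(all(cmp$accuracy >= 0 & cmp$accuracy <= 1))
})
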