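test_that("standardization centres by the reference and drops constants", {
  withr::local_seed(1)
  x <- matrix(rnorm(60, mean = 5, sd = 2), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize_features(x)
  expect_equal(unname(colMeans(st$reference)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(st$reference, 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  # constant column dropped and logged
  x2 <- cbind(x, k = 7)
  st2 <- standardize_features(x2)
  expect_equal(st2$dropped, "k")
  expect_equal(ncol(st2$reference), 3L)
  # held-out row transformed with training statistics: closed form
  new <- matrix(c(10, 0, 3), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  st3 <- standardize_features(x, new)
  expect_equal(as.numeric(st3$newdata),
               unname((c(10, 0, 3) - colMeans(x)) / apply(x, 2, sd)),
               tolerance = 1e-12)
  # missing values imputed by the reference mean (-> 0 after scaling)
  xm <- x; xm[3, 2] <- NA
  stm <- standardize_features(xm, matrix(c(1, NA, 1), 1, 3))
  expect_equal(stm$n_imputed, 2L)
  expect_equal(stm$newdata[1, 2], 0, ignore_attr = TRUE)
})

test_that("the Rprop perceptron separates linearly separable groups", {
  withr::local_seed(4)
  x <- matrix(c(rnorm(10, -1, 0.2), rnorm(10, 1, 0.2)), ncol = 1)
  y <- rep(c("lo", "hi"), each = 10)
  fit <- train_perceptron(x, y, perceptron_spec(seed = 9))
  expect_equal(as.character(predict(fit, x)), y)
  expect_true(fit$epochs <= 1000)
  # identical inputs for both labels cannot beat chance systematically
  xid <- matrix(rep(c(0.3, -0.2), 10), ncol = 2, byrow = TRUE)
  yid <- rep(c("A", "B"), each = 5)
  accs <- vapply(1:10, function(s) {
    f <- train_perceptron(xid, yid, perceptron_spec(seed = s))
    mean(as.character(predict(f, xid)) == yid)
  }, 1)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("high-dimensional separable groups reach zero training error", {
  withr::local_seed(11)
  n <- 12
  x <- rbind(matrix(rnorm(n * 204), n, 204),
             matrix(rnorm(n * 204), n, 204))
  x[(n + 1):(2 * n), 1:20] <- x[(n + 1):(2 * n), 1:20] + 2
  y <- rep(c("ctl", "trt"), each = n)
  st <- standardize_features(x)
  fit <- train_perceptron(st$reference, y, perceptron_spec(seed = 2))
  expect_equal(mean(as.character(predict(fit, st$reference)) == y), 1)
  expect_lt(fit$epochs, 1000)
  # independent linear-separability oracle on the same data
  or <- nnet::multinom(factor(y) ~ st$reference, trace = FALSE, maxit = 500)
  expect_equal(mean(predict(or) == y), 1)
})

test_that("training is bit-reproducible for a fixed seed", {
  withr::local_seed(3)
  x <- matrix(rnorm(80), 20, 4)
  y <- rep(c("A", "B"), 10)
  f1 <- train_perceptron(x, y, perceptron_spec(seed = 77))
  f2 <- train_perceptron(x, y, perceptron_spec(seed = 77))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$loss, f2$loss)
  cv1 <- cross_validate(x, y, perceptron_spec(seed = 5))
  cv2 <- cross_validate(x, y, perceptron_spec(seed = 5))
  expect_identical(cv1$confusion, cv2$confusion)
})

test_that("chi-squared recognition test matches the reference oracle", {
  m <- matrix(c(19, 6, 11, 14), 2, 2, byrow = TRUE)
  got <- chi_square_recognition(m)
  # independent reference: per-row goodness-of-fit against uniform chance
  ref_stat <- sum(vapply(1:2, function(i) {
    suppressWarnings(chisq.test(m[i, ], p = c(0.5, 0.5))$statistic)
  }, 1))
  expect_equal(got$statistic, unname(ref_stat), tolerance = 1e-12)
  expect_equal(got$df, 2L)
  expect_equal(got$p_value, pchisq(ref_stat, 2, lower.tail = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # chance-level confusion: statistic 0, p 1
  even <- matrix(c(10, 10, 7, 7), 2, 2, byrow = TRUE)
  expect_equal(chi_square_recognition(even)$statistic, 0)
  expect_equal(chi_square_recognition(even)$p_value, 1)
  # doubling counts doubles the statistic
  expect_equal(chi_square_recognition(2 * m)$statistic, 2 * got$statistic)
  expect_error(chi_square_recognition(matrix(c(0, 0, 3, 2), 2, 2,
                                             byrow = TRUE)),
               "zero counts")
})

test_that("LOO cross-validation recognises perfectly separated groups", {
  withr::local_seed(21)
  x <- rbind(matrix(rnorm(8 * 5, 0), 8, 5), matrix(rnorm(8 * 5, 6), 8, 5))
  y <- rep(c("ctl", "trt"), each = 8)
  res <- cross_validate(x, y, perceptron_spec(seed = 1))
  expect_equal(unname(diag(res$recognition_pct)), c(100, 100))
  expect_equal(unname(rowSums(res$recognition_pct)), c(100, 100))
  expect_equal(unname(rowSums(res$confusion)), c(8L, 8L))
  expect_lt(res$chi2_p, 0.01)
  # tidiers
  td <- tidy(res)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$n), 16L)
  gl <- glance(res)
  expect_equal(gl$accuracy, 1)
  expect_equal(gl$folds, "leave-one-out")
})

test_that("fold hygiene: the held-out sample never shapes the scaling", {
  withr::local_seed(31)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("A", "B"), 10)
  x[1, ] <- c(1e6, -1e6)  # gross outlier
  # manual fold 1: training statistics must exclude row 1
  st <- standardize_features(x[-1, , drop = FALSE], x[1, , drop = FALSE])
  expect_equal(st$center, colMeans(x[-1, ]), ignore_attr = TRUE)
  expect_true(all(abs(st$reference) < 10))
  expect_true(all(abs(st$newdata) > 100))
})

test_that("k-fold assignment is label-balanced and complete", {
  withr::local_seed(8)
  x <- matrix(rnorm(240), 24, 10)
  y <- rep(c("A", "B"), each = 12)
  res <- cross_validate(x, y, perceptron_spec(seed = 3), folds = 4)
  expect_equal(sum(res$confusion), 24)
  expect_equal(res$folds, "4-fold")
})

test_that("recognition table export mirrors the confusion structure", {
  withr::local_seed(2)
  x <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 5), 6, 2))
  res <- cross_validate(x, rep(c("control", "treatment"), each = 6),
                        perceptron_spec(seed = 4))
  path <- file.path(withr::local_tempdir(), "recognition.csv")
  out <- write_recognition_table(res, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(tab$group, c("control", "treatment"))
  expect_equal(tab$pct_recognized_as_control[1] +
                 tab$pct_recognized_as_treatment[1], 100)
  expect_true(all(c("n", "chi2_p") %in% names(tab)))
})
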