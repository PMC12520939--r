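test_that("autoscaling centers and scales with the sample convention", {
  sc <- autoscale(cbind(a = c(1, 3), b = c(5, 5)))
  expect_equal(unname(sc$X[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(sc$X[, "b"]), c(0, 0))     # constant column
  expect_equal(unname(sc$sds["b"]), 1)
  # applying the stored scaler reproduces the fit
  expect_equal(apply_scaler(sc, cbind(c(1, 3), c(5, 5))),
               unname(sc$X), tolerance = 1e-12)
  expect_error(autoscale(matrix(1, 1, 2)), "2 rows")
})

test_that("with no orthogonal components the fit is exactly PLS2-DA", {
  fx <- make_sep_features(3, 15, 2.5, seed = 4)
  sc <- autoscale(fx$X)
  model <- fit_oplsda(sc, fx$labels, A_pred = 2, A_ortho = 0)
  pred <- predict_oplsda(model, fx$X)
  oracle_Y <- pls2da_oracle_predict(sc$X, fx$labels, A = 2)
  expect_lt(max(abs(pred$predicted_Y - oracle_Y)), 1e-9)
})

test_that("orthogonal scores are uncorrelated with every dummy column", {
  fx <- make_sep_features(3, 20, 2, p = 6, seed = 9)
  model <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2,
                      A_ortho = 2)
  Y <- outer(fx$labels, model$class_labels, "==") * 1
  Yc <- scale(Y, scale = FALSE)
  for (j in seq_len(ncol(model$T_ortho)))
    expect_lt(max(abs(cor(model$T_ortho[, j], Yc))), 1e-8)
  # weight columns are unit norm
  expect_equal(unname(colSums(model$W_pred^2)), rep(1, 2),
               tolerance = 1e-9)
  expect_equal(unname(colSums(model$W_ortho^2)), rep(1, 2),
               tolerance = 1e-9)
})

test_that("orthogonal deflation conserves sum of squares", {
  fx <- make_sep_features(3, 20, 2, p = 6, seed = 2)
  sc <- autoscale(fx$X)
  model <- fit_oplsda(sc, fx$labels, A_pred = 2, A_ortho = 2)
  ss_in <- sum(sc$X^2)
  ss_f <- sum(model$X_filtered^2)
  ss_o <- sum((model$T_ortho %*% t(model$P_ortho))^2)
  expect_lt(abs(ss_in - (ss_f + ss_o)) / ss_in, 1e-6)
})

test_that("a class contrast on one feature concentrates the weight there", {
  withr::with_seed(12, {
    n <- 40
    X <- matrix(rnorm(2 * n * 5), 2 * n, 5)
    X[1:n, 1] <- X[1:n, 1] + 4
    labels <- rep(c("pos", "neg"), each = n)
  })
  model <- fit_oplsda(autoscale(X), labels, A_pred = 1, A_ortho = 1)
  w <- model$W_pred[, 1]
  expect_gt(abs(w[1]), 0.95)
})

test_that("separable classes are classified perfectly in training", {
  fx <- make_sep_features(3, 12, 4, seed = 6)
  model <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2,
                      A_ortho = 1)
  pred <- predict_oplsda(model, fx$X)
  expect_equal(pred$predicted_label, fx$labels)
  # a sample at a class's raw feature mean is assigned to that class
  for (cl in unique(fx$labels)) {
    mu <- colMeans(fx$X[fx$labels == cl, , drop = FALSE])
    expect_equal(predict_oplsda(model, matrix(mu, 1))$predicted_label, cl)
  }
  # training predictions equal training-score argmax assignments
  Yhat_train <- model$T_pred %*% t(model$C)
  Yhat_train <- sweep(Yhat_train, 2, model$y_means, "+")
  expect_equal(pred$predicted_label,
               model$class_labels[max.col(Yhat_train,
                                          ties.method = "first")])
})

test_that("predictions are invariant to a consistent feature permutation", {
  fx <- make_sep_features(3, 10, 3, seed = 8)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2, A_ortho = 1)
  m2 <- fit_oplsda(autoscale(fx$X[, perm]), fx$labels, A_pred = 2,
                   A_ortho = 1)
  p1 <- predict_oplsda(m1, fx$X)
  p2 <- predict_oplsda(m2, fx$X[, perm])
  expect_equal(p1$predicted_label, p2$predicted_label)
  expect_equal(p1$predicted_Y, p2$predicted_Y, tolerance = 1e-9)
})

test_that("relabeling classes permutes predictions consistently", {
  fx <- make_sep_features(3, 10, 3, seed = 5)
  ren <- c(class1 = "zeta", class2 = "alpha", class3 = "mid")
  m1 <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2, A_ortho = 1)
  m2 <- fit_oplsda(autoscale(fx$X), unname(ren[fx$labels]), A_pred = 2,
                   A_ortho = 1)
  p1 <- predict_oplsda(m1, fx$X)$predicted_label
  p2 <- predict_oplsda(m2, fx$X)$predicted_label
  expect_equal(unname(ren[p1]), p2)
})

test_that("scores-plot coordinates use predictive then orthogonal axes", {
  fx <- make_sep_features(3, 10, 4, seed = 3)
  m2 <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2, A_ortho = 1)
  sp <- scores_plot_data(m2, fx$labels)
  expect_equal(sp$score1, m2$T_pred[, 1])
  expect_equal(sp$score2, m2$T_pred[, 2])
  # pairwise distinct class centroids on the separable fixture
  cent <- aggregate(cbind(score1, score2) ~ class, sp, mean)
  d <- as.matrix(dist(cent[, 2:3]))
  expect_gt(min(d[upper.tri(d)]), 1)

  m1 <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 1, A_ortho = 1)
  sp1 <- scores_plot_data(m1)
  expect_equal(sp1$score2, m1$T_ortho[, 1])
})

test_that("degenerate inputs raise the documented errors", {
  fx <- make_sep_features(2, 5, 3, seed = 1)
  expect_error(fit_oplsda(autoscale(fx$X), rep("one", 10)), "2 classes")
  expect_error(fit_oplsda(autoscale(fx$X),
                          c("a", fx$labels[-1])), "at least 2 samples")
  expect_error(fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 3),
               "rank-error")
  m <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 1, A_ortho = 1)
  expect_error(predict_oplsda(m, fx$X[, 1:3]), "column count")
})

test_that("model JSON round-trips to identical predictions", {
  fx <- make_sep_features(3, 10, 2, seed = 7)
  model <- fit_oplsda(autoscale(fx$X), fx$labels, A_pred = 2,
                      A_ortho = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_oplsda_json(model, path)
  back <- read_oplsda_json(path)
  p1 <- predict_oplsda(model, fx$X)
  p2 <- predict_oplsda(back, fx$X)
  expect_equal(p1$predicted_label, p2$predicted_label)
  expect_equal(p1$predicted_Y, p2$predicted_Y, tolerance = 1e-12)
})
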