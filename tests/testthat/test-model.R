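test_that("make_folds deals near-equal, stratified, deterministic folds", {
  y100 <- rep(letters[1:4], 25)
  f <- make_folds(y100, n = 10, seed = 3)
  expect_equal(unname(table(f)), rep(10L, 10), ignore_attr = TRUE)
  y95 <- rep(letters[1:5], 19)
  f95 <- make_folds(y95, n = 10, seed = 3)
  expect_setequal(as.integer(table(f95)), c(9L, 10L))
  # stratification balances classes where sizes permit
  f_str <- make_folds(y100, n = 5, seed = 3, stratified = TRUE)
  per_class <- table(y100, f_str)
  expect_true(all(per_class == 5L))
  # determinism
  expect_identical(make_folds(y100, n = 10, seed = 7),
                   make_folds(y100, n = 10, seed = 7))
  expect_error(make_folds(letters[1:5], n = 10), "more folds")
})

test_that("train_svm separates toy clouds and errors on bad input", {
  toy <- toy_clouds(20, list(a = c(0, 0), b = c(4, 4)))
  m <- train_svm(toy$x, toy$y, kernel_params(1, 0.5), seed = 1)
  expect_equal(mean(predict(m, toy$x, type = "class") == toy$y), 1)
  # duplicating every training point leaves predictions unchanged
  m2 <- train_svm(rbind(toy$x, toy$x), c(toy$y, toy$y),
                  kernel_params(1, 0.5), seed = 1)
  expect_equal(predict(m2, toy$x, type = "vote"),
               predict(m, toy$x, type = "vote"))
  expect_error(train_svm(toy$x, rep("a", nrow(toy$x)),
                         kernel_params(1, 0.5)), "single class")
  expect_error(train_svm(toy$x, toy$y[-1], kernel_params(1, 0.5)),
               "mismatch")
  expect_error(predict(m, toy$x[, 1, drop = FALSE]), "mismatch")
})

test_that("SMO solution matches the exact quadprog dual on small problems", {
  skip_if_not_installed("quadprog")
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 16
      xx <- matrix(rnorm(n * 2), n)
      yy <- ifelse(xx[, 1] + xx[, 2] + rnorm(n, 0, 0.5) > 0, 1L, -1L)
      if (length(unique(yy)) < 2) next
      g <- runif(1, 0.1, 2)
      C <- sample(c(0.5, 2, 8), 1)
      K <- exp(-g * as.matrix(dist(xx))^2)
      Q <- (yy %o% yy) * K
      fit <- peploc:::smo_train(K, yy, C)
      qp <- quadprog::solve.QP(Q + diag(1e-8, n), rep(1, n),
                               cbind(yy, diag(n), -diag(n)),
                               c(0, rep(0, n), rep(-C, n)), meq = 1)
      obj_smo <- fit$obj
      obj_qp <- 0.5 * drop(t(qp$solution) %*% Q %*% qp$solution) -
        sum(qp$solution)
      expect_equal(obj_smo, obj_qp, tolerance = 1e-4)
      # decision values agree (rho from free SVs)
      u_smo <- drop(K %*% (fit$alpha * yy)) - fit$rho
      sv <- which(qp$solution > 1e-6 & qp$solution < C - 1e-6)
      if (length(sv)) {
        rho_qp <- mean(drop(K %*% (qp$solution * yy))[sv] - yy[sv])
        u_qp <- drop(K %*% (qp$solution * yy)) - rho_qp
        expect_equal(sign(u_smo[abs(u_smo) > 1e-3]),
                     sign(u_qp[abs(u_smo) > 1e-3]))
      }
    }
  })
})

test_that("probabilities are normalized, argmax-consistent, permutation-equivariant", {
  toy <- toy_clouds(15, list(a = c(0, 0), b = c(4, 0), c = c(0, 4)))
  m <- train_svm(toy$x, toy$y, kernel_params(4, 0.5), seed = 2)
  pr <- predict(m, toy$x, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0 & pr <= 1))
  # a point deep inside a cloud gets that class
  deep <- matrix(c(0, 0, 4, 0, 0, 4), ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("f1", "f2")))
  pd <- predict(m, deep, type = "prob")
  expect_equal(colnames(pd)[max.col(pd)], c("a", "b", "c"))
  # relabeling classes permutes probability columns (up to the calibration
  # folds' dependence on class order, as in the reference implementation)
  relab <- c(a = "z", b = "y", c = "x")
  m2 <- train_svm(toy$x, unname(relab[toy$y]), kernel_params(4, 0.5),
                  seed = 2)
  pr2 <- predict(m2, deep, type = "prob")
  expect_equal(unname(pr2[, relab]), unname(pd), tolerance = 0.02)
  expect_equal(max.col(pr2[, relab]), max.col(pd))
  # predict_proba on a single named vector
  p1 <- predict_proba(m, c(f1 = 0, f2 = 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_equal(names(which.max(p1)), "a")
})

test_that("grid_search equals an exhaustive double-loop oracle and breaks ties", {
  toy <- toy_clouds(10, list(a = c(0, 0), b = c(3, 3), c = c(0, 3)))
  y <- toy$y
  folds <- make_folds(y, n = 3, seed = 5)
  grid <- default_grid(C = c(0.5, 8), gamma = c(0.05, 1))
  gs <- grid_search(toy$x, y, folds, grid)
  # independent oracle: plain double loop over grid points and folds using
  # only train_svm/predict on raw submatrices
  oracle_acc <- vapply(grid, function(par) {
    accs <- vapply(1:3, function(f) {
      tr <- folds != f
      scaler <- peploc:::scaler_fit(peploc:::as_sparse(toy$x))
      xs <- peploc:::scaler_apply(peploc:::as_sparse(toy$x), scaler)
      K <- exp(-par$gamma * peploc:::sq_dist(xs, xs))
      machines <- peploc:::ovo_train_kernel(K[tr, tr], y[tr],
                                            sort(unique(y)), par$C)
      dec <- vapply(machines, function(m) {
        as.numeric(K[!tr, which(tr)[m$idx], drop = FALSE] %*% m$coef) - m$rho
      }, numeric(sum(!tr)))
      pred <- peploc:::ovo_vote(machines, matrix(dec, nrow = sum(!tr)),
                                sort(unique(y)))
      c(sum(pred == y[!tr]), sum(!tr))
    }, numeric(2))
    sum(accs[1, ]) / sum(accs[2, ])
  }, numeric(1))
  expect_equal(gs$table$accuracy, oracle_acc, tolerance = 1e-12)
  best_oracle <- grid[[order(-oracle_acc,
                             vapply(grid, `[[`, numeric(1), "C"),
                             vapply(grid, `[[`, numeric(1), "gamma"))[1]]]
  expect_equal(gs$best, best_oracle)
  # one-point grid returns that point
  one <- grid_search(toy$x, y, folds, list(kernel_params(2, 0.1)))
  expect_equal(one$best, kernel_params(2, 0.1))
  # equal accuracies -> smaller C, then smaller gamma
  all_tied <- grid_search(toy$x, y, folds,
                          default_grid(C = c(1, 4), gamma = c(0.2, 0.4)))
  tab <- all_tied$table
  top <- tab[tab$accuracy == max(tab$accuracy), ]
  expect_equal(all_tied$best$C, min(top$C))
})

test_that("nested_evaluate recovers planted signal, is deterministic, no scaler leak", {
  cfg <- synthetic_config(classes = c("chl", "mit", "nuc"), n_per_class = 12,
                          signal_strength = 1, seed = 5)
  ds <- generate_dataset(cfg)
  reg <- build_feature_registry()
  grid <- default_grid(C = c(1, 32), gamma = c(0.01, 0.5))
  res <- nested_evaluate(ds, reg$comp_ungrouped_k1, grid = grid, seed = 5,
                         n_outer = 4, n_inner = 3)
  expect_gte(res$aggregate$acc_mean, 90)
  res2 <- nested_evaluate(ds, reg$comp_ungrouped_k1, grid = grid, seed = 5,
                          n_outer = 4, n_inner = 3)
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$aggregate, res2$aggregate)
  # per-fold metric tables carry fold accuracy
  expect_length(res$per_fold, 4L)
  expect_false(is.null(attr(res$per_fold[[1]], "acc")))
})

test_that("scaling parameters are fitted per outer-training fold (no leak)", {
  # heterogeneous data: scaling fitted on different folds must differ
  withr::with_seed(42, {
    x <- matrix(runif(60 * 3) * rep(c(1, 10, 100), each = 60), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    x[31:60, ] <- x[31:60, ] * 5  # second half on a different scale
    y <- rep(c("p", "q"), 30)
  })
  xs <- peploc:::as_sparse(x)
  s_all <- peploc:::scaler_fit(xs)
  s_part <- peploc:::scaler_fit(xs[1:30, ])
  expect_false(isTRUE(all.equal(s_all$min + s_all$range,
                                s_part$min + s_part$range)))
  # train_svm stores a scaler fitted on exactly its training rows
  m <- train_svm(x[1:30, ], y[1:30], kernel_params(1, 0.1),
                 probability = FALSE)
  expect_equal(m$scaler$min, s_part$min)
  expect_equal(m$scaler$range, s_part$range)
})
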