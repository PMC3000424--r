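# Multi-class RBF-kernel maximum-margin classification: one-vs-one
# decomposition over the SMO solver in src/smo.cpp, per-dimension [0,1]
# scaling fitted on training data only, Platt-sigmoid probability
# calibration with internal cross-validated decision values, and
# pairwise-coupled multi-class probabilities.

#' RBF kernel hyperparameters
#' @param C penalty parameter, > 0.
#' @param gamma kernel width of exp(-gamma ||x - y||^2), > 0.
#' @return Object of class `kernel_params`.
#' @export
kernel_params <- function(C, gamma) {
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma), class = "kernel_params")
}

#' Default hyperparameter grid
#'
#' The usual log2 grid: C in 2^(-5), 2^(-3), ..., 2^15 and gamma in
#' 2^(-15), 2^(-13), ..., 2^3.  `coarse = TRUE` thins both axes to every
#' second point (a compute-budget option for tests and small studies).
#'
#' @param C,gamma numeric vectors of candidate values.
#' @param coarse use the thinned grid.
#' @return List of `kernel_params`, ordered by C then gamma (the
#'   tie-breaking order of [grid_search()]).
#' @export
default_grid <- function(C = 2^seq(-5, 15, by = 2),
                         gamma = 2^seq(-15, 3, by = 2),
                         coarse = FALSE) {
  if (coarse) {
    C <- C[seq(1, length(C), by = 2)]
    gamma <- gamma[seq(1, length(gamma), by = 2)]
  }
  grid <- list()
  for (cc in sort(C)) {
    for (g in sort(gamma)) grid[[length(grid) + 1L]] <- kernel_params(cc, g)
  }
  grid
}

# ---- scaling --------------------------------------------------------------

scaler_fit <- function(x) {
  # per-dimension affine map to [0, 1], implicit zeros included
  n <- nrow(x)
  nnz <- diff(x@p)
  mins <- numeric(ncol(x))
  maxs <- numeric(ncol(x))
  if (length(x@x)) {
    grp <- rep.int(seq_len(ncol(x)), nnz)
    mins_nz <- vapply(split(x@x, factor(grp, levels = seq_len(ncol(x)))),
                      function(v) if (length(v)) min(v) else Inf, numeric(1))
    maxs_nz <- vapply(split(x@x, factor(grp, levels = seq_len(ncol(x)))),
                      function(v) if (length(v)) max(v) else -Inf, numeric(1))
    has_zero <- nnz < n
    mins <- ifelse(has_zero, pmin(0, mins_nz), mins_nz)
    maxs <- ifelse(has_zero, pmax(0, maxs_nz), maxs_nz)
    mins[!is.finite(mins)] <- 0
    maxs[!is.finite(maxs)] <- 0
  }
  range <- maxs - mins
  range[range == 0] <- 1  # constant dimensions map to 0
  list(min = mins, range = range, keys = colnames(x))
}

scaler_apply <- function(x, scaler) {
  stopifnot(ncol(x) == length(scaler$min))
  out <- x %*% Matrix::Diagonal(x = 1 / scaler$range)
  shift_cols <- which(scaler$min != 0)
  if (length(shift_cols)) {
    dense <- as.matrix(out[, shift_cols, drop = FALSE])
    dense <- sweep(dense, 2, scaler$min[shift_cols] / scaler$range[shift_cols])
    out <- as.matrix(out)
    out[, shift_cols] <- dense
    out <- methods::as(Matrix::Matrix(out, sparse = TRUE), "CsparseMatrix")
  } else {
    out <- methods::as(out, "CsparseMatrix")
  }
  dimnames(out) <- dimnames(x)
  out
}

# squared Euclidean distances between rows of a and rows of b (dense result)
sq_dist <- function(a, b = a) {
  ra <- Matrix::rowSums(a^2)
  rb <- Matrix::rowSums(b^2)
  d <- outer(as.numeric(ra), as.numeric(rb), "+") -
    2 * as.matrix(Matrix::tcrossprod(a, b))
  pmax(d, 0)
}

rbf_kernel <- function(d2, gamma) exp(-gamma * d2)

# ---- Platt sigmoid and pairwise coupling ----------------------------------

# Fit P(y = 1 | f) = 1 / (1 + exp(A f + B)) by regularized maximum
# likelihood (Platt's method with the Lin-Weng numerical fixes).
sigmoid_fit <- function(dec, pos) {
  prior1 <- sum(pos)
  prior0 <- sum(!pos)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(pos, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  sigma <- 1e-12
  fval <- {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  for (it in seq_len(100)) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sigma + sum(dec * dec * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    repeat {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      fApB <- dec * newA + newB
      newf <- sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
                         (t - 1) * fApB + log1p(exp(fApB))))
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) break
    }
    if (stepsize < 1e-10) break
  }
  c(A = A, B = B)
}

sigmoid_predict <- function(dec, ab) {
  fApB <- dec * ab[["A"]] + ab[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# Couple pairwise probabilities r[i, j] = P(class i | i or j) into a
# multi-class distribution (Wu, Lin & Weng's second method).
couple_probabilities <- function(r) {
  k <- nrow(r)
  if (k == 2L) return(c(r[1, 2], r[2, 1]) / sum(c(r[1, 2], r[2, 1])))
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) {
      if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
    }
  }
  p <- rep(1 / k, k)
  eps <- 0.005 / k
  for (it in seq_len(100)) {
    Qp <- as.numeric(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[t, ]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

# ---- one-vs-one training on a precomputed kernel --------------------------

class_pairs <- function(classes) {
  k <- length(classes)
  pairs <- list()
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  pairs
}

# Train all one-vs-one binary machines on a precomputed kernel K (rows =
# training samples).  Returns per-pair index sets, coefficients and rho.
ovo_train_kernel <- function(K, y, classes, C, eps = 1e-3,
                             max_iter = 1000000L) {
  lapply(class_pairs(classes), function(pr) {
    idx <- which(y == classes[pr[1]] | y == classes[pr[2]])
    ysub <- ifelse(y[idx] == classes[pr[1]], 1L, -1L)
    fit <- smo_train(K[idx, idx, drop = FALSE], ysub, C, eps = eps,
                     max_iter = max_iter)
    list(pair = pr, idx = idx, y = ysub,
         coef = fit$alpha * ysub, rho = fit$rho)
  })
}

# decision values of every pair machine for test rows; Ktest is m x n_train
ovo_decision <- function(machines, Ktest) {
  dec <- vapply(machines, function(m) {
    as.numeric(Ktest[, m$idx, drop = FALSE] %*% m$coef) - m$rho
  }, numeric(nrow(Ktest)))
  matrix(dec, nrow = nrow(Ktest))
}

ovo_vote <- function(machines, dec, classes) {
  votes <- matrix(0L, nrow(dec), length(classes))
  for (p in seq_along(machines)) {
    pr <- machines[[p]]$pair
    pos <- dec[, p] > 0
    votes[, pr[1]] <- votes[, pr[1]] + pos
    votes[, pr[2]] <- votes[, pr[2]] + !pos
  }
  classes[max.col(votes, ties.method = "first")]
}

# ---- the user-facing model ------------------------------------------------

#' Train a multi-class RBF-kernel SVM
#'
#' Fits the per-dimension [0,1] scaler on the given data, then a one-vs-one
#' multi-class soft-margin classifier with the RBF kernel.  With
#' `probability = TRUE`, a Platt sigmoid is fitted per binary machine on
#' decision values from an internal 5-fold cross-validation, and class
#' probabilities are obtained by pairwise coupling.
#'
#' @param x feature matrix (`dgCMatrix` or matrix; rows = records) with
#'   column names identifying feature keys.
#' @param labels character vector of class labels, one per row.
#' @param params a `kernel_params` object.
#' @param probability fit the probability model (default `TRUE`).
#' @param seed seed for the internal calibration folds.
#' @return Object of class `peploc_svm`.
#' @export
train_svm <- function(x, labels, params, probability = TRUE, seed = 1L) {
  stopifnot(inherits(params, "kernel_params"))
  x <- as_sparse(x)
  if (nrow(x) != length(labels)) stop("dimension mismatch: ", nrow(x),
                                      " rows vs ", length(labels), " labels")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training data contains a single class")
  scaler <- scaler_fit(x)
  xs <- scaler_apply(x, scaler)
  K <- rbf_kernel(sq_dist(xs), params$gamma)
  machines <- ovo_train_kernel(K, labels, classes, params$C)
  if (probability) {
    machines <- fit_platt(machines, xs, K, labels, classes, params, seed)
  }
  structure(list(classes = classes, params = params, scaler = scaler,
                 keys = colnames(x), x = xs, labels = labels,
                 machines = machines, probability = probability,
                 format_version = "peploc-svm-1"),
            class = "peploc_svm")
}

# Platt calibration on cross-validated decision values, per binary machine.
fit_platt <- function(machines, xs, K, y, classes, params, seed,
                      n_cal_folds = 5L) {
  for (p in seq_along(machines)) {
    m <- machines[[p]]
    idx <- m$idx
    pos <- m$y == 1L
    nf <- min(n_cal_folds, length(idx))
    folds <- make_folds(labels = ifelse(pos, "p", "n"), n = nf,
                        seed = seed + p, stratified = TRUE)
    dec <- numeric(length(idx))
    for (f in seq_len(nf)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(unique(pos[tr])) < 2L || !length(te)) {
        dec[te] <- 0
        next
      }
      fit <- smo_train(K[idx[tr], idx[tr], drop = FALSE],
                       ifelse(pos[tr], 1L, -1L), params$C)
      dec[te] <- as.numeric(K[idx[te], idx[tr], drop = FALSE] %*%
                              (fit$alpha * ifelse(pos[tr], 1L, -1L))) -
        fit$rho
    }
    machines[[p]]$platt <- sigmoid_fit(dec, pos)
  }
  machines
}

as_sparse <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(x, "CsparseMatrix")
}

#' Predict classes or probabilities from a trained SVM
#'
#' @param object a `peploc_svm`.
#' @param x feature matrix over the model's feature keys (use
#'   [feature_matrix()] with `keys = object$keys`).
#' @param type `"prob"` for the pairwise-coupled class-probability matrix,
#'   `"class"` for its argmax, `"vote"` for one-vs-one voting labels.
#' @param ... unused.
#' @return Probability matrix (rows sum to 1) or character vector.
#' @export
predict.peploc_svm <- function(object, x, type = c("prob", "class", "vote"),
                               ...) {
  type <- match.arg(type)
  x <- as_sparse(x)
  if (ncol(x) != length(object$keys)) {
    stop("dimension mismatch: model expects ", length(object$keys),
         " features, got ", ncol(x))
  }
  xs <- scaler_apply(x, object$scaler)
  Ktest <- rbf_kernel(sq_dist(xs, object$x), object$params$gamma)
  dec <- ovo_decision(object$machines, Ktest)
  if (type == "vote") return(ovo_vote(object$machines, dec, object$classes))
  if (!object$probability) {
    stop("model was trained without probability estimation")
  }
  k <- length(object$classes)
  probs <- t(vapply(seq_len(nrow(dec)), function(i) {
    r <- matrix(0, k, k)
    for (p in seq_along(object$machines)) {
      pr <- object$machines[[p]]$pair
      rp <- sigmoid_predict(dec[i, p], object$machines[[p]]$platt)
      rp <- min(max(rp, 1e-7), 1 - 1e-7)
      r[pr[1], pr[2]] <- rp
      r[pr[2], pr[1]] <- 1 - rp
    }
    couple_probabilities(r)
  }, numeric(k)))
  colnames(probs) <- object$classes
  rownames(probs) <- rownames(x)
  if (type == "class") {
    return(object$classes[max.col(probs, ties.method = "first")])
  }
  probs
}

#' Class probabilities for a single feature vector
#'
#' @param model a `peploc_svm`.
#' @param vector named numeric feature vector (as from
#'   [extract_features()]); keys outside the model's key set are ignored.
#' @return Named probability vector over the model's classes, summing to 1.
#' @export
predict_proba <- function(model, vector) {
  keys <- model$keys
  v <- setNames(numeric(length(keys)), keys)
  common <- intersect(names(vector), keys)
  v[common] <- vector[common]
  x <- Matrix::Matrix(matrix(v, nrow = 1, dimnames = list(NULL, keys)),
                      sparse = TRUE)
  drop(predict(model, x, type = "prob"))
}

# ---- cross-validation plumbing --------------------------------------------

#' Assign records to cross-validation folds
#'
#' Deals records into `n` folds whose sizes differ by at most one.
#' Stratified mode (the default) shuffles within each class and deals
#' classes consecutively round-robin, so class proportions are balanced per
#' fold as far as class sizes permit; plain mode shuffles the whole set.
#'
#' @param labels class labels (used in stratified mode; any vector of the
#'   right length works for plain mode).
#' @param n number of folds.
#' @param seed RNG seed; same seed, same assignment.
#' @param stratified balance classes across folds.
#' @return Integer vector of fold ids in 1..n, one per record.
#' @export
make_folds <- function(labels, n = 10L, seed = 1L, stratified = TRUE) {
  sz <- length(labels)
  if (n < 2L) stop("need at least 2 folds")
  if (n > sz) stop("more folds (", n, ") than records (", sz, ")")
  withr::with_seed(seed, {
    folds <- integer(sz)
    if (stratified) {
      ord <- unlist(lapply(split(seq_len(sz), labels), sample))
    } else {
      ord <- sample.int(sz)
    }
    folds[ord] <- rep_len(seq_len(n), sz)
    folds
  })
}

#' Grid search for C and gamma by inner cross-validation
#'
#' For every grid point, trains on each inner-fold complement and measures
#' vote-based overall accuracy on the fold; returns the grid point with the
#' highest mean inner accuracy, ties broken by smaller C, then smaller
#' gamma.  The per-dimension scaler is fitted once on all of `x` — which in
#' the nested protocol is outer-training data only.
#'
#' Inner-loop fits use a relaxed SMO stopping tolerance (`eps`, default
#' 0.01 instead of the final-fit 0.001) and an iteration cap of
#' `max_iter_factor` (default 100) times the training size — a pure compute-budget
#' measure for model selection; the model refitted with the selected
#' parameters always uses full precision.
#'
#' @param x feature matrix of the (outer-)training records.
#' @param y labels.
#' @param inner_folds fold ids from [make_folds()].
#' @param grid list of `kernel_params` (see [default_grid()]).
#' @param eps SMO stopping tolerance for the inner fits.
#' @param max_iter_factor iteration cap multiplier for the inner fits.
#' @return List with `best` (a `kernel_params`) and `table`
#'   (C, gamma, mean inner accuracy per grid point).
#' @export
grid_search <- function(x, y, inner_folds, grid = default_grid(),
                        eps = 0.01, max_iter_factor = 100L) {
  stopifnot(length(grid) >= 1L)
  x <- as_sparse(x)
  classes <- sort(unique(y))
  scaler <- scaler_fit(x)
  xs <- scaler_apply(x, scaler)
  d2 <- sq_dist(xs)
  nf <- max(inner_folds)
  gammas <- unique(vapply(grid, `[[`, numeric(1), "gamma"))
  acc <- numeric(length(grid))
  for (g in gammas) {
    K <- rbf_kernel(d2, g)
    gi <- which(vapply(grid, `[[`, numeric(1), "gamma") == g)
    for (pi in gi) {
      C <- grid[[pi]]$C
      correct <- 0L
      total <- 0L
      for (f in seq_len(nf)) {
        tr <- which(inner_folds != f)
        te <- which(inner_folds == f)
        if (!length(te) || length(unique(y[tr])) < 2L) next
        machines <- ovo_train_kernel(K[tr, tr, drop = FALSE], y[tr],
                                     classes, C, eps = eps,
                                     max_iter = max_iter_factor * length(tr))
        # machines index into the tr subset; decision needs K[te, tr]
        dec <- vapply(machines, function(m) {
          as.numeric(K[te, tr[m$idx], drop = FALSE] %*% m$coef) - m$rho
        }, numeric(length(te)))
        dec <- matrix(dec, nrow = length(te))
        pred <- ovo_vote(machines, dec, classes)
        correct <- correct + sum(pred == y[te])
        total <- total + length(te)
      }
      acc[pi] <- correct / total
    }
  }
  tab <- data.frame(C = vapply(grid, `[[`, numeric(1), "C"),
                    gamma = vapply(grid, `[[`, numeric(1), "gamma"),
                    accuracy = acc)
  ord <- order(-tab$accuracy, tab$C, tab$gamma)
  best <- grid[[ord[1]]]
  list(best = best, table = tab)
}

#' Nested cross-validated evaluation of one feature representation
#'
#' The two-level protocol: the data are split into `n_outer` folds; for
#' each outer fold, an inner `n_inner`-fold grid search on the remaining
#' data selects C and gamma, a model is refitted on all outer-training
#' records with the selected parameters, and the held-out fold is
#' predicted.  The scaler and all hyperparameters only ever see
#' outer-training data.
#'
#' @param records labeled `peptide_set`.
#' @param spec a `feature_spec`, or an already-built feature matrix whose
#'   rows match `records`.
#' @param table an `aaindex_table` (AAindex spec only).
#' @param grid hyperparameter grid.
#' @param seed RNG seed driving fold assignment.
#' @param n_outer,n_inner fold counts.
#' @param stratified stratify folds by class.
#' @return List with `per_fold` (class metric tables with fold accuracy as
#'   attribute `acc`), `aggregate` (mean/SD over folds, see
#'   [aggregate_folds()]), `confusion` (pooled counts), `best_params`,
#'   `predictions`.
#' @export
nested_evaluate <- function(records, spec, table = NULL,
                            grid = default_grid(), seed = 1L,
                            n_outer = 10L, n_inner = 10L,
                            stratified = TRUE) {
  if (any(is.na(records$label))) stop("all records must be labeled")
  y <- records$label
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  X <- if (inherits(spec, "feature_spec")) {
    feature_matrix(records, spec, table)
  } else {
    as_sparse(spec)
  }
  outer_folds <- make_folds(y, n = n_outer, seed = seed,
                            stratified = stratified)
  per_fold <- list()
  best_params <- list()
  pred_all <- character(length(y))
  for (f in seq_len(n_outer)) {
    tr <- which(outer_folds != f)
    te <- which(outer_folds == f)
    if (length(unique(y[tr])) < 2L) {
      peploc_log("outer fold ", f, " training data has a single class",
                 level = "warn")
      next
    }
    missing_cls <- setdiff(classes, unique(y[tr]))
    if (length(missing_cls)) {
      peploc_log("class(es) absent from outer-training fold ", f, ": ",
                 paste(missing_cls, collapse = ", "), level = "warn")
    }
    inner <- make_folds(y[tr], n = min(n_inner, length(tr)),
                        seed = seed * 1000L + f, stratified = stratified)
    gs <- grid_search(X[tr, , drop = FALSE], y[tr], inner, grid)
    model <- train_svm(X[tr, , drop = FALSE], y[tr], gs$best,
                       probability = FALSE, seed = seed + f)
    pred <- predict(model, X[te, , drop = FALSE], type = "vote")
    pred_all[te] <- pred
    cc <- confusion_counts(y[te], pred, classes = classes)
    cm <- class_metrics(cc)
    attr(cm, "acc") <- overall_accuracy(cc)
    per_fold[[length(per_fold) + 1L]] <- cm
    best_params[[length(best_params) + 1L]] <- gs$best
  }
  pooled <- confusion_counts(y, pred_all, classes = classes)
  list(per_fold = per_fold,
       aggregate = aggregate_folds(per_fold),
       confusion = pooled,
       best_params = best_params,
       predictions = pred_all,
       outer_folds = outer_folds)
}
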