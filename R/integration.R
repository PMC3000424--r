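# Feature integration: the five prediction schemes — single best feature,
# attribute concatenation (all 41 or a chosen subset), and two-layer
# probability stacking where per-feature SVM class probabilities feed a
# second-layer SVM.

#' The three historically best-performing feature representations
#'
#' Ungrouped 4th-order composition, group-C 6th-order composition and
#' group-D 7th-order composition.
#' @return Character vector of three registry names.
#' @export
top3_members <- function() {
  c("comp_ungrouped_k4", "comp_groupC_k6", "comp_groupD_k7")
}

#' Define an integration scheme
#'
#' @param kind `"single_feature"`, `"concat_attributes"` or
#'   `"stacked_predictions"`.
#' @param members registry names (see [build_feature_registry()]);
#'   `single_feature` takes exactly one.  Members are always used in
#'   registry order so meta-vector layout is reproducible.
#' @return Object of class `scheme_spec`.
#' @export
scheme_spec <- function(kind = c("single_feature", "concat_attributes",
                                 "stacked_predictions"),
                        members) {
  kind <- match.arg(kind)
  if (!length(members)) stop("scheme needs at least one member")
  if (anyDuplicated(members)) stop("duplicate scheme member(s)")
  if (kind == "single_feature" && length(members) != 1L) {
    stop("single_feature scheme takes exactly one member")
  }
  registry_names <- names(build_feature_registry())
  unknown <- setdiff(members, registry_names)
  if (length(unknown)) {
    stop("unknown registry name(s): ", paste(unknown, collapse = ", "))
  }
  members <- registry_names[registry_names %in% members]  # registry order
  structure(list(kind = kind, members = members), class = "scheme_spec")
}

#' Concatenated attribute vector of one peptide
#'
#' Member feature vectors in registry order, keys prefixed with the member
#' name; the nominal dimension is the sum of the member dimensions.
#'
#' @param seq cleaned peptide string.
#' @param members registry names.
#' @param table an `aaindex_table`.
#' @return Named numeric vector with attribute `dimension`.
#' @export
concat_attributes <- function(seq, members, table = NULL) {
  if (anyDuplicated(members)) stop("duplicate member(s)")
  registry <- build_feature_registry(table)
  members <- names(registry)[names(registry) %in% members]
  parts <- lapply(members, function(m) {
    v <- extract_features(seq, registry[[m]], table)
    setNames(as.numeric(v), paste0(m, ".", names(v)))
  })
  out <- unlist(parts)
  attr(out, "dimension") <- sum(vapply(members, function(m) {
    registry[[m]]$dimension
  }, numeric(1)))
  out
}

# concatenated feature matrix for a peptide set
concat_matrix <- function(records, members, table = NULL, keys = NULL) {
  registry <- build_feature_registry(table)
  members <- names(registry)[names(registry) %in% members]
  mats <- lapply(members, function(m) {
    mk <- NULL
    if (!is.null(keys)) {
      pref <- paste0(m, ".")
      mk <- sub(pref, "", keys[startsWith(keys, pref)], fixed = TRUE)
    }
    x <- feature_matrix(records, registry[[m]], table, keys = mk)
    colnames(x) <- paste0(m, ".", colnames(x))
    x
  })
  do.call(cbind, mats)
}

#' First-layer meta-vector matrix
#'
#' Runs every member model over the records and concatenates the class
#' probability blocks in (member order x class order); each block of
#' `n_classes` entries sums to 1.  Dimension = |members| x n_classes
#' (369 for all 41 members over 9 classes).
#'
#' @param records a `peptide_set`.
#' @param first_layer named list of `peploc_svm` models, one per member,
#'   with identical class order.
#' @param table an `aaindex_table`.
#' @return Dense matrix, rows = records, columns `member.class`.
#' @export
stack_first_layer <- function(records, first_layer, table = NULL) {
  registry <- build_feature_registry(table)
  class_sets <- lapply(first_layer, `[[`, "classes")
  if (length(unique(lapply(class_sets, paste, collapse = ","))) != 1L) {
    stop("inconsistent class orders across first-layer models")
  }
  blocks <- lapply(names(first_layer), function(m) {
    model <- first_layer[[m]]
    x <- feature_matrix(records, registry[[m]], table, keys = model$keys)
    pr <- predict(model, x, type = "prob")
    colnames(pr) <- paste0(m, ".", colnames(pr))
    pr
  })
  do.call(cbind, blocks)
}

#' Train a prediction scheme
#'
#' `single_feature` and `concat_attributes` train one RBF-SVM on the
#' (concatenated) attributes.  `stacked_predictions` trains one
#' probability-emitting SVM per member, converts the training records into
#' meta-vectors of per-member class probabilities, and trains a second-layer
#' SVM on those.  All hyperparameters are selected by inner cross-validated
#' grid search on the given (training) records only.  The second layer uses
#' the first layer's in-sample probabilities on its own training data.
#'
#' @param records labeled training `peptide_set`.
#' @param scheme a `scheme_spec`.
#' @param table an `aaindex_table`.
#' @param grid hyperparameter grid.
#' @param seed RNG seed.
#' @param n_inner inner folds for the grid search.
#' @return Object of class `peploc_scheme`.
#' @export
train_scheme <- function(records, scheme, table = NULL,
                         grid = default_grid(), seed = 1L, n_inner = 10L) {
  stopifnot(inherits(scheme, "scheme_spec"))
  if (any(is.na(records$label))) stop("all records must be labeled")
  y <- records$label
  registry <- build_feature_registry(table)
  inner <- make_folds(y, n = min(n_inner, length(y)), seed = seed)
  fit_one <- function(X) {
    gs <- grid_search(X, y, inner, grid)
    train_svm(X, y, gs$best, probability = TRUE, seed = seed)
  }
  if (scheme$kind == "single_feature") {
    X <- feature_matrix(records, registry[[scheme$members]], table)
    model <- fit_one(X)
    out <- list(scheme = scheme, model = model)
  } else if (scheme$kind == "concat_attributes") {
    X <- concat_matrix(records, scheme$members, table)
    model <- fit_one(X)
    out <- list(scheme = scheme, model = model)
  } else {
    first_layer <- lapply(scheme$members, function(m) {
      X <- feature_matrix(records, registry[[m]], table)
      fit_one(X)
    })
    names(first_layer) <- scheme$members
    meta <- stack_first_layer(records, first_layer, table)
    gs2 <- grid_search(meta, y, inner, grid)
    second <- train_svm(meta, y, gs2$best, probability = TRUE, seed = seed)
    out <- list(scheme = scheme, first_layer = first_layer, model = second)
  }
  structure(out, class = "peploc_scheme")
}

#' Predict class probabilities under a trained scheme
#'
#' @param composite a `peploc_scheme` from [train_scheme()].
#' @param records a `peptide_set` (labels not required).
#' @param table an `aaindex_table`.
#' @param type `"prob"` or `"class"`.
#' @return Probability matrix over the nine classes (rows sum to 1), or
#'   the argmax class vector.
#' @export
predict_scheme <- function(composite, records, table = NULL,
                           type = c("prob", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(composite, "peploc_scheme"))
  scheme <- composite$scheme
  if (scheme$kind == "stacked_predictions") {
    meta <- stack_first_layer(records, composite$first_layer, table)
    X <- meta
  } else if (scheme$kind == "concat_attributes") {
    X <- concat_matrix(records, scheme$members, table,
                       keys = composite$model$keys)
  } else {
    registry <- build_feature_registry(table)
    X <- feature_matrix(records, registry[[scheme$members]], table,
                        keys = composite$model$keys)
  }
  predict(composite$model, X, type = type)
}
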