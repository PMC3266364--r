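# Maximum-entropy relation classifier.  Binary conditional maxent over
# indicator features is identical to L2-regularized (Gaussian prior)
# logistic regression; the penalized log-likelihood is convex, so
# training is deterministic up to optimizer tolerance regardless of
# initialization.  Fitting uses L-BFGS-B with an analytic gradient over
# a sparse design matrix.

#' Build a sparse design matrix from feature-name vectors
#'
#' @param features list of character vectors (one per instance).
#' @param feature_index optional existing name-to-column map; features
#'   absent from it are dropped (prediction-time behavior).  When
#'   \code{NULL} the index is built from the data.
#' @return list with \code{x} (dgCMatrix) and \code{feature_index}
#'   (named integer vector).
#' @export
feature_matrix <- function(features, feature_index = NULL) {
  if (is.null(feature_index)) {
    all_names <- sort(unique(unlist(features, use.names = FALSE)))
    feature_index <- setNames(seq_along(all_names), all_names)
  }
  ii <- integer(0); jj <- integer(0)
  for (i in seq_along(features)) {
    cols <- unname(feature_index[features[[i]]])
    cols <- cols[!is.na(cols)]
    ii <- c(ii, rep.int(i, length(cols)))
    jj <- c(jj, cols)
  }
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(features), length(feature_index)))
  list(x = x, feature_index = feature_index)
}

# penalized negative log-likelihood and gradient; theta = c(bias, w)
maxent_objective <- function(theta, x, y, sigma2) {
  w <- theta[-1]
  eta <- as.numeric(x %*% w) + theta[1]
  # stable log(1 + exp(eta))
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  nll <- -sum(y * eta - lse) + sum(w^2) / (2 * sigma2)
  p <- 1 / (1 + exp(-eta))
  grad_w <- -as.numeric(Matrix::crossprod(x, y - p)) + w / sigma2
  grad_b <- -sum(y - p)
  list(value = nll, gradient = c(grad_b, grad_w))
}

#' Train a maximum-entropy relation classifier
#'
#' Maximizes the conditional log-likelihood of POSITIVE/NEGATIVE labels
#' under a Gaussian prior on the weights (variance \code{sigma2}); the
#' intercept is unpenalized.  The objective is convex, so the fit is
#' deterministic given the configuration.
#'
#' @param features list of character vectors, or a precomputed result of
#'   \code{\link{feature_matrix}}.
#' @param labels character vector of \code{"POSITIVE"}/\code{"NEGATIVE"}.
#' @param relation_kind \code{"GM"} or \code{"GC"} (metadata).
#' @param sigma2 Gaussian prior variance (default 1).
#' @param tol convergence tolerance on the projected gradient.
#' @param maxit maximum L-BFGS-B iterations.
#' @param init optional initial parameter vector \code{c(bias, weights)}
#'   (default all zeros); used by the convexity checks.
#' @return an object of class \code{maxent_model}.
#' @export
train_maxent <- function(features, labels, relation_kind = "GM",
                         sigma2 = 1, tol = 1e-8, maxit = 1000L,
                         init = NULL) {
  if (!all(labels %in% c("POSITIVE", "NEGATIVE"))) {
    stop("training labels must be POSITIVE or NEGATIVE")
  }
  if (length(unique(labels)) < 2) stop("training data contains a single class")
  fm <- if (is.list(features) && !is.null(features$x)) features
        else feature_matrix(features)
  if (ncol(fm$x) == 0) stop("no features present in the training data")
  y <- as.numeric(labels == "POSITIVE")
  p <- ncol(fm$x)
  theta0 <- if (is.null(init)) numeric(p + 1L) else init
  fn <- function(th) maxent_objective(th, fm$x, y, sigma2)$value
  gr <- function(th) maxent_objective(th, fm$x, y, sigma2)$gradient
  fit <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 10, pgtol = tol))
  structure(
    list(relation_kind = relation_kind,
         feature_index = fm$feature_index,
         bias = fit$par[1],
         weights = setNames(fit$par[-1], names(fm$feature_index)),
         sigma2 = sigma2,
         training_meta = list(tol = tol, maxit = maxit,
                              n = length(labels),
                              converged = fit$convergence == 0)),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model %s> %d features, sigma2=%g, n=%d\n",
              x$relation_kind, length(x$weights), x$sigma2,
              x$training_meta$n))
  invisible(x)
}

#' Gradient norm of the penalized log-likelihood at the fitted optimum
#'
#' Diagnostic used to verify convergence: at a true optimum of the
#' convex objective the gradient vanishes.
#'
#' @param model a \code{\link{maxent_model}}.
#' @param features,labels the training data.
#' @return Euclidean norm of the gradient.
#' @export
maxent_gradient_norm <- function(model, features, labels) {
  fm <- feature_matrix(features, model$feature_index)
  y <- as.numeric(labels == "POSITIVE")
  g <- maxent_objective(c(model$bias, unname(model$weights)),
                        fm$x, y, model$sigma2)$gradient
  sqrt(sum(g^2))
}

#' Predict the POSITIVE probability of relation instances
#'
#' Features unseen at training time contribute zero; a vector of only
#' unseen features receives the fitted prior class probability (bias
#' only).
#'
#' @param model a \code{\link{maxent_model}}.
#' @param features list of character vectors (or a single one).
#' @return numeric vector of P(POSITIVE | x) in [0, 1].
#' @export
predict_maxent <- function(model, features) {
  if (is.character(features)) features <- list(features)
  eta <- vapply(features, function(f) {
    w <- model$weights[f]
    model$bias + sum(w, na.rm = TRUE)
  }, numeric(1))
  1 / (1 + exp(-eta))
}

#' Classify with a fixed decision threshold
#'
#' @param model a \code{\link{maxent_model}}.
#' @param features list of character vectors.
#' @param threshold POSITIVE iff probability >= threshold (default 0.5).
#' @return character vector of labels.
#' @export
classify_maxent <- function(model, features, threshold = 0.5) {
  ifelse(predict_maxent(model, features) >= threshold,
         "POSITIVE", "NEGATIVE")
}

precision_recall <- function(pred, gold) {
  tp <- sum(pred == "POSITIVE" & gold == "POSITIVE")
  fp <- sum(pred == "POSITIVE" & gold == "NEGATIVE")
  fn <- sum(pred == "NEGATIVE" & gold == "POSITIVE")
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# stratified group-aware fold assignment: groups (duplicated instances
# from one source sentence) stay in one fold; stratification by the
# group's majority label
make_folds <- function(labels, groups, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  glab <- tapply(labels, groups, function(l) names(sort(-table(l)))[1])
  for (lab in unique(glab)) {
    gs <- sample(names(glab)[glab == lab])
    gf <- rep_len(seq_len(k), length(gs))
    for (t in seq_along(gs)) fold[groups == gs[t]] <- gf[t]
  }
  fold
}

#' Stratified k-fold cross-validation of the maxent classifier
#'
#' Instances are shuffled by \code{seed} and partitioned into \code{k}
#' folds stratified by label; duplicated instances expanded from the
#' same source sentence are kept in the same fold.  Per fold the model
#' is trained on the remaining folds (optionally subsampled to
#' \code{train_n} instances) and precision/recall of the POSITIVE class
#' are computed on the held-out fold.
#'
#' @param features list of character vectors.
#' @param labels character vector of gold labels.
#' @param groups optional per-instance source-sentence keys.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @param train_n optional fixed training-set size per fold.
#' @param ... passed to \code{\link{train_maxent}}.
#' @return an object of class \code{fold_report}: data.frame of per-fold
#'   precision/recall plus \code{mean_precision}, \code{sd_precision},
#'   \code{mean_recall}, \code{sd_recall} attributes.
#' @export
cross_validate <- function(features, labels, groups = NULL, k = 10L,
                           seed = 1L, train_n = NULL, ...) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("corpus smaller than the number of folds")
  if (is.null(groups)) groups <- as.character(seq_len(n))
  fold <- make_folds(labels, groups, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!is.null(train_n) && length(tr) > train_n) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed + f)
      tr <- sort(sample(tr, train_n))
    }
    model <- train_maxent(features[tr], labels[tr], ...)
    pr <- precision_recall(classify_maxent(model, features[te]), labels[te])
    data.frame(fold = f, n_train = length(tr), n_test = length(te),
               precision = pr[["precision"]], recall = pr[["recall"]])
  })
  report <- do.call(rbind, rows)
  structure(report, class = c("fold_report", "data.frame"),
            mean_precision = mean(report$precision),
            sd_precision = sd(report$precision),
            mean_recall = mean(report$recall),
            sd_recall = sd(report$recall))
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: precision %.1f +/- %.1f%%, recall %.1f +/- %.1f%%\n",
              nrow(x), 100 * attr(x, "mean_precision"),
              100 * attr(x, "sd_precision"),
              100 * attr(x, "mean_recall"), 100 * attr(x, "sd_recall")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Save a maxent model as versioned JSON
#'
#' @param model a \code{\link{maxent_model}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_maxent <- function(model, path) {
  obj <- list(format = "methrelex-maxent", version = 1L,
              relation_kind = model$relation_kind,
              feature_names = names(model$feature_index),
              bias = model$bias,
              weights = unname(model$weights),
              sigma2 = model$sigma2,
              training_meta = model$training_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a maxent model saved by \code{\link{write_maxent}}
#'
#' @param path JSON model file.
#' @return a \code{\link{maxent_model}}.
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "methrelex-maxent")) {
    stop("not a methrelex maxent model file: ", path)
  }
  fi <- setNames(seq_along(obj$feature_names), obj$feature_names)
  structure(
    list(relation_kind = obj$relation_kind, feature_index = fi,
         bias = obj$bias,
         weights = setNames(obj$weights, obj$feature_names),
         sigma2 = obj$sigma2, training_meta = obj$training_meta),
    class = "maxent_model"
  )
}
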