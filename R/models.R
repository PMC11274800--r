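# Activity classification models: five algorithms x three fingerprints,
# leave-one-out cross-validated balanced accuracy, and a grid search over
# small hyperparameter menus. The positive class is ACTIVE throughout.

MODEL_ALGORITHMS <- c("KNN", "RF", "GBT", "SVM", "FFNN")
MODEL_FINGERPRINTS <- c("MACCS166", "ECFP4_2048", "FP2_1024")
CLASS_LEVELS <- c("ACTIVE", "INACTIVE")

#' Model specification
#'
#' @param algorithm One of `"KNN"`, `"RF"`, `"GBT"`, `"SVM"`, `"FFNN"`.
#' @param fingerprint One of `"MACCS166"`, `"ECFP4_2048"`, `"FP2_1024"`.
#' @param hyper Named list of hyperparameters (see
#'   [default_hyper_grids()] for the tunable ones per algorithm).
#' @return A `libprof_model_spec` object.
#' @export
model_spec <- function(algorithm, fingerprint = "ECFP4_2048", hyper = list()) {
  algorithm <- match.arg(algorithm, MODEL_ALGORITHMS)
  fingerprint <- match.arg(fingerprint, MODEL_FINGERPRINTS)
  structure(list(algorithm = algorithm, fingerprint = fingerprint,
                 hyper = hyper),
            class = "libprof_model_spec")
}

#' Default hyperparameter grids
#'
#' Small documented menus per algorithm: neighbours for KNN, tree count
#' for RF, tree depth for GBT, cost for SVM, hidden width and weight decay
#' for the feed-forward network. All user-overridable.
#'
#' @return Named list of named lists of candidate values.
#' @export
default_hyper_grids <- function() {
  list(
    KNN  = list(k = c(1L, 3L, 5L)),
    RF   = list(num_trees = c(200L)),
    GBT  = list(max_depth = c(3L), nrounds = c(50L)),
    SVM  = list(cost = c(1)),
    FFNN = list(hidden = c(8L), decay = c(1e-3))
  )
}

# ---- fitting backends -------------------------------------------------

fit_backend <- function(spec, X, y, seed = 1L) {
  h <- spec$hyper
  obj <- switch(
    spec$algorithm,
    KNN = list(X = X, y = y, k = h$k %||% 3L),
    RF = ranger::ranger(
      x = X, y = y,
      num.trees = h$num_trees %||% 200L,
      seed = as.integer(seed), num.threads = 1L),
    GBT = {
      dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y == "ACTIVE"),
                                  nthread = 1)
      params <- list(objective = "binary:logistic",
                     max_depth = h$max_depth %||% 3L,
                     eta = h$learning_rate %||% 0.3,
                     nthread = 1, seed = as.integer(seed))
      xgboost::xgb.train(params = params, data = dtr,
                         nrounds = h$nrounds %||% 50L, verbose = 0)
    },
    SVM = fit_svm_precomp(X, y, cost = h$cost %||% 1),
    FFNN = ffnn_fit(X, y, hidden = h$hidden %||% 8L,
                    decay = h$decay %||% 1e-3, seed = seed)
  )
  structure(list(algorithm = spec$algorithm, model = obj, spec = spec),
            class = "libprof_fit")
}

predict_backend <- function(fit, Xnew) {
  out <- switch(
    fit$algorithm,
    KNN = knn_predict(fit$model, Xnew),
    RF = as.character(stats::predict(fit$model, Xnew,
                                     num.threads = 1L)$predictions),
    GBT = {
      pr <- stats::predict(fit$model,
                           xgboost::xgb.DMatrix(Xnew, nthread = 1))
      ifelse(pr >= 0.5, "ACTIVE", "INACTIVE")
    },
    SVM = svm_predict_precomp(fit$model, Xnew),
    FFNN = ffnn_predict(fit$model, Xnew)
  )
  factor(out, levels = CLASS_LEVELS)
}

# KNN on Euclidean bit distance; ties on the vote are broken by the class
# of the single nearest neighbour (deterministic).
knn_predict <- function(obj, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(obj$X^2), "+") -
    2 * Xnew %*% t(obj$X)
  apply(d2, 1, function(di) {
    o <- order(di)
    nb <- obj$y[o[seq_len(min(obj$k, length(o)))]]
    tb <- table(nb)
    win <- names(tb)[tb == max(tb)]
    if (length(win) == 1L) win else as.character(obj$y[o[1L]])
  })
}

# SVM with a precomputed RBF kernel (kernel width from the median
# heuristic); keeps the training matrix for query-kernel evaluation.
fit_svm_precomp <- function(X, y, cost = 1) {
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  d2[d2 < 0] <- 0
  med <- stats::median(d2[upper.tri(d2)])
  sigma <- if (med > 0) 1 / med else 1
  K <- exp(-sigma * d2)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = cost)
  list(fit = fit, X = X, sigma = sigma)
}

# LOO fast path for the SVM: the Gram matrix is computed once and sliced
# per held-out record.
loocv_svm_predictions <- function(X, y, cost = 1) {
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  d2[d2 < 0] <- 0
  med <- stats::median(d2[upper.tri(d2)])
  sigma <- if (med > 0) 1 / med else 1
  K <- exp(-sigma * d2)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K[-i, -i]), y[-i],
                         type = "C-svc", C = cost)
    sv <- kernlab::SVindex(fit)
    kq <- kernlab::as.kernelMatrix(K[i, -i, drop = FALSE][, sv, drop = FALSE])
    pred[i] <- as.character(kernlab::predict(fit, kq))
  }
  pred
}

svm_predict_precomp <- function(obj, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(obj$X^2), "+") - 2 * Xnew %*% t(obj$X)
  d2[d2 < 0] <- 0
  K <- exp(-obj$sigma * d2)
  sv <- kernlab::SVindex(obj$fit)
  as.character(kernlab::predict(
    obj$fit, kernlab::as.kernelMatrix(K[, sv, drop = FALSE])))
}

# Single-hidden-layer feed-forward network (tanh hidden, logistic output)
# trained full-batch with Adam; deterministic given the seed.
ffnn_fit <- function(X, y, hidden = 8L, decay = 1e-3, epochs = 200L,
                     lr = 0.02, seed = 1L) {
  p <- ncol(X); n <- nrow(X)
  t <- as.numeric(y == "ACTIVE")
  withr::with_seed(as.integer(seed), {
    W1 <- matrix(stats::rnorm(p * hidden, sd = 1 / sqrt(p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- stats::rnorm(hidden, sd = 1 / sqrt(hidden))
    b2 <- 0
  })
  mW1 <- vW1 <- matrix(0, p, hidden); mb1 <- vb1 <- numeric(hidden)
  mW2 <- vW2 <- numeric(hidden); mb2 <- vb2 <- 0
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  prev_loss <- Inf; stall <- 0L
  for (it in seq_len(epochs)) {
    H <- tanh(sweep(X %*% W1, 2, b1, "+"))
    z <- as.vector(H %*% W2) + b2
    prob <- 1 / (1 + exp(-z))
    loss <- -mean(t * log(pmax(prob, 1e-12)) +
                    (1 - t) * log(pmax(1 - prob, 1e-12)))
    if (prev_loss - loss < 1e-4) stall <- stall + 1L else stall <- 0L
    prev_loss <- loss
    if (it > 50L && stall >= 10L) break
    delta <- (prob - t) / n
    gW2 <- as.vector(crossprod(H, delta)) + decay * W2
    gb2 <- sum(delta)
    dH <- outer(delta, W2) * (1 - H^2)
    gW1 <- crossprod(X, dH) + decay * W1
    gb1 <- colSums(dH)
    upd <- function(m, v, g) {
      m <- b1m * m + (1 - b1m) * g
      v <- b2m * v + (1 - b2m) * g^2
      mh <- m / (1 - b1m^it); vh <- v / (1 - b2m^it)
      list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
    }
    u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
    u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
    u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
    u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ffnn_predict <- function(obj, Xnew) {
  H <- tanh(sweep(Xnew %*% obj$W1, 2, obj$b1, "+"))
  z <- as.vector(H %*% obj$W2) + obj$b2
  ifelse(z >= 0, "ACTIVE", "INACTIVE")
}

# ---- evaluation -------------------------------------------------------

confusion_metrics <- function(truth, pred) {
  truth <- factor(truth, CLASS_LEVELS); pred <- factor(pred, CLASS_LEVELS)
  tp <- sum(truth == "ACTIVE" & pred == "ACTIVE")
  fn <- sum(truth == "ACTIVE" & pred == "INACTIVE")
  tn <- sum(truth == "INACTIVE" & pred == "INACTIVE")
  fp <- sum(truth == "INACTIVE" & pred == "ACTIVE")
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       ba = (tpr + tnr) / 2,
       precision_active = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall_active = tpr,
       precision_inactive = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       recall_inactive = tnr)
}

#' Leave-one-out cross-validated balanced accuracy
#'
#' Refits the model n times leaving one record out, aggregates the held-out
#' predictions into a single confusion matrix and reports balanced accuracy
#' (mean of sensitivity and specificity) plus per-class precision/recall.
#'
#' @param spec A [model_spec()].
#' @param train Labeled tibble (rows with `kept == FALSE` are ignored) with
#'   `canonical_smiles` and `label`.
#' @param seed Integer seed forwarded to stochastic learners.
#' @param X Optional precomputed fingerprint matrix (rows aligned with
#'   `train`).
#' @return A `libprof_model_eval` list: `ba`, per-class precision/recall,
#'   `n_train`, and the held-out `predictions` tibble.
#' @export
loocv_balanced_accuracy <- function(spec, train, seed = 1L, X = NULL) {
  if ("kept" %in% names(train)) train <- train[train$kept, , drop = FALSE]
  n <- nrow(train)
  if (n < 10L) stop("need at least 10 training records")
  y <- factor(train$label, CLASS_LEVELS)
  if (any(table(y) == 0L)) stop("both classes must be present")
  if (is.null(X)) X <- fp_matrix(train$canonical_smiles, spec$fingerprint) * 1.0
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  pred <- if (spec$algorithm == "SVM") {
    loocv_svm_predictions(X, y, cost = spec$hyper$cost %||% 1)
  } else {
    p <- character(n)
    for (i in seq_len(n)) {
      fit <- fit_backend(spec, X[-i, , drop = FALSE], y[-i], seed = seed)
      p[i] <- as.character(predict_backend(fit, X[i, , drop = FALSE]))
    }
    p
  }
  cm <- confusion_metrics(y, pred)
  structure(c(cm, list(
    n_train = n, spec = spec,
    predictions = tibble::tibble(
      id = train$id %||% ordinal_ids(n, "TR"),
      truth = as.character(y), pred = pred))),
    class = "libprof_model_eval")
}

#' @export
print.libprof_model_eval <- function(x, ...) {
  cat(sprintf("%s + %s: LOO-CV BA %.3f (n = %d)\n", x$spec$algorithm,
              x$spec$fingerprint, x$ba, x$n_train))
  invisible(x)
}

#' Grid search over algorithms, fingerprints and hyperparameters
#'
#' Evaluates every algorithm x fingerprint combination; within each, the
#' hyperparameter combination with the best LOO-CV balanced accuracy wins
#' (ties go to the earlier grid entry). The full leaderboard is returned;
#' the winning specification and its evaluation are in attributes
#' `best_spec` and `best_eval`.
#'
#' @param train Labeled training tibble.
#' @param algorithms,fingerprints Subsets of the menus (defaults: all).
#' @param grids Hyperparameter grids (see [default_hyper_grids()]).
#' @param seed Integer seed.
#' @return A `libprof_grid` tibble: one row per evaluated model with
#'   `algorithm`, `fingerprint`, `hyper` (list), `ba`, precision/recall.
#' @export
grid_search_models <- function(train, algorithms = MODEL_ALGORITHMS,
                               fingerprints = MODEL_FINGERPRINTS,
                               grids = default_hyper_grids(), seed = 1L) {
  if ("kept" %in% names(train)) train <- train[train$kept, , drop = FALSE]
  rows <- list(); evals <- list()
  for (fp_kind in fingerprints) {
    X <- fp_matrix(train$canonical_smiles, fp_kind) * 1.0
    for (alg in algorithms) {
      grid <- grids[[alg]] %||% list()
      combos <- if (length(grid)) {
        do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE,
                                          stringsAsFactors = FALSE)))
      } else data.frame(row.names = 1)
      for (ci in seq_len(nrow(combos))) {
        hyper <- as.list(combos[ci, , drop = FALSE])
        names(hyper) <- names(combos)
        spec <- model_spec(alg, fp_kind, hyper)
        ev <- loocv_balanced_accuracy(spec, train, seed = seed, X = X)
        key <- sprintf("%s|%s|%d", alg, fp_kind, ci)
        evals[[key]] <- ev
        rows[[key]] <- tibble::tibble(
          algorithm = alg, fingerprint = fp_kind, hyper = list(hyper),
          ba = ev$ba,
          precision_active = ev$precision_active,
          recall_active = ev$recall_active,
          n_train = ev$n_train)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  # stable ranking: ba desc, then declaration order
  out$.order <- seq_len(nrow(out))
  out <- out[order(-out$ba, out$.order), , drop = FALSE]
  best_key <- sprintf("%s|%s", out$algorithm[1], out$fingerprint[1])
  best_idx <- which(startsWith(names(evals), best_key) &
                      vapply(evals, function(e) isTRUE(all.equal(e$ba, out$ba[1])),
                             logical(1)))[1]
  attr(out, "best_eval") <- evals[[best_idx]]
  attr(out, "best_spec") <- evals[[best_idx]]$spec
  out$.order <- NULL
  class(out) <- c("libprof_grid", class(out))
  out
}

#' @method tidy libprof_grid
#' @export
tidy.libprof_grid <- function(x, ...) {
  y <- x
  class(y) <- setdiff(class(y), "libprof_grid")
  y
}

#' @method glance libprof_grid
#' @export
glance.libprof_grid <- function(x, ...) {
  best <- attr(x, "best_eval")
  tibble::tibble(algorithm = best$spec$algorithm,
                 fingerprint = best$spec$fingerprint,
                 ba = best$ba, n_train = best$n_train,
                 n_models = nrow(x))
}
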