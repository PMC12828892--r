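## Band-wise classification of dilation type: dataset construction,
## stratified cross-validation, and the six model kinds (1-D CNN, RBF-SVM,
## random forest, LDA, elastic-net logistic regression, MLP).

#' Build a labeled trial matrix for one band
#'
#' Rows are the peak-aligned band-power windows ([align_to_peaks()]), labels
#' come from the event class (spontaneous = 0, evoked = 1). With
#' `balance = TRUE` the majority class is randomly subsampled (seeded) to
#' the minority count so the two classes are represented equally.
#' Standardization is deliberately NOT applied here: per-feature statistics
#' are computed inside each cross-validation training fold to avoid leakage.
#'
#' @param band_series a `band_power_series` from [sliding_band_power()].
#' @param events a `dilation_events` data.frame with both classes present.
#' @param halfspan_s half-width of the aligned window (s); 6 s gives the
#'   standard 1200-sample (12 s at 100 Hz) feature window.
#' @param balance subsample the majority class to the minority count.
#' @param seed seed for the balancing subsample.
#' @return an object of class `trial_matrix`: list with `features`
#'   (n x 1200), `labels` (0/1 integer), `band`, `balanced`,
#'   `standardized` (always `FALSE` here), `times_rel_s`, `session_ids`.
#' @export
build_trial_dataset <- function(band_series, events, halfspan_s = 6,
                                balance = TRUE, seed = 1L) {
  al <- align_to_peaks(band_series, events, halfspan_s)
  labels <- ifelse(al$events$label == "evoked", 1L, 0L)
  assert_that(length(unique(labels)) == 2,
              "classification requires both event classes")
  feats <- al$matrix
  sess <- al$events$session_id %||% rep(1L, nrow(feats))
  if (balance) {
    n0 <- sum(labels == 0L)
    n1 <- sum(labels == 1L)
    n_min <- min(n0, n1)
    keep <- withr::with_seed(child_seed(seed, 7L), {
      c(sample(which(labels == 0L), n_min), sample(which(labels == 1L), n_min))
    })
    keep <- sort(keep)
    feats <- feats[keep, , drop = FALSE]
    labels <- labels[keep]
    sess <- sess[keep]
  }
  structure(list(features = feats, labels = labels,
                 band = band_series$band$name, balanced = balance,
                 standardized = FALSE, times_rel_s = al$times_rel_s,
                 session_ids = sess),
            class = "trial_matrix")
}

#' Construct a trial matrix directly from components
#' @param features n x p numeric matrix.
#' @param labels 0/1 labels (spontaneous = 0, evoked = 1).
#' @param band band name.
#' @return a `trial_matrix`.
#' @export
trial_matrix <- function(features, labels, band = "unknown") {
  assert_that(is.matrix(features) && all(is.finite(features)),
              "features must be a finite matrix")
  assert_that(length(labels) == nrow(features), "one label per row required")
  structure(list(features = features, labels = as.integer(labels), band = band,
                 balanced = FALSE, standardized = FALSE,
                 times_rel_s = NULL, session_ids = rep(1L, nrow(features))),
            class = "trial_matrix")
}

#' Classifier specification
#'
#' @param kind one of `"cnn"`, `"svm_rbf"`, `"random_forest"`, `"lda"`,
#'   `"elastic_net"`, `"mlp"`.
#' @param ... hyperparameter overrides. Defaults per kind:
#'   * `cnn`: `filters = c(8, 16, 32)`, `kernel = 7`, `pool = 4`,
#'     `dense = 32`, Adam (`lr = 1e-3`), `batch_size = 32`,
#'     `epochs = 100`, early stopping on a 20% validation slice with
#'     `patience = 10`;
#'   * `svm_rbf`: inner 3-fold grid search over `C = c(0.1, 1, 10, 100)`
#'     and `gamma = scale-heuristic * c(0.1, 1, 10)`;
#'   * `random_forest`: `num_trees = 500`, `min_node_size = 5`
#'     (depth left unbounded, controlled by the node-size constraints);
#'   * `lda`: Fisher discriminant with pseudoinverse pooled scatter
#'     (shrinkage `gamma_reg = 1e-3`), required because the 1200-sample
#'     windows exceed the trial count;
#'   * `elastic_net`: penalized logistic regression, `alpha = 0.5`, lambda
#'     chosen by inner 3-fold cross-validation;
#'   * `mlp`: hidden layers 128 and 64 (ReLU), `dropout = 0.3`, Adam,
#'     same batch/epoch/early-stopping protocol as the CNN.
#' @param seed seed consumed by stochastic fitters.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("cnn", "svm_rbf", "random_forest",
                                     "lda", "elastic_net", "mlp"),
                            ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    cnn = list(filters = c(8, 16, 32), kernel = 7, pool = 4, dense = 32,
               lr = 1e-3, batch_size = 32, epochs = 100, patience = 10,
               val_frac = 0.2),
    svm_rbf = list(C_grid = c(0.1, 1, 10, 100), gamma_mult = c(0.1, 1, 10),
                   inner_k = 3),
    random_forest = list(num_trees = 500, min_node_size = 5),
    lda = list(gamma_reg = 1e-3),
    elastic_net = list(alpha = 0.5, inner_k = 3),
    mlp = list(hidden = c(128, 64), dropout = 0.3, lr = 1e-3,
               batch_size = 32, epochs = 100, patience = 10, val_frac = 0.2)
  )
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "classifier_spec")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately (seeded) and deals trials round-robin into
#' folds, so each fold's class proportions match the global proportions
#' within one trial. Fold memberships depend only on `labels`, `k` and
#' `seed`, hence are identical across model kinds and bands.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed seed for the within-class shuffles.
#' @return integer vector of fold ids (1..k), one per trial.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  folds <- integer(length(labels))
  withr::with_seed(child_seed(seed, 5L), {
    for (cl in sort(unique(labels))) {
      ix <- sample(which(labels == cl))
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

## per-column standardization using training statistics only
standardize_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, sd)
  sg[sg < 1e-12] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sg, "/"),
       test = sweep(sweep(xte, 2, mu), 2, sg, "/"))
}

## ---- model fitters: each returns function(newdata) -> probability of 1 ----

fit_model_cnn <- function(xtr, ytr, spec, seed) {
  L <- ncol(xtr)
  layers <- withr::with_seed(child_seed(seed, 21L), {
    ls <- list()
    in_ch <- 1L
    for (f in spec$filters) {
      ls <- c(ls, list(nn_conv1d(in_ch, f, spec$kernel), nn_relu(),
                       nn_maxpool(spec$pool)))
      in_ch <- f
    }
    c(ls, list(nn_gap(), nn_dense(in_ch, spec$dense, "relu"),
               nn_dense(spec$dense, 1, "sigmoid")))
  })
  best <- nn_train(layers, xtr, ytr, conv_input = TRUE,
                   seed = child_seed(seed, 22L), epochs = spec$epochs,
                   batch_size = spec$batch_size, lr = spec$lr,
                   val_frac = spec$val_frac, patience = spec$patience)
  function(xte) nn_predict_prob(best$layers, xte, conv_input = TRUE)
}

fit_model_mlp <- function(xtr, ytr, spec, seed) {
  p <- ncol(xtr)
  layers <- withr::with_seed(child_seed(seed, 23L), {
    ls <- list()
    d_in <- p
    for (h in spec$hidden) {
      ls <- c(ls, list(nn_dense(d_in, h, "relu"), nn_dropout(spec$dropout)))
      d_in <- h
    }
    c(ls, list(nn_dense(d_in, 1, "sigmoid")))
  })
  best <- nn_train(layers, xtr, ytr, conv_input = FALSE,
                   seed = child_seed(seed, 24L), epochs = spec$epochs,
                   batch_size = spec$batch_size, lr = spec$lr,
                   val_frac = spec$val_frac, patience = spec$patience)
  function(xte) nn_predict_prob(best$layers, xte, conv_input = FALSE)
}

fit_model_svm <- function(xtr, ytr, spec, seed) {
  gamma_scale <- 1 / (ncol(xtr) * max(var(as.vector(xtr)), 1e-12))
  grid <- expand.grid(C = spec$C_grid, gamma = gamma_scale * spec$gamma_mult)
  inner <- stratified_folds(ytr, spec$inner_k, seed = child_seed(seed, 25L))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    ok <- vapply(seq_len(spec$inner_k), function(f) {
      tr <- inner != f
      fit <- withr::with_seed(child_seed(seed, 28L), {
        e1071::svm(xtr[tr, , drop = FALSE], factor(ytr[tr]),
                   kernel = "radial", cost = grid$C[g],
                   gamma = grid$gamma[g], scale = FALSE)
      })
      mean(as.character(predict(fit, xtr[!tr, , drop = FALSE])) ==
             as.character(ytr[!tr]))
    }, numeric(1))
    mean(ok)
  }, numeric(1))
  bestg <- which.max(acc)
  # probability calibration runs an internal cross-validation off the global
  # RNG, so the final fit must be seeded for reproducible output
  fit <- withr::with_seed(child_seed(seed, 29L), {
    e1071::svm(xtr, factor(ytr), kernel = "radial",
               cost = grid$C[bestg], gamma = grid$gamma[bestg],
               scale = FALSE, probability = TRUE)
  })
  function(xte) {
    pr <- attr(predict(fit, xte, probability = TRUE), "probabilities")
    pr[, "1"]
  }
}

fit_model_rf <- function(xtr, ytr, spec, seed) {
  d <- as.data.frame(xtr)
  colnames(d) <- paste0("f", seq_len(ncol(xtr)))
  d$.y <- factor(ytr)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = d,
                        num.trees = spec$num_trees,
                        min.node.size = spec$min_node_size,
                        probability = TRUE, seed = child_seed(seed, 26L),
                        num.threads = 1)
  function(xte) {
    dn <- as.data.frame(xte)
    colnames(dn) <- colnames(d)[seq_len(ncol(xte))]
    predict(fit, dn, num.threads = 1)$predictions[, "1"]
  }
}

## Fisher discriminant: w maximizes the between/within scatter ratio, solved
## as w = S_w^+ (m1 - m0) with a shrinkage-regularized pooled scatter
## (Woodbury identity keeps the solve at n x n even for 1200 features).
fit_model_lda <- function(xtr, ytr, spec, seed) {
  m0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
  m1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  xc <- rbind(sweep(xtr[ytr == 0, , drop = FALSE], 2, m0),
              sweep(xtr[ytr == 1, , drop = FALSE], 2, m1))
  n <- nrow(xtr)
  p <- ncol(xtr)
  dof <- max(n - 2, 1)
  avg_var <- max(sum(xc^2) / (dof * p), 1e-12)
  g <- spec$gamma_reg * avg_var
  d <- m1 - m0
  # (g I + Xc'Xc/dof)^{-1} d via Woodbury
  K <- tcrossprod(xc) / dof
  diag(K) <- diag(K) + g
  w <- (d - crossprod(xc, solve(K, xc %*% d / dof))) / g
  thr <- sum(w * (m0 + m1)) / 2
  function(xte) 1 / (1 + exp(-(as.vector(xte %*% w) - thr)))
}

fit_model_enet <- function(xtr, ytr, spec, seed) {
  foldid <- stratified_folds(ytr, spec$inner_k, seed = child_seed(seed, 27L))
  cv <- glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = spec$alpha,
                          foldid = foldid, standardize = FALSE)
  function(xte) {
    as.vector(predict(cv, xte, s = "lambda.min", type = "response"))
  }
}

fit_classifier <- function(xtr, ytr, spec, seed) {
  switch(spec$kind,
         cnn = fit_model_cnn(xtr, ytr, spec, seed),
         mlp = fit_model_mlp(xtr, ytr, spec, seed),
         svm_rbf = fit_model_svm(xtr, ytr, spec, seed),
         random_forest = fit_model_rf(xtr, ytr, spec, seed),
         lda = fit_model_lda(xtr, ytr, spec, seed),
         elastic_net = fit_model_enet(xtr, ytr, spec, seed))
}

#' Stratified five-fold cross-validated accuracy
#'
#' Splits the trials with [stratified_folds()] (identical memberships across
#' model kinds and bands for a given seed), standardizes features with
#' training-fold statistics only, fits the model on the four training folds
#' (the neural models additionally reserve a validation slice of the
#' training data for early stopping) and scores accuracy on the held-out
#' fold at a probability threshold of 0.5 (ties go to class 0).
#'
#' @param data a `trial_matrix`.
#' @param spec a [classifier_spec()].
#' @param k number of folds.
#' @param seed seed controlling fold assignment and all stochastic fitting.
#' @return an object of class `cv_result`: list with `fold_accuracies`,
#'   `mean_accuracy`, `kind`, `band`, `n_trials`, `folds`, `seed`.
#' @export
crossval_evaluate <- function(data, spec, k = 5, seed = 1L) {
  stopifnot(inherits(data, "trial_matrix"), inherits(spec, "classifier_spec"))
  y <- data$labels
  assert_that(length(unique(y)) == 2, "two classes required")
  assert_that(min(table(y)) >= max(k, 10), "at least 10 trials per class required")
  folds <- stratified_folds(y, k, seed)
  accs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    st <- standardize_train_test(data$features[tr, , drop = FALSE],
                                 data$features[!tr, , drop = FALSE])
    pred <- try(fit_classifier(st$train, y[tr], spec,
                               seed = child_seed(seed, 30L + f)),
                silent = TRUE)
    if (inherits(pred, "try-error")) {
      warning(sprintf("fold %d (%s) failed to fit; excluded", f, spec$kind))
      next
    }
    p <- pred(st$test)
    accs[f] <- mean((p > 0.5) == (y[!tr] == 1))
  }
  structure(list(fold_accuracies = accs,
                 mean_accuracy = mean(accs, na.rm = TRUE),
                 kind = spec$kind, band = data$band,
                 n_trials = nrow(data$features), folds = folds,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s: mean accuracy %.3f (folds: %s)\n",
              x$kind, x$band, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " ")))
  invisible(x)
}

#' Accuracy of every model on every band
#'
#' Runs [crossval_evaluate()] for each (band, model) pair with one shared
#' seed, so fold memberships are identical everywhere, and returns a
#' long-format table.
#'
#' @param trials_by_band named list of `trial_matrix` objects (one per band,
#'   identical trial sets).
#' @param specs list of [classifier_spec()] objects.
#' @param seed shared cross-validation seed.
#' @param k folds.
#' @return data.frame with columns `band`, `model`, `fold`, `accuracy` plus
#'   a `mean_accuracy` summary attribute (band x model matrix).
#' @export
band_accuracy_profile <- function(trials_by_band, specs, seed = 1L, k = 5) {
  rows <- list()
  means <- matrix(NA_real_, nrow = length(trials_by_band), ncol = length(specs),
                  dimnames = list(names(trials_by_band),
                                  vapply(specs, `[[`, "", "kind")))
  for (b in names(trials_by_band)) {
    for (s in seq_along(specs)) {
      cv <- crossval_evaluate(trials_by_band[[b]], specs[[s]], k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, model = cv$kind, fold = seq_len(k),
        accuracy = cv$fold_accuracies, stringsAsFactors = FALSE)
      means[b, cv$kind] <- cv$mean_accuracy
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_accuracy") <- means
  out
}
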