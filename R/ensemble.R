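#' @title Majority-voting ensemble of per-descriptor base classifiers
#' @name ensemble_model
#' @description
#' Every descriptor yields two base classifiers — a k-nearest-neighbour
#' voter and an RBF-kernel support vector machine — trained on that
#' descriptor's auto-correlation features. Bases are ranked by the F1 of
#' their concatenated out-of-fold predictions under k-fold cross-validation,
#' and the ensemble predicts by majority vote over the top-n bases, with n
#' chosen to maximize out-of-fold ensemble F1.
NULL

#' Base classifier specification
#'
#' @param accession descriptor accession the base is trained on.
#' @param learner `"knn"` or `"svm_rbf"`.
#' @param hyper named list of hyperparameters: `k` (neighbour count,
#'   default 5) for KNN; `cost` (default 1) and `gamma` (default
#'   1/feature-dimension, the libsvm default) for the SVM.
#' @return object of class `base_spec`.
#' @export
base_spec <- function(accession, learner = c("knn", "svm_rbf"), hyper = list()) {
  learner <- match.arg(learner)
  defaults <- if (learner == "knn") list(k = 5L) else list(cost = 1, gamma = NULL)
  hyper <- utils::modifyList(defaults, hyper)
  structure(list(accession = accession, learner = learner, hyper = hyper),
            class = "base_spec")
}

# Column-wise standardization parameters from training rows only.
standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_standardizer <- function(x, s) sweep(sweep(x, 2, s$mu), 2, s$sd, "/")

# Fit one base learner on (already subset) rows. Standardization is part of
# the fit: parameters come from these rows only.
fit_base <- function(x, y, spec) {
  if (length(unique(y)) < 2L)
    stop("degenerate training fold: only one class present")
  s <- standardizer(x)
  xs <- apply_standardizer(x, s)
  fit <- switch(spec$learner,
    knn = list(train = xs, y = y),
    svm_rbf = {
      gamma <- if (is.null(spec$hyper$gamma)) 1 / ncol(x) else spec$hyper$gamma
      e1071::svm(xs, y, kernel = "radial", cost = spec$hyper$cost,
                 gamma = gamma, scale = FALSE)
    })
  structure(list(spec = spec, scaler = s, fit = fit), class = "base_fit")
}

# Predict labels + hot-oriented scores for new rows.
predict_base <- function(bf, newx) {
  xs <- apply_standardizer(newx, bf$scaler)
  if (bf$spec$learner == "knn") {
    # pinned RNG: class::knn breaks distance ties at random, and the whole
    # pipeline must be reproducible bit-for-bit
    pr <- with_seed(0L, class::knn(bf$fit$train, xs, bf$fit$y,
                                   k = bf$spec$hyper$k, prob = TRUE))
    win <- attr(pr, "prob")
    score <- ifelse(pr == "hot", win, 1 - win)
    list(label = factor(as.character(pr), levels = c("nonhot", "hot")),
         score = as.numeric(score))
  } else {
    pr <- stats::predict(bf$fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    sgn <- if (startsWith(colnames(dv)[1], "hot")) 1 else -1
    list(label = factor(as.character(pr), levels = c("nonhot", "hot")),
         score = as.numeric(sgn * dv[, 1]))
  }
}

#' Cross-validation fold assignment
#'
#' Folds are as equal in size as possible (sizes differ by at most one) and,
#' when stratified, each class is spread across folds so per-fold class
#' counts differ by at most one; classes are interleaved so the total sizes
#' stay balanced. Deterministic given `seed`.
#'
#' @param labels `"hot"`/`"nonhot"` vector (or a [residue_dataset], whose
#'   labels are used).
#' @param k number of folds, default 10.
#' @param seed RNG seed for the within-class shuffles.
#' @param stratified preserve the class ratio per fold? Default `TRUE`.
#' @return integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  if (inherits(labels, "residue_dataset")) labels <- labels$residues$label
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer samples than folds")
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      load <- integer(k)   # current fold sizes, to balance totals
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop("class '", cl, "' has fewer than k samples; ",
               "use stratified = FALSE")
        idx <- sample(idx)
        ord <- order(load, seq_len(k))   # fill emptiest folds first
        assign_to <- rep(ord, length.out = length(idx))
        folds[idx] <- assign_to
        load <- load + tabulate(assign_to, nbins = k)
      }
    } else {
      folds <- sample(rep(seq_len(k), length.out = n))
    }
  })
  folds
}

#' Train one base classifier with out-of-fold prediction
#'
#' For each fold, the base is fitted on the remaining folds (feature
#' standardization computed from those folds only) and predicts the held-out
#' fold; the concatenated out-of-fold predictions cover every residue
#' exactly once and yield the base's F1.
#'
#' @param fm a `feature_matrix` from [build_feature_matrices].
#' @param spec a [base_spec].
#' @param folds integer fold assignment aligned with `fm` rows.
#' @return object of class `trained_base`: `spec`, `oof_pred` (factor),
#'   `oof_score` (numeric, hot-oriented), `f1`.
#' @export
train_base <- function(fm, spec, folds) {
  y <- fm$labels
  n <- nrow(fm$x)
  if (length(folds) != n) stop("fold assignment does not match matrix rows")
  oof_pred <- factor(rep(NA_character_, n), levels = c("nonhot", "hot"))
  oof_score <- numeric(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    bf <- fit_base(fm$x[tr, , drop = FALSE], y[tr], spec)
    pr <- predict_base(bf, fm$x[!tr, , drop = FALSE])
    oof_pred[!tr] <- pr$label
    oof_score[!tr] <- pr$score
  }
  f1 <- metrics_from_predictions(oof_pred, y)$f1
  structure(list(spec = spec, oof_pred = oof_pred, oof_score = oof_score,
                 f1 = f1),
            class = "trained_base")
}

#' Majority vote over base-classifier labels
#'
#' The label with strictly more votes wins; an exact tie is called
#' `"nonhot"` (the conservative call for a hot-spot screen).
#'
#' @param votes character/factor vector of `"hot"`/`"nonhot"` votes.
#' @return `"hot"` or `"nonhot"`.
#' @export
majority_vote <- function(votes) {
  votes <- as.character(votes)
  if (length(votes) == 0L) stop("empty vote list")
  if (2L * sum(votes == "hot") > length(votes)) "hot" else "nonhot"
}

#' Vote-fraction ensemble score
#'
#' The fraction of bases voting `"hot"`; exceeds 1/2 exactly when
#' [majority_vote] returns `"hot"`. Serves as the graded score behind the
#' ensemble's ROC curves.
#'
#' @inheritParams majority_vote
#' @return real in `[0, 1]`.
#' @export
ensemble_score <- function(votes) {
  votes <- as.character(votes)
  if (length(votes) == 0L) stop("empty vote list")
  mean(votes == "hot")
}

# Ranking order of trained bases: F1 descending; ties broken KNN before
# SVM, then by descriptor position in `acc_order`.
rank_bases <- function(bases, acc_order) {
  f1 <- vapply(bases, `[[`, numeric(1), "f1")
  learner <- vapply(bases, function(b) b$spec$learner, character(1))
  didx <- match(vapply(bases, function(b) b$spec$accession, character(1)),
                acc_order)
  order(-f1, match(learner, c("knn", "svm_rbf")), didx)
}

vote_matrix <- function(bases) {
  vapply(bases, function(b) as.character(b$oof_pred),
         character(length(bases[[1]]$oof_pred)))
}

#' Select the top-n voting ensemble
#'
#' Bases are ranked by out-of-fold F1 (ties: KNN before SVM, then descriptor
#' order); for each n in the grid the F1 of the majority vote of the top n
#' bases' out-of-fold predictions is computed, and the n with the highest F1
#' is selected (smallest n on ties).
#'
#' @param bases list of [train_base] results.
#' @param labels true labels aligned with the out-of-fold predictions.
#' @param n_grid candidate ensemble sizes; default odd 3..91 (odd sizes
#'   avoid vote ties). Values above the pool size are dropped.
#' @param acc_order descriptor accessions in table order (tie-breaking);
#'   defaults to first-appearance order in `bases`.
#' @return list with `order` (ranking permutation of `bases`),
#'   `n_selected`, `f1_by_n` (data.frame `n`, `f1`), `oof_pred`,
#'   `oof_score` and `f1` of the selected ensemble.
#' @export
select_top_n <- function(bases, labels, n_grid = seq(3L, 91L, by = 2L),
                         acc_order = NULL) {
  if (length(bases) == 0L) stop("no base classifiers")
  if (is.null(acc_order))
    acc_order <- unique(vapply(bases, function(b) b$spec$accession, character(1)))
  n_grid <- sort(unique(as.integer(n_grid)))
  n_grid <- n_grid[n_grid >= 1L & n_grid <= length(bases)]
  if (length(n_grid) == 0L) stop("empty n grid after clipping to pool size")
  ord <- rank_bases(bases, acc_order)
  votes <- vote_matrix(bases[ord])
  labels <- as.character(labels)

  trace <- lapply(n_grid, function(n) {
    v <- votes[, seq_len(n), drop = FALSE]
    pred <- apply(v, 1, majority_vote)
    list(n = n, f1 = metrics_from_predictions(pred, labels)$f1)
  })
  f1s <- vapply(trace, `[[`, numeric(1), "f1")
  best <- n_grid[which.max(f1s)]          # smallest n on ties

  v <- votes[, seq_len(best), drop = FALSE]
  list(order = ord,
       n_selected = best,
       f1_by_n = data.frame(n = n_grid, f1 = f1s),
       oof_pred = factor(apply(v, 1, majority_vote), levels = c("nonhot", "hot")),
       oof_score = apply(v, 1, ensemble_score),
       f1 = max(f1s))
}

default_base_specs <- function(table, knn_k = 5L, svm_cost = 1, svm_gamma = NULL) {
  accs <- accessions(table)
  c(lapply(accs, base_spec, learner = "knn", hyper = list(k = knn_k)),
    lapply(accs, base_spec, learner = "svm_rbf",
           hyper = list(cost = svm_cost, gamma = svm_gamma)))
}

#' Train the full hot-spot voting ensemble
#'
#' Runs the complete training protocol: per-descriptor feature matrices,
#' stratified k-fold cross-validation of every KNN and SVM base, F1 ranking,
#' top-n selection by out-of-fold ensemble F1, and a final refit of the
#' selected bases on all training residues (the deployed model).
#'
#' @param dataset training [residue_dataset].
#' @param table [property_table]; min-max normalized automatically unless
#'   already so.
#' @param config an [encoding_config].
#' @param relasa optional relASA table (see [build_feature_matrices]).
#' @param folds_k number of cross-validation folds, default 10.
#' @param seed fold-assignment seed.
#' @param n_grid candidate ensemble sizes (see [select_top_n]).
#' @param knn_k,svm_cost,svm_gamma base-learner hyperparameters (see
#'   [base_spec]).
#' @return object of class `hotspot_ensemble`: the normalized table, the
#'   encoding config, the ranked base metadata (accession, learner, F1),
#'   `n_selected`, the refitted base fits, out-of-fold predictions/scores
#'   and training metrics.
#' @export
train_hotspot_ensemble <- function(dataset, table = hotspot_properties(),
                                   config = encoding_config(),
                                   relasa = NULL, folds_k = 10L, seed = 1L,
                                   n_grid = seq(3L, 91L, by = 2L),
                                   knn_k = 5L, svm_cost = 1, svm_gamma = NULL) {
  if (table$normalization == "none") table <- normalize_properties(table, "minmax")
  fms <- build_feature_matrices(dataset, table, config, relasa)
  labels <- fms[[1]]$labels
  folds <- make_folds(as.character(labels), k = folds_k, seed = seed)
  specs <- default_base_specs(table, knn_k, svm_cost, svm_gamma)
  bases <- lapply(specs, function(sp) train_base(fms[[sp$accession]], sp, folds))
  sel <- select_top_n(bases, labels, n_grid, acc_order = accessions(table))

  top <- bases[sel$order[seq_len(sel$n_selected)]]
  fits <- lapply(top, function(b)
    fit_base(fms[[b$spec$accession]]$x, fms[[b$spec$accession]]$labels, b$spec))
  sel_accs <- unique(vapply(top, function(b) b$spec$accession, character(1)))
  train_x <- lapply(fms[sel_accs], `[[`, "x")

  ranked <- data.frame(
    accession = vapply(bases[sel$order], function(b) b$spec$accession, character(1)),
    learner = vapply(bases[sel$order], function(b) b$spec$learner, character(1)),
    f1 = vapply(bases[sel$order], `[[`, numeric(1), "f1"))

  m <- metrics_from_predictions(sel$oof_pred, labels)
  auc <- roc_auc(sel$oof_score, as.character(labels))$auc
  structure(list(table = table, config = config,
                 ranked_bases = ranked, n_selected = sel$n_selected,
                 f1_by_n = sel$f1_by_n,
                 fits = fits, train_x = train_x,
                 train_labels = labels, folds = folds, seed = seed,
                 oof_pred = sel$oof_pred, oof_score = sel$oof_score,
                 train_metrics = m, train_auc = auc,
                 hyper = list(knn_k = knn_k, svm_cost = svm_cost,
                              svm_gamma = svm_gamma, folds_k = folds_k)),
            class = "hotspot_ensemble")
}

#' @export
print.hotspot_ensemble <- function(x, ...) {
  cat(sprintf("hotspot_ensemble: top %d of %d bases (M = %d%s), oof F1 %.4f, AUC %.4f\n",
              x$n_selected, nrow(x$ranked_bases), x$config$m,
              if (x$config$include_relasa) " + relASA" else "",
              x$train_metrics$f1, x$train_auc))
  invisible(x)
}

#' Predict hot spots with a trained ensemble
#'
#' Encodes the query residues with the model's own property table and
#' encoding configuration, lets each stored base vote, and reports the
#' majority label together with the hot-vote fraction.
#'
#' @param object a `hotspot_ensemble`.
#' @param dataset query [residue_dataset].
#' @param relasa optional relASA table (required if the model encodes it and
#'   the dataset carries no `relasa` column).
#' @param ... unused.
#' @return data.frame: residue keys, `label` (true label, if present),
#'   `pred`, `score`.
#' @export
predict.hotspot_ensemble <- function(object, dataset, relasa = NULL, ...) {
  fms <- build_feature_matrices(dataset, object$table, object$config, relasa)
  votes <- vapply(object$fits, function(bf)
    as.character(predict_base(bf, fms[[bf$spec$accession]]$x)$label),
    character(nrow(dataset$residues)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  data.frame(fms[[1]]$keys,
             label = as.character(fms[[1]]$labels),
             pred = apply(votes, 1, majority_vote),
             score = apply(votes, 1, ensemble_score),
             stringsAsFactors = FALSE)
}

#' Scan the auto-correlation depth M
#'
#' Trains a full ensemble for every candidate M and reports the
#' out-of-fold-F1-maximizing value together with the whole trace.
#'
#' @inheritParams train_hotspot_ensemble
#' @param m_grid candidate M values, default `c(3, 7, 11, 15, 19)`.
#' @param include_relasa,pad_value forwarded to [encoding_config].
#' @param ... forwarded to [train_hotspot_ensemble].
#' @return list with `best_m` (smallest argmax-F1 M) and `trace`
#'   (data.frame `m`, `f1`, `n_selected`).
#' @export
select_m <- function(dataset, table = hotspot_properties(),
                     m_grid = c(3L, 7L, 11L, 15L, 19L),
                     include_relasa = TRUE, pad_value = 1.0, ...) {
  m_grid <- sort(unique(as.integer(m_grid)))
  rows <- lapply(m_grid, function(m) {
    fit <- train_hotspot_ensemble(
      dataset, table,
      config = encoding_config(m, pad_value, include_relasa), ...)
    data.frame(m = m, f1 = fit$train_metrics$f1, n_selected = fit$n_selected)
  })
  trace <- do.call(rbind, rows)
  list(best_m = trace$m[which.max(trace$f1)], trace = trace)
}
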