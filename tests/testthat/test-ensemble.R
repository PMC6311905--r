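test_that("make_folds balances sizes and classes and is deterministic", {
  labels <- rep(c("hot", "nonhot"), c(58, 91))   # the training-corpus margins
  f <- make_folds(labels, k = 10, seed = 1)
  sizes <- tabulate(f, 10)
  expect_equal(sort(sizes), c(14, rep(15, 9)))
  expect_equal(make_folds(labels, k = 10, seed = 1), f)
  expect_false(identical(make_folds(labels, k = 10, seed = 2), f))

  # stratification: per-fold positive count within 1 of the proportional share
  labels2 <- rep(c("hot", "nonhot"), c(40, 60))
  f2 <- make_folds(labels2, k = 10, seed = 3)
  pos <- tabulate(f2[labels2 == "hot"], 10)
  expect_true(all(abs(pos - 4) <= 1))
  expect_true(all(abs(tabulate(f2, 10) - 10) <= 1))

  expect_error(make_folds(rep(c("hot", "nonhot"), c(3, 97)), k = 10, seed = 1),
               "stratified = FALSE")
  f3 <- make_folds(rep(c("hot", "nonhot"), c(3, 97)), k = 10, seed = 1,
                   stratified = FALSE)
  expect_true(all(abs(tabulate(f3, 10) - 10) <= 1))
})

test_that("majority_vote and ensemble_score agree with the documented tie rule", {
  expect_equal(majority_vote(c("hot", "hot", "nonhot")), "hot")
  expect_equal(majority_vote(c("hot", "nonhot")), "nonhot")   # tie -> nonhot
  expect_equal(majority_vote(rep("hot", 7)), "hot")
  expect_equal(majority_vote(rep("nonhot", 4)), "nonhot")
  expect_error(majority_vote(character(0)), "empty")

  expect_equal(ensemble_score(rep("hot", 5)), 1.0)
  expect_equal(ensemble_score(c("hot", "nonhot", "hot", "nonhot")), 0.5)
  # score > 1/2 exactly when the majority vote is hot
  set.seed(6)
  for (i in 1:50) {
    v <- sample(c("hot", "nonhot"), sample(1:9, 1), TRUE)
    expect_equal(ensemble_score(v) > 0.5, majority_vote(v) == "hot")
  }
  # voting is permutation-invariant
  v <- c("hot", "hot", "nonhot", "hot", "nonhot")
  expect_equal(majority_vote(sample(v)), majority_vote(v))
})

test_that("train_base reaches F1 = 1 on linearly separable data for both learners", {
  set.seed(9)
  n <- 60
  labels <- factor(rep(c("hot", "nonhot"), each = n / 2),
                   levels = c("nonhot", "hot"))
  x <- cbind(rnorm(n, ifelse(labels == "hot", 3, -3), 0.3), rnorm(n))
  colnames(x) <- c("r1", "r2")
  fm <- structure(list(accession = "SEP000001", x = x,
                       keys = data.frame(complex_id = "C", chain = "A",
                                         position = seq_len(n)),
                       labels = labels), class = "feature_matrix")
  folds <- make_folds(as.character(labels), k = 5, seed = 2)
  for (learner in c("knn", "svm_rbf")) {
    tb <- train_base(fm, base_spec("SEP000001", learner), folds)
    expect_equal(tb$f1, 1.0)
    expect_equal(as.character(tb$oof_pred), as.character(labels))
    # oof scores separate the classes too
    expect_equal(roc_auc(tb$oof_score, as.character(labels))$auc, 1.0)
  }
})

test_that("1-NN reproduces the labels of exact duplicates across folds", {
  set.seed(10)
  proto <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("r1", "r2")))
  labels <- factor(rep(c("hot", "nonhot"), 5), levels = c("nonhot", "hot"))
  fm <- structure(list(accession = "DUP000001",
                       x = rbind(proto, proto),
                       keys = data.frame(complex_id = "C", chain = "A",
                                         position = 1:20),
                       labels = c(labels, labels)), class = "feature_matrix")
  tb <- train_base(fm, base_spec("DUP000001", "knn", hyper = list(k = 1)),
                   folds = rep(c(1, 2), each = 10))
  expect_equal(tb$f1, 1.0)
})

test_that("a base trained on permuted labels stays at the class-ratio baseline", {
  set.seed(12)
  n <- 100
  labels <- factor(rep(c("hot", "nonhot"), each = n / 2),
                   levels = c("nonhot", "hot"))
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("r", 1:4)))
  folds <- make_folds(as.character(labels), k = 5, seed = 3)
  f1s <- sapply(1:20, function(i) {
    set.seed(100 + i)
    fm <- structure(list(accession = "NUL000001", x = x,
                         keys = data.frame(complex_id = "C", chain = "A",
                                           position = seq_len(n)),
                         labels = sample(labels)), class = "feature_matrix")
    train_base(fm, base_spec("NUL000001", "knn"), folds)$f1
  })
  null <- permutation_null_f1(as.character(labels), n_perm = 500, seed = 4)
  expect_lt(abs(mean(f1s) - mean(null)), 3 * sd(null))
})

test_that("degenerate single-class training folds are an error", {
  labels <- factor(rep(c("hot", "nonhot"), c(2, 8)), levels = c("nonhot", "hot"))
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("r1", "r2")))
  fm <- structure(list(accession = "DEG000001", x = x,
                       keys = data.frame(complex_id = "C", chain = "A",
                                         position = 1:10),
                       labels = labels), class = "feature_matrix")
  # fold 1 holds all the hot residues -> training fold 2 sees one class
  expect_error(train_base(fm, base_spec("DEG000001", "knn"),
                          folds = rep(c(2, 1), c(2, 8))),
               "degenerate|one class")
})

test_that("select_top_n selects the argmax n and degenerates correctly", {
  set.seed(14)
  n <- 40
  labels <- sample(c("hot", "nonhot"), n, TRUE)
  accs <- sprintf("ACC%06d", 1:5)
  perfect <- fake_base(accs[1], "knn", labels, labels)
  mediocre <- lapply(2:5, function(i)
    fake_base(accs[i], "svm_rbf",
              ifelse(runif(n) < 0.5, labels, sample(labels)), labels))
  sel <- select_top_n(c(list(perfect), mediocre), labels, n_grid = c(1, 3),
                      acc_order = accs)
  expect_equal(sel$n_selected, 1L)
  expect_equal(as.character(sel$oof_pred), labels)
  expect_equal(sel$f1, 1.0)

  # identical bases: F1 constant in n, smallest grid value wins
  same <- lapply(1:5, function(i)
    fake_base(accs[i], "knn", ifelse(runif(n) < 0.8, labels, "hot"), labels))
  for (i in 2:5) { same[[i]]$oof_pred <- same[[1]]$oof_pred
                   same[[i]]$f1 <- same[[1]]$f1 }
  sel2 <- select_top_n(same, labels, n_grid = c(1, 3, 5), acc_order = accs)
  expect_equal(sel2$n_selected, 1L)
  expect_equal(length(unique(sel2$f1_by_n$f1)), 1L)
})

test_that("select_top_n matches an exhaustive brute-force grid scan", {
  set.seed(15)
  n <- 60
  labels <- sample(c("hot", "nonhot"), n, TRUE, prob = c(0.4, 0.6))
  accs <- sprintf("ACC%06d", 1:5)
  pool <- unlist(lapply(1:5, function(i) lapply(c("knn", "svm_rbf"), function(l) {
    acc_rate <- runif(1, 0.55, 0.95)
    fake_base(accs[i], l, ifelse(runif(n) < acc_rate, labels, sample(labels)),
              labels)
  })), recursive = FALSE)
  grid <- c(1, 3, 5, 7, 9)
  sel <- select_top_n(pool, labels, n_grid = grid, acc_order = accs)
  want <- brute_select(pool, labels, grid, accs)
  expect_equal(sel$n_selected, want$n)
  expect_equal(sel$f1_by_n$f1, want$f1s)
  # argmax property: selected F1 >= F1 at every grid n
  expect_true(all(sel$f1 >= sel$f1_by_n$f1))
  expect_equal(sel$f1, max(sel$f1_by_n$f1))
})

test_that("the full pipeline is reproducible and transfers to held-out data", {
  rc <- recovery_study_config(seed = 3)
  gen <- generate_synthetic(rc$config, rc$table)
  cfg <- encoding_config(5)
  fit1 <- train_hotspot_ensemble(gen$dataset, rc$table, cfg,
                                 folds_k = 5, seed = 11, n_grid = seq(1, 9, 2))
  fit2 <- train_hotspot_ensemble(gen$dataset, rc$table, cfg,
                                 folds_k = 5, seed = 11, n_grid = seq(1, 9, 2))
  expect_identical(fit1$ranked_bases, fit2$ranked_bases)
  expect_identical(fit1$oof_pred, fit2$oof_pred)
  expect_identical(fit1$n_selected, fit2$n_selected)

  held <- generate_synthetic(
    synthetic_config(n_chains = 3, chain_length = 100, n_sites_per_chain = 30,
                     hot_fraction = 0.4,
                     signal_descriptors = rc$config$signal_descriptors,
                     signal_strength = 8, noise_sd = 0.05, m = 5, seed = 99),
    rc$table)
  p1 <- predict(fit1, held$dataset)
  p2 <- predict(fit1, held$dataset)
  expect_identical(p1, p2)
  # planted signal is recoverable out of sample
  expect_gt(metrics_from_predictions(p1$pred, p1$label)$f1, 0.7)
  # vote-fraction score is consistent with the hard vote
  expect_equal(p1$pred == "hot", p1$score > 0.5)
})

test_that("a saved model predicts identically after reloading", {
  rc <- recovery_study_config(seed = 5)
  gen <- generate_synthetic(rc$config, rc$table)
  fit <- train_hotspot_ensemble(gen$dataset, rc$table, encoding_config(5),
                                folds_k = 5, seed = 2, n_grid = c(1, 3, 5))
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- load_model(dir)
  expect_equal(back$n_selected, fit$n_selected)
  expect_equal(back$ranked_bases$f1, fit$ranked_bases$f1, tolerance = 1e-12)
  p_orig <- predict(fit, gen$dataset)
  p_back <- predict(back, gen$dataset)
  expect_equal(p_back$pred, p_orig$pred)
  expect_equal(p_back$score, p_orig$score)
})

test_that("select_m returns the argmax M with a full trace", {
  rc <- recovery_study_config(seed = 8)
  gen <- generate_synthetic(rc$config, rc$table)
  one <- select_m(gen$dataset, rc$table, m_grid = 5, folds_k = 5, seed = 1,
                  n_grid = c(1, 3, 5))
  expect_equal(one$best_m, 5L)
  expect_equal(nrow(one$trace), 1L)

  res <- select_m(gen$dataset, rc$table, m_grid = c(3, 5, 7), folds_k = 5,
                  seed = 1, n_grid = c(1, 3, 5))
  expect_equal(nrow(res$trace), 3L)
  expect_equal(res$best_m, res$trace$m[which.max(res$trace$f1)])
})
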