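# Shared fixtures, built in code.

aa20 <- hotspotter:::AA_ORDER

# Small property table with reproducible random descriptors.
random_property_table <- function(n = 5, seed = 1, prefix = "RND") {
  set.seed(seed)
  v <- matrix(rnorm(20 * n), nrow = 20,
              dimnames = list(aa20, sprintf("%s%06d", prefix, seq_len(n))))
  property_table(v)
}

# Minimal AAindex1 flat-file text for parser tests (synthetic descriptor
# values, not catalogue entries).
aaindex_entry_text <- function(accession, values, description = "synthetic test entry") {
  c(paste("H", accession),
    paste("D", description),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("   ", paste(values[1:10], collapse = "  ")),
    paste0("   ", paste(values[11:20], collapse = "  ")),
    "//")
}

write_aaindex_text <- function(entries) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(unlist(entries), path)
  path
}

# Tiny labeled dataset on two chains, with deterministic sequences.
toy_dataset <- function(seed = 7, n_per_chain = 12, chain_len = 40) {
  set.seed(seed)
  seqs <- c(CPLX1_A = paste(sample(aa20, chain_len, TRUE), collapse = ""),
            CPLX2_B = paste(sample(aa20, chain_len, TRUE), collapse = ""))
  res <- do.call(rbind, lapply(names(seqs), function(k) {
    pos <- sort(sample.int(chain_len, n_per_chain))
    data.frame(complex_id = sub("_.*", "", k),
               chain = sub(".*_", "", k),
               position = pos,
               wild_type = substr(rep(seqs[[k]], n_per_chain), pos, pos),
               relasa = runif(n_per_chain),
               label = sample(c("hot", "nonhot"), n_per_chain, TRUE),
               stringsAsFactors = FALSE)
  }))
  residue_dataset(res, sequences = seqs, name = "toy")
}

# Literal term-by-term evaluation of the windowed auto-correlation: the
# independent oracle for the encoder.
oracle_autocorr <- function(h, m) {
  L <- length(h)
  r <- numeric(m)
  for (j in 1:m) {
    s <- 0
    for (l in 1:(L - j)) s <- s + h[l] * h[l + j]
    r[j] <- s / (L - 1)
  }
  r
}

oracle_encode <- function(seq_values, center, m, pad = 1.0) {
  window <- numeric(2 * m + 1)
  for (o in -m:m) {
    p <- center + o
    window[o + m + 1] <- if (p >= 1 && p <= length(seq_values)) seq_values[p] else pad
  }
  oracle_autocorr(window, m)
}

# Direct evaluation of the printed metric formulas.
oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  pre <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  list(acc = (tp + tn) / (tp + fp + tn + fn),
       spe = div(tn, tn + fp),
       recall = rec, pre = pre,
       f1 = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec),
       mcc = {
         den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
         if (den == 0) 0 else (tp * tn - fp * fn) / den
       })
}

# A fake trained base with chosen out-of-fold predictions.
fake_base <- function(accession, learner, oof_pred, labels, score = NULL) {
  structure(list(
    spec = base_spec(accession, learner),
    oof_pred = factor(oof_pred, levels = c("nonhot", "hot")),
    oof_score = if (is.null(score)) as.numeric(oof_pred == "hot") else score,
    f1 = metrics_from_predictions(oof_pred, labels)$f1),
    class = "trained_base")
}

# Independent re-implementation of the ranked top-n grid scan.
brute_select <- function(bases, labels, n_grid, acc_order) {
  f1 <- sapply(bases, `[[`, "f1")
  lrn <- sapply(bases, function(b) b$spec$learner)
  didx <- match(sapply(bases, function(b) b$spec$accession), acc_order)
  ord <- order(-f1, ifelse(lrn == "knn", 1, 2), didx)
  f1s <- sapply(n_grid, function(n) {
    votes <- sapply(bases[ord[1:n]], function(b) as.character(b$oof_pred))
    pred <- apply(votes, 1, function(v) {
      if (sum(v == "hot") > length(v) / 2) "hot" else "nonhot"
    })
    metrics_from_predictions(pred, labels)$f1
  })
  list(n = n_grid[which.max(f1s)], f1s = f1s)
}

# All-pairs AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "hot"]; neg <- scores[labels != "hot"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
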