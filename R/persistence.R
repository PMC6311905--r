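#' @title Plain-text model persistence
#' @name model_persistence
#' @description
#' A trained ensemble is stored as a directory of plain-text files: a
#' versioned key-value manifest (encoding configuration, hyperparameters,
#' seed, the ranked base list with F1 scores, n), the normalized property
#' table, and one feature TSV per selected descriptor holding the training
#' rows. Loading refits the selected bases from the stored rows — both
#' learners are deterministic given data and hyperparameters, so the
#' reloaded model reproduces the saved one's predictions exactly.
NULL

MODEL_FORMAT_VERSION <- "1"

#' Save a trained ensemble
#' @param model a `hotspot_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- c(
    paste0("format_version=", MODEL_FORMAT_VERSION),
    paste0("package_version=", as.character(utils::packageVersion("hotspotter"))),
    paste0("m=", model$config$m),
    paste0("pad_value=", model$config$pad_value),
    paste0("include_relasa=", model$config$include_relasa),
    paste0("normalization=", model$table$normalization),
    paste0("provenance=", model$table$provenance),
    paste0("n_selected=", model$n_selected),
    paste0("seed=", model$seed),
    paste0("folds_k=", model$hyper$folds_k),
    paste0("knn_k=", model$hyper$knn_k),
    paste0("svm_cost=", model$hyper$svm_cost),
    paste0("svm_gamma=", if (is.null(model$hyper$svm_gamma)) "auto"
           else model$hyper$svm_gamma),
    paste0("base=", model$ranked_bases$accession, ",",
           model$ranked_bases$learner, ",",
           formatC(model$ranked_bases$f1, format = "g", digits = 17)))
  writeLines(man, file.path(dir, "manifest.txt"))
  write_property_tsv(model$table, file.path(dir, "properties.tsv"))
  for (acc in names(model$train_x)) {
    df <- cbind(as.data.frame(model$train_x[[acc]]),
                label = as.character(model$train_labels))
    utils::write.table(df, file.path(dir, paste0("train_", acc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a saved ensemble
#' @param dir directory written by [save_model].
#' @return a `hotspot_ensemble` whose predictions match the saved model's.
#' @export
load_model <- function(dir) {
  man_lines <- readLines(file.path(dir, "manifest.txt"))
  kv <- strsplit(man_lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  get1 <- function(k) vals[keys == k][1]
  if (get1("format_version") != MODEL_FORMAT_VERSION)
    stop("unsupported model format version: ", get1("format_version"))
  config <- encoding_config(as.integer(get1("m")),
                            as.numeric(get1("pad_value")),
                            as.logical(get1("include_relasa")))
  table <- read_property_tsv(file.path(dir, "properties.tsv"))
  table$normalization <- get1("normalization")
  table$provenance <- get1("provenance")
  bases <- do.call(rbind, lapply(strsplit(vals[keys == "base"], ","), function(p)
    data.frame(accession = p[1], learner = p[2], f1 = as.numeric(p[3]))))
  n_selected <- as.integer(get1("n_selected"))
  svm_gamma <- get1("svm_gamma")
  svm_gamma <- if (svm_gamma == "auto") NULL else as.numeric(svm_gamma)
  hyper <- list(knn_k = as.integer(get1("knn_k")),
                svm_cost = as.numeric(get1("svm_cost")),
                svm_gamma = svm_gamma,
                folds_k = as.integer(get1("folds_k")))

  fits <- lapply(seq_len(n_selected), function(i) {
    acc <- bases$accession[i]
    df <- utils::read.delim(file.path(dir, paste0("train_", acc, ".tsv")),
                            check.names = FALSE)
    x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
    y <- factor(df$label, levels = c("nonhot", "hot"))
    sp <- base_spec(acc, bases$learner[i],
                    hyper = if (bases$learner[i] == "knn")
                      list(k = hyper$knn_k)
                    else list(cost = hyper$svm_cost, gamma = hyper$svm_gamma))
    fit_base(x, y, sp)
  })
  sel_accs <- unique(bases$accession[seq_len(n_selected)])
  train_x <- lapply(sel_accs, function(acc) {
    df <- utils::read.delim(file.path(dir, paste0("train_", acc, ".tsv")),
                            check.names = FALSE)
    as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  })
  names(train_x) <- sel_accs
  lab_df <- utils::read.delim(file.path(dir, paste0("train_", sel_accs[1], ".tsv")),
                              check.names = FALSE)
  structure(list(table = table, config = config,
                 ranked_bases = bases, n_selected = n_selected,
                 fits = fits, train_x = train_x,
                 train_labels = factor(lab_df$label, levels = c("nonhot", "hot")),
                 seed = as.integer(get1("seed")),
                 hyper = hyper),
            class = "hotspot_ensemble")
}
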