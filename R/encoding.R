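#' @title Auto-correlation residue encoding
#' @name residue_encoding
#' @description
#' Each residue is represented, per descriptor, by the auto-correlation of
#' the descriptor's value profile inside a sliding window centred on the
#' residue. The window has length `W = 2M + 1`; positions hanging over a
#' chain end are filled with a pad value (1.0 by default, the top of a
#' min-max-normalized descriptor's range). The auto-correlation at lag `j`
#' of a window `h_1..h_W` is
#' \deqn{r_j = \frac{1}{W-1} \sum_{l=1}^{W-j} h_l \, h_{l+j}, \quad j = 1..M,}
#' so each residue yields `M` features per descriptor, optionally followed
#' by its relative accessible surface area.
NULL

#' Encoding configuration
#'
#' @param m number of auto-correlation lags (window length is `2m + 1`);
#'   default 11, giving a 23-residue window.
#' @param pad_value value used for window positions beyond either chain end;
#'   default 1.0 (assumes min-max-normalized descriptor values).
#' @param include_relasa append the residue's relative accessible surface
#'   area as a final feature column? Default `TRUE`.
#' @return an object of class `encoding_config`.
#' @export
encoding_config <- function(m = 11L, pad_value = 1.0, include_relasa = TRUE) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  if (!is.finite(pad_value)) stop("pad_value must be finite")
  structure(list(m = m, window = 2L * m + 1L, pad_value = pad_value,
                 include_relasa = isTRUE(include_relasa)),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf("encoding_config: M = %d (window %d), pad = %g, relASA %s\n",
              x$m, x$window, x$pad_value,
              if (x$include_relasa) "appended" else "off"))
  invisible(x)
}

#' Auto-correlation of a numeric sequence
#'
#' @param h numeric sequence of length `L >= 2`.
#' @param m number of lags, `1 <= m <= L - 1`.
#' @return numeric vector `r_1..r_m` with
#'   `r_j = sum(h[1:(L-j)] * h[(1+j):L]) / (L - 1)`.
#' @export
autocorrelation <- function(h, m) {
  L <- length(h)
  if (L < 2L) stop("sequence must have length >= 2")
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > L - 1L)
    stop("m must satisfy 1 <= m <= length(h) - 1")
  if (anyNA(h)) stop("non-finite values in sequence")
  vapply(seq_len(m),
         function(j) sum(h[seq_len(L - j)] * h[seq_len(L - j) + j]) / (L - 1),
         numeric(1))
}

#' Encode one residue from its chain's property profile
#'
#' Extracts the window of length `2m + 1` centred on `center` from the
#' per-residue property values of a chain, pads positions beyond either end
#' with `config$pad_value`, and returns the window's auto-correlation at
#' lags `1..m`.
#'
#' @param seq_values numeric vector: the property value of each residue of
#'   the chain, in sequence order.
#' @param center 1-based position of the residue to encode.
#' @param config an [encoding_config].
#' @return numeric vector of length `config$m`.
#' @export
encode_residue <- function(seq_values, center, config) {
  stopifnot(inherits(config, "encoding_config"))
  n <- length(seq_values)
  if (center < 1L || center > n) stop("center outside the chain")
  idx <- (center - config$m):(center + config$m)
  window <- ifelse(idx < 1L | idx > n, config$pad_value, seq_values[pmax(pmin(idx, n), 1L)])
  autocorrelation(window, config$m)
}

#' Build per-descriptor feature matrices for a labeled dataset
#'
#' For every descriptor in `table`, each chain sequence is mapped to the
#' descriptor's per-residue values (letters outside the 20 canonical codes
#' take the descriptor's mean), every labeled residue is encoded with
#' [encode_residue], and, when `config$include_relasa`, the residue's
#' relative accessible surface area is appended as a final column. Rows are
#' aligned across descriptors (same residue order everywhere).
#'
#' @param dataset a [residue_dataset]; every residue must resolve to a
#'   sequence.
#' @param table a [property_table] (normally min-max normalized).
#' @param config an [encoding_config].
#' @param relasa optional data.frame as returned by [read_netsurfp]
#'   (`chain` keys of the form `complex_chain`); if `NULL`, the dataset's
#'   own `relasa` column is used when required.
#' @return named list of `feature_matrix` objects, one per descriptor:
#'   each has `accession`, `x` (numeric matrix, rows = residues), `keys`
#'   (data.frame `complex_id`, `chain`, `position`) and `labels` (factor
#'   with levels `nonhot`, `hot`).
#' @export
build_feature_matrices <- function(dataset, table, config = encoding_config(),
                                   relasa = NULL) {
  stopifnot(inherits(dataset, "residue_dataset"),
            inherits(table, "property_table"))
  res <- dataset$residues
  skey <- chain_key(res$complex_id, res$chain)
  missing_seq <- !(skey %in% names(dataset$sequences))
  if (any(missing_seq))
    stop("no sequence for residue key(s): ",
         paste(unique(skey[missing_seq]), collapse = ", "))

  rsa <- NULL
  if (config$include_relasa) {
    if (!is.null(relasa)) {
      rk <- paste(relasa$chain, relasa$position, sep = "|")
      rsa <- relasa$relasa[match(paste(skey, res$position, sep = "|"), rk)]
    } else if ("relasa" %in% names(res)) {
      rsa <- res$relasa
    }
    if (is.null(rsa))
      stop("relASA required (include_relasa = TRUE) but none supplied")
    if (anyNA(rsa))
      stop("relASA missing for residue(s): ",
           paste(utils::head(paste0(skey, ":", res$position)[is.na(rsa)], 5),
                 collapse = ", "))
  }

  chains <- unique(skey)
  letters_by_chain <- lapply(dataset$sequences[chains], function(s) strsplit(s, "")[[1]])

  out <- lapply(seq_len(ncol(table$values)), function(d) {
    vals <- table$values[, d]
    fill <- mean(vals)
    profiles <- lapply(letters_by_chain, function(ltr) {
      v <- vals[ltr]
      v[is.na(v)] <- fill
      unname(v)
    })
    x <- t(vapply(seq_len(nrow(res)), function(i)
      encode_residue(profiles[[skey[i]]], res$position[i], config),
      numeric(config$m)))
    colnames(x) <- paste0("r", seq_len(config$m))
    if (config$include_relasa) {
      x <- cbind(x, relasa = rsa)
    }
    structure(list(accession = colnames(table$values)[d],
                   x = x,
                   keys = res[, c("complex_id", "chain", "position")],
                   labels = factor(res$label, levels = c("nonhot", "hot"))),
              class = "feature_matrix")
  })
  names(out) <- colnames(table$values)
  out
}

#' Serialize a feature matrix as TSV
#'
#' One row per residue: the key columns, the lag features `r1..rM`
#' (+ `relasa` when present) and the label.
#'
#' @param fm a `feature_matrix` from [build_feature_matrices].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- cbind(fm$keys, as.data.frame(fm$x), label = as.character(fm$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
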