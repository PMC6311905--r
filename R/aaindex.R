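#' @title Amino-acid property tables
#' @name property_table
#' @description
#' A property table holds an ordered set of amino-acid descriptors, one
#' numeric value per canonical residue type per descriptor. Descriptors come
#' from the AAindex1 catalogue (parsed from its flat-file format or taken from
#' the copy bundled with \pkg{seqinr}) and are the raw material for the
#' auto-correlation residue encoding.
NULL

# Canonical one-letter codes in AAindex column order (A/L, R/K, ... header).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a property table
#'
#' @param values numeric matrix, 20 rows (one per canonical amino acid, any
#'   row order as long as rownames are one-letter codes), one column per
#'   descriptor; column names are the descriptor accessions.
#' @param descriptions character vector of free-text descriptions, one per
#'   descriptor (recycled from `""` if omitted).
#' @param normalization `"none"` or `"minmax"`; records how `values` are
#'   scaled.
#' @param provenance character scalar identifying the source.
#'
#' @details Descriptors with missing values or zero variance are rejected:
#'   the Pearson correlations used downstream are undefined for them.
#'   Accessions must be unique; column order is preserved and is the
#'   table's canonical descriptor order.
#'
#' @return An object of class `property_table`: a list with elements
#'   `values` (20 x n matrix, rows in fixed A,R,N,...,V order),
#'   `descriptions`, `normalization`, `provenance`.
#' @export
property_table <- function(values, descriptions = NULL,
                           normalization = c("none", "minmax"),
                           provenance = "constructed") {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (nrow(values) != 20L)
    stop("property values must have 20 rows (one per canonical amino acid)")
  if (is.null(rownames(values)))
    rownames(values) <- AA_ORDER
  if (!setequal(rownames(values), AA_ORDER))
    stop("row names must be the 20 canonical one-letter codes")
  values <- values[AA_ORDER, , drop = FALSE]
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("descriptor accessions must be present and unique")
  if (anyNA(values))
    stop("missing values are not admitted in a property table: ",
         paste(colnames(values)[colSums(is.na(values)) > 0], collapse = ", "))
  vars <- apply(values, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance descriptors rejected (correlation undefined): ",
         paste(colnames(values)[vars == 0], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", ncol(values))
  structure(
    list(values = values,
         descriptions = stats::setNames(descriptions, colnames(values)),
         normalization = normalization,
         provenance = provenance),
    class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("property_table:", ncol(x$values), "descriptors,",
      "normalization =", x$normalization,
      "(", x$provenance, ")\n")
  invisible(x)
}

#' @export
length.property_table <- function(x) ncol(x$values)

#' Accessions of a property table
#' @param table a `property_table`
#' @return character vector of descriptor accessions in table order.
#' @export
accessions <- function(table) colnames(table$values)

#' Parse an AAindex1 flat file
#'
#' Reads the standard AAindex1 dialect: records delimited by `//`, with an
#' `H` line carrying the accession, a `D` line the description, and an `I`
#' line introducing two rows of ten values each in the conventional
#' `A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V` column layout.
#'
#' Entries containing `NA` values cannot take part in correlation analysis
#' and are excluded; their accessions are reported via a message and stored
#' in the `"excluded"` attribute of the result.
#'
#' @param path path to a flat file (or a connection readable by `readLines`).
#' @return a [property_table] with one descriptor per complete entry, in
#'   file order; attribute `"excluded"` lists accessions dropped for `NA`s.
#' @export
parse_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term <- grep("^//", lines)
  start <- c(1L, utils::head(term, -1L) + 1L)
  if (length(term) == 0L && any(nzchar(trimws(lines))))
    stop("no '//'-terminated entries found")
  recs <- Map(function(s, e) lines[s:e], start, term)

  parsed <- lapply(recs, parse_aaindex_record)
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(parsed) == 0L)
    stop("no complete AAindex entries in ", path)
  accs  <- vapply(parsed, `[[`, character(1), "accession")
  descs <- vapply(parsed, `[[`, character(1), "description")
  vals  <- vapply(parsed, `[[`, numeric(20), "values")
  rownames(vals) <- AA_ORDER
  colnames(vals) <- accs

  has_na <- colSums(is.na(vals)) > 0
  if (any(has_na))
    message("excluding ", sum(has_na), " entr",
            if (sum(has_na) == 1) "y" else "ies",
            " with NA values: ", paste(accs[has_na], collapse = ", "))
  tab <- property_table(vals[, !has_na, drop = FALSE],
                        descriptions = descs[!has_na],
                        provenance = if (is.character(path)) path else "stream")
  attr(tab, "excluded") <- accs[has_na]
  tab
}

parse_aaindex_record <- function(rec) {
  if (all(!nzchar(trimws(rec)))) return(NULL)
  h <- grep("^H ", rec, value = TRUE)
  if (length(h) == 0L)
    stop("malformed AAindex entry: no H record near line starting '",
         trimws(rec[1]), "'")
  accession <- trimws(sub("^H ", "", h[1]))
  d <- grep("^D ", rec)
  description <- if (length(d)) trimws(sub("^D ", "", rec[d[1]])) else ""
  i <- grep("^I ", rec)
  if (length(i) == 0L)
    stop("malformed AAindex entry ", accession, ": missing I record")
  if (i[1] + 2L > length(rec))
    stop("malformed AAindex entry ", accession, ": truncated value rows")
  toks <- unlist(strsplit(trimws(rec[(i[1] + 1L):(i[1] + 2L)]), "[[:space:]]+"))
  if (length(toks) != 20L)
    stop("malformed AAindex entry ", accession, ": expected 20 values, got ",
         length(toks), " (I record at record line ", i[1], ")")
  vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
  bad <- is.na(vals) & toks != "NA"
  if (any(bad))
    stop("malformed AAindex entry ", accession, ": non-numeric value(s) ",
         paste(toks[bad], collapse = ", "))
  list(accession = accession, description = description, values = vals)
}

#' Write a property table in AAindex1 flat-file format
#'
#' @param table a [property_table]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- table$values
  for (j in seq_len(ncol(v))) {
    writeLines(c(
      paste("H", colnames(v)[j]),
      paste("D", table$descriptions[j]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("   ", paste(formatC(v[1:10, j], format = "g", digits = 7), collapse = "  ")),
      paste0("   ", paste(formatC(v[11:20, j], format = "g", digits = 7), collapse = "  ")),
      "//"), con)
  }
  invisible(path)
}

#' Load the full AAindex1 catalogue
#'
#' Builds a [property_table] from the 544-entry AAindex1 copy distributed
#' with \pkg{seqinr}. Entries with missing values or zero variance are
#' dropped (they cannot enter correlation analysis), leaving 531 usable
#' descriptors.
#'
#' @param accessions optional character vector restricting (and ordering)
#'   the descriptors returned; unknown accessions are an error.
#' @return a [property_table].
#' @export
aaindex_catalogue <- function(accessions = NULL) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  accs  <- vapply(idx, `[[`, character(1), "H")
  descs <- vapply(idx, `[[`, character(1), "D")
  vals  <- vapply(idx, function(e) as.numeric(e$I), numeric(20))
  rownames(vals) <- unname(vapply(names(idx[[1]]$I), function(a3)
    seqinr::a(a3), character(1)))
  colnames(vals) <- accs
  if (!is.null(accessions)) {
    missing <- setdiff(accessions, accs)
    if (length(missing))
      stop("unknown AAindex accession(s): ", paste(missing, collapse = ", "))
    vals <- vals[, accessions, drop = FALSE]
    descs <- descs[match(accessions, accs)]
  } else {
    keep <- colSums(is.na(vals)) == 0 & apply(vals, 2, stats::var) > 0
    keep[is.na(keep)] <- FALSE
    vals <- vals[, keep, drop = FALSE]
    descs <- descs[keep]
  }
  property_table(vals, descriptions = descs, provenance = "AAindex1 (seqinr)")
}

# The 46 descriptors of the default encoding set. The published list of
# selected properties survives only as 40 unique resolvable accessions (two
# obvious accession typos corrected); the remaining 6 are deterministic
# completions: the first catalogue entries, in file order, whose absolute
# Pearson correlation with every already-selected descriptor is <= 0.5.
HOTSPOT_PROPERTY_SET <- c(
  # alpha/turn propensity group
  "GEIM800103", "CHAM830102", "QIAN880129", "ROBB760111", "RICJ880114",
  "RACS820104", "QIAN880117", "WOLS870103", "FASG760104", "ISOY800106",
  "ROBB760107", "QIAN880139", "QIAN880113", "RICJ880117", "SNEP660104",
  "VASM830101", "BUNA790103",
  # hydrophobicity group
  "NAKH900113", "QIAN880128", "PRAM820101", "KHAG800101", "SUEM840102",
  "WERD780103", "RICJ880104", "VASM830102", "ROSM880103", "RICJ880105",
  "ISOY800107", "RACS820103", "JOND750102", "TANS770108", "KLEP840101",
  "VELV850101",
  # physicochemical group
  "JOND920102",
  # additional properties group
  "GEOR030103", "NADH010107", "AURR980118", "AURR980120", "WILM950104",
  "GEOR030107",
  # deterministic low-correlation completions
  "BEGF750103", "BROC820101", "CHAM830103", "CHAM830105", "CHOP780207",
  "ISOY800102")

#' The default 46-descriptor property set
#'
#' The bundled reconstruction of the 46 mutually low-correlation AAindex1
#' descriptors used for residue encoding: 40 accessions recovered from the
#' published selection plus 6 deterministic completions chosen so that every
#' added descriptor has absolute Pearson correlation at most 0.5 with all
#' previously selected ones (see the methods vignette for the derivation).
#'
#' @param normalization `"minmax"` (default; each descriptor rescaled to
#'   span `[0, 1]`, the scale the pad value 1.0 of the residue encoder
#'   assumes) or `"none"` for raw catalogue values.
#' @return a [property_table] with 46 descriptors.
#' @export
hotspot_properties <- function(normalization = c("minmax", "none")) {
  normalization <- match.arg(normalization)
  tab <- aaindex_catalogue(HOTSPOT_PROPERTY_SET)
  tab$provenance <- "hotspotter default 46-property set"
  normalize_properties(tab, normalization)
}

#' Pearson correlation of two descriptor value vectors
#'
#' @param p,q numeric vectors of equal length (>= 2), both with positive
#'   variance.
#' @return the Pearson product-moment correlation coefficient, in `[-1, 1]`.
#' @export
pearson_correlation <- function(p, q) {
  if (length(p) != length(q) || length(p) < 2L)
    stop("p and q must have equal length >= 2")
  if (anyNA(p) || anyNA(q) || any(!is.finite(c(p, q))))
    stop("non-finite values in input")
  if (stats::var(p) == 0 || stats::var(q) == 0)
    stop("correlation undefined: zero-variance input")
  as.numeric(stats::cor(p, q))
}

#' Remove correlation-redundant descriptors
#'
#' Greedy elimination of mutually correlated descriptors: at each step the
#' count `Np_i` of other descriptors whose absolute Pearson correlation with
#' descriptor `i` exceeds `threshold` is computed, and the descriptor with
#' the largest count is removed (ties broken toward the later table
#' position), until no pair exceeds the threshold. The survivors keep their
#' original relative order.
#'
#' Absolute correlation is used: an anti-correlated descriptor pair carries
#' the same linear information as a correlated one.
#'
#' @param table a [property_table] with at least one descriptor.
#' @param threshold redundancy threshold in (0, 1); default 0.5.
#' @return the pruned [property_table]; attribute `"removed"` lists the
#'   eliminated accessions in removal order.
#' @export
remove_redundant <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "property_table"))
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  v <- table$values
  n <- ncol(v)
  keep <- rep(TRUE, n)
  removed <- character(0)
  cmat <- abs(stats::cor(v))
  diag(cmat) <- 0
  repeat {
    sub <- cmat[keep, keep, drop = FALSE]
    np <- rowSums(sub > threshold)
    if (all(np == 0)) break
    worst <- which(np == max(np))
    drop_idx <- which(keep)[worst[length(worst)]]   # later position on ties
    keep[drop_idx] <- FALSE
    removed <- c(removed, colnames(v)[drop_idx])
  }
  out <- property_table(v[, keep, drop = FALSE],
                        descriptions = table$descriptions[keep],
                        normalization = table$normalization,
                        provenance = table$provenance)
  attr(out, "removed") <- removed
  out
}

#' Rescale descriptor values
#'
#' @param table a [property_table]
#' @param mode `"minmax"` maps each descriptor affinely onto `[0, 1]`
#'   (min to 0, max to 1); `"none"` is the identity.
#' @return the rescaled [property_table] with its `normalization` field
#'   updated.
#' @export
normalize_properties <- function(table, mode = c("minmax", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(table)
  v <- apply(table$values, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  rownames(v) <- rownames(table$values)
  out <- property_table(v, descriptions = table$descriptions,
                        normalization = "minmax",
                        provenance = table$provenance)
  out
}

#' Read/write a property table as TSV
#'
#' The TSV layout is one row per descriptor: an `accession` column followed
#' by 20 columns headed by the one-letter amino-acid codes.
#'
#' @param table a [property_table]
#' @param path file path
#' @return `write_property_tsv` returns `path` invisibly;
#'   `read_property_tsv` returns a [property_table].
#' @export
write_property_tsv <- function(table, path) {
  df <- data.frame(accession = accessions(table),
                   t(table$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_tsv
#' @export
read_property_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "accession") ||
      !setequal(names(df)[-1], AA_ORDER))
    stop("property TSV must have columns: accession, ", paste(AA_ORDER, collapse = ", "))
  v <- t(as.matrix(df[, AA_ORDER]))
  colnames(v) <- df$accession
  property_table(v, provenance = path)
}
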