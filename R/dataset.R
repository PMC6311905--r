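#' @title Labeled residue datasets
#' @name residue_dataset
#' @description
#' A residue dataset couples residue-level mutation records (alanine-scanning
#' ddG values or qualitative interaction-strength categories, labeled
#' hot/non-hot) with the chain sequences the residues live on. Sequences are
#' keyed by `complex id` + `chain`, matching FASTA record ids of the form
#' `complex_chain`.
NULL

#' Construct a residue dataset
#'
#' @param residues data.frame with columns `complex_id`, `chain`, `position`
#'   (1-based within the chain sequence), `wild_type` (one-letter code),
#'   `label` (`"hot"`/`"nonhot"`); optional columns `ddg` (kcal/mol),
#'   `category`, `relasa`.
#' @param sequences named character vector of amino-acid sequences; names
#'   are `paste(complex_id, chain, sep = "_")`.
#' @param name corpus label.
#' @return an object of class `residue_dataset`.
#' @export
residue_dataset <- function(residues, sequences = character(0), name = "dataset") {
  req <- c("complex_id", "chain", "position", "wild_type", "label")
  miss <- setdiff(req, names(residues))
  if (length(miss))
    stop("residues is missing required column(s): ", paste(miss, collapse = ", "))
  residues$label <- as.character(residues$label)
  if (!all(residues$label %in% c("hot", "nonhot")))
    stop("labels must be 'hot' or 'nonhot'")
  bad_aa <- !(residues$wild_type %in% AA_ORDER)
  if (any(bad_aa))
    stop("non-canonical wild-type code(s): ",
         paste(unique(residues$wild_type[bad_aa]), collapse = ", "))
  if (any(residues$position < 1))
    stop("positions must be >= 1")
  key <- with(residues, paste(complex_id, chain, position, sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate (complex_id, chain, position) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  skey <- chain_key(residues$complex_id, residues$chain)
  attached <- skey %in% names(sequences)
  if (any(attached)) {
    len <- nchar(sequences[skey[attached]])
    if (any(residues$position[attached] > len))
      stop("residue position beyond chain sequence length for key(s): ",
           paste(unique(skey[attached][residues$position[attached] > len]),
                 collapse = ", "))
    seq_aa <- substr(sequences[skey[attached]],
                     residues$position[attached], residues$position[attached])
    mism <- seq_aa != residues$wild_type[attached]
    if (any(mism))
      warning("wild-type code disagrees with attached sequence at: ",
              paste(utils::head(paste0(skey[attached][mism], ":",
                                       residues$position[attached][mism]), 5),
                    collapse = ", "))
  }
  rownames(residues) <- NULL
  structure(list(name = name, residues = residues,
                 sequences = sequences),
            class = "residue_dataset")
}

chain_key <- function(complex_id, chain) paste(complex_id, chain, sep = "_")

#' @export
print.residue_dataset <- function(x, ...) {
  cat(sprintf("residue_dataset '%s': %d residues (%d hot / %d nonhot), %d chains\n",
              x$name, nrow(x$residues), sum(x$residues$label == "hot"),
              sum(x$residues$label == "nonhot"), length(x$sequences)))
  invisible(x)
}

#' Label a residue from its alanine-scanning ddG
#'
#' Residues whose mutation to alanine raises the binding free energy by at
#' least `hot_cut` kcal/mol are hot spots; those below `nonhot_cut` are
#' non-hot spots; values in between are ambiguous and excluded from
#' datasets.
#'
#' @param ddg change in binding free energy on alanine substitution, kcal/mol
#'   (vectorised).
#' @param hot_cut hot-spot threshold, default 2.0 kcal/mol.
#' @param nonhot_cut non-hot threshold, default 0.4 kcal/mol.
#' @param strict if `TRUE`, values exactly at a cutoff are excluded (a
#'   literal reading of strictly greater/less); default assigns boundaries
#'   to the nearer class.
#' @return character vector in `{"hot", "nonhot", "excluded"}`.
#' @export
label_from_ddg <- function(ddg, hot_cut = 2.0, nonhot_cut = 0.4, strict = FALSE) {
  if (!is.numeric(ddg) || any(!is.finite(ddg)))
    stop("ddG must be finite numeric")
  if (!(hot_cut > nonhot_cut)) stop("hot_cut must exceed nonhot_cut")
  if (strict)
    ifelse(ddg > hot_cut, "hot", ifelse(ddg < nonhot_cut, "nonhot", "excluded"))
  else
    ifelse(ddg >= hot_cut, "hot", ifelse(ddg <= nonhot_cut, "nonhot", "excluded"))
}

#' Label a residue from a BID interaction-strength category
#'
#' `"strong"` interactions are hot spots; `"intermediate"`, `"weak"` and
#' `"insignificant"` are non-hot spots. Matching is case-insensitive.
#'
#' @param category character vector of categories.
#' @return character vector in `{"hot", "nonhot"}`.
#' @export
label_from_bid_category <- function(category) {
  cat_lc <- tolower(trimws(as.character(category)))
  known <- c("strong", "intermediate", "weak", "insignificant")
  bad <- !(cat_lc %in% known)
  if (any(bad))
    stop("unknown interaction-strength category: ",
         paste(unique(category[bad]), collapse = ", "))
  ifelse(cat_lc == "strong", "hot", "nonhot")
}

#' Read a residue-level mutation table
#'
#' Reads a delimited table of interface-residue mutation records and labels
#' each row, either from a ddG column (see [label_from_ddg]; rows in the
#' ambiguous band are dropped and counted) or from a strength category
#' (see [label_from_bid_category]).
#'
#' @param path path to a TSV/CSV file.
#' @param schema named list mapping the roles `complex`, `chain`, `position`,
#'   `wild_type` and `ddg` and/or `category` (plus optional `relasa`) to
#'   column names in the file. Defaults to identically named columns.
#' @param label_by `"ddg"`, `"category"`, or `"auto"` (category if mapped
#'   and present, else ddg).
#' @param sequences optional named character vector (see [residue_dataset])
#'   attached to the result.
#' @param name corpus label; defaults to the file name.
#' @param sep field separator; `"\t"` by default, `","` for CSV.
#' @param strict passed to [label_from_ddg].
#' @return a [residue_dataset]; attribute `"n_excluded"` counts rows dropped
#'   by the ambiguous ddG band.
#' @export
read_mutation_table <- function(path, schema = list(), label_by = c("auto", "ddg", "category"),
                                sequences = character(0), name = NULL,
                                sep = "\t", strict = FALSE) {
  label_by <- match.arg(label_by)
  defaults <- list(complex = "complex_id", chain = "chain", position = "position",
                   wild_type = "wild_type", ddg = "ddg", category = "category",
                   relasa = "relasa")
  schema <- utils::modifyList(defaults, schema)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("complex", "chain", "position", "wild_type")
  miss <- vapply(need, function(r) !(schema[[r]] %in% names(df)), logical(1))
  if (any(miss))
    stop("missing required column(s): ",
         paste(unlist(schema[need][miss]), collapse = ", "))
  if (label_by == "auto")
    label_by <- if (schema$category %in% names(df)) "category" else "ddg"

  out <- data.frame(complex_id = as.character(df[[schema$complex]]),
                    chain = as.character(df[[schema$chain]]),
                    position = as.integer(df[[schema$position]]),
                    wild_type = toupper(as.character(df[[schema$wild_type]])),
                    stringsAsFactors = FALSE)
  if (schema$relasa %in% names(df)) out$relasa <- as.numeric(df[[schema$relasa]])
  n_excluded <- 0L
  if (label_by == "ddg") {
    if (!(schema$ddg %in% names(df)))
      stop("missing required column: ", schema$ddg)
    out$ddg <- as.numeric(df[[schema$ddg]])
    lab <- label_from_ddg(out$ddg, strict = strict)
    n_excluded <- sum(lab == "excluded")
    if (n_excluded > 0)
      message(n_excluded, " row(s) in the ambiguous ddG band excluded")
    out <- out[lab != "excluded", , drop = FALSE]
    out$label <- lab[lab != "excluded"]
  } else {
    if (!(schema$category %in% names(df)))
      stop("missing required column: ", schema$category)
    out$category <- as.character(df[[schema$category]])
    out$label <- label_from_bid_category(out$category)
  }
  ds <- residue_dataset(out, sequences = sequences,
                        name = if (is.null(name)) basename(path) else name)
  attr(ds, "n_excluded") <- n_excluded
  ds
}

#' Serialize a residue dataset as TSV
#'
#' Writes the residue records with a fixed header
#' (`complex_id chain position wild_type [ddg] [category] [relasa] label`);
#' [read_mutation_table] on the result round-trips the dataset.
#'
#' @param dataset a [residue_dataset]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(dataset, path) {
  cols <- intersect(c("complex_id", "chain", "position", "wild_type",
                      "ddg", "category", "relasa", "label"),
                    names(dataset$residues))
  utils::write.table(dataset$residues[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chain sequences from FASTA
#'
#' Sequences are uppercased; letters outside the 20 canonical codes are
#' flagged with a warning listing record and positions (the residue encoder
#' later maps them to the descriptor mean).
#'
#' @param path FASTA file path.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  if (any(!nzchar(seqs))) stop("empty FASTA record in ", path)
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  for (id in names(seqs)) {
    ltr <- strsplit(seqs[[id]], "")[[1]]
    bad <- which(!(ltr %in% AA_ORDER))
    if (length(bad))
      warning("record '", id, "' has non-canonical letter(s) ",
              paste(unique(ltr[bad]), collapse = ""), " at position(s) ",
              paste(utils::head(bad, 10), collapse = ","))
  }
  seqs
}

#' Write chain sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read per-residue relative accessible surface area (NetSurfP output)
#'
#' Parses the classic whitespace-delimited NetSurfP tabular output (one row
#' per residue: burial class, one-letter code, chain/sequence id, 1-based
#' position, RSA, ASA, ...). Comment lines beginning with `#` are skipped.
#'
#' @param path file path.
#' @param sequences optional named character vector; when supplied, each
#'   row's residue code is cross-checked against the sequence and a mismatch
#'   is an error.
#' @return data.frame with columns `chain` (the sequence id), `position`,
#'   `relasa`.
#' @export
read_netsurfp <- function(path, sequences = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    warning("empty NetSurfP file: ", path)
    return(data.frame(chain = character(0), position = integer(0),
                      relasa = numeric(0)))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(toks) < 5L
  if (any(short))
    stop("malformed NetSurfP row (need >= 5 fields): line ", which(short)[1])
  out <- data.frame(
    code = vapply(toks, `[[`, character(1), 2L),
    chain = vapply(toks, `[[`, character(1), 3L),
    position = as.integer(vapply(toks, `[[`, character(1), 4L)),
    relasa = as.numeric(vapply(toks, `[[`, character(1), 5L)),
    stringsAsFactors = FALSE)
  if (!is.null(sequences)) {
    known <- out$chain %in% names(sequences)
    if (any(known)) {
      seq_aa <- substr(sequences[out$chain[known]], out$position[known],
                       out$position[known])
      mism <- seq_aa != out$code[known]
      if (any(mism))
        stop("NetSurfP residue code disagrees with sequence at ",
             paste(utils::head(paste0(out$chain[known][mism], ":",
                                      out$position[known][mism]), 5),
                   collapse = ", "))
    }
  }
  out[, c("chain", "position", "relasa")]
}

#' Write a relASA table in NetSurfP-like layout
#'
#' Emits the same whitespace-delimited dialect [read_netsurfp] consumes;
#' used by the synthetic generator. The burial-class column is derived from
#' the conventional 25% relASA cutoff, the absolute ASA column is a
#' placeholder.
#'
#' @param rsa data.frame with columns `chain`, `position`, `relasa`.
#' @param sequences named character vector supplying the residue codes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_netsurfp <- function(rsa, sequences, path) {
  code <- substr(sequences[rsa$chain], rsa$position, rsa$position)
  cls <- ifelse(rsa$relasa >= 0.25, "E", "B")
  writeLines(c("# Class Code Chain Position RSA ASA",
               sprintf("%s %s %s %d %.4f %.1f", cls, code, rsa$chain,
                       rsa$position, rsa$relasa, rsa$relasa * 150)),
             path)
  invisible(path)
}

#' Merge two residue datasets into a mixed corpus
#'
#' Concatenates the residue records of two datasets and removes exact
#' duplicate `(complex_id, chain, position, wild_type)` keys, keeping the
#' first occurrence; sequences are merged (shared keys must agree).
#'
#' @param a,b [residue_dataset] objects.
#' @param name corpus label for the result.
#' @return a [residue_dataset].
#' @export
mix_datasets <- function(a, b, name = "Mix") {
  common <- intersect(names(a$sequences), names(b$sequences))
  if (length(common) && !identical(a$sequences[common], b$sequences[common]))
    stop("shared sequence key(s) disagree between datasets")
  res <- rbind(pad_cols(a$residues, b$residues), pad_cols(b$residues, a$residues))
  key <- with(res, paste(complex_id, chain, position, wild_type, sep = "|"))
  res <- res[!duplicated(key), , drop = FALSE]
  residue_dataset(res, sequences = c(a$sequences,
                                     b$sequences[setdiff(names(b$sequences), common)]),
                  name = name)
}

pad_cols <- function(x, like) {
  for (cl in setdiff(names(like), names(x))) x[[cl]] <- NA
  x[, union(names(x), names(like)), drop = FALSE]
}
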