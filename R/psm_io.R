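# Tabular I/O: PSM tables, annotation maps, protein quant tables,
# fermentation yield tables, purity matrices.  One dialect everywhere:
# tab-separated, '.' decimal point, required header, '#' comment lines
# skipped, optional numeric fields written as "NA".

PSM_COLUMNS <- c("spectrum_id", "peptide", "protein_acc", "log_e",
                 "has_label", "in_target_db", INTENSITY_COLUMNS)

FERMENTATION_COLUMNS <- c("condition_mM", "h2_mL_L", "co2_mL_L",
                          "ethanol_total_mg_L", "acetate_mg_L", "cdw_mg_L")

PROTEIN_COLUMNS <- c("protein_acc", "comparison", "median_ratio",
                     "n_psm", "p_value", "status")

#' @noRd
stop_format <- function(..., line = NULL) {
  msg <- paste0(...)
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, class = c("plexquant_format_error", "plexquant_error")))
}

#' @noRd
stop_validation <- function(..., line = NULL) {
  msg <- paste0(...)
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, class = c("plexquant_validation_error", "plexquant_error")))
}

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("plexquant_config_error", "plexquant_error")))
}

# Low-level TSV reader that keeps track of the physical line number of every
# data row, so malformed rows can be reported precisely.  Lines starting with
# '#' and blank lines are skipped.  Returns a character matrix plus the line
# number vector as attribute "lines".
#' @noRd
read_tsv_raw <- function(source) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop_format("empty table: no header row found")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (anyDuplicated(header))
    stop_format("duplicated column name in header", line = idx[1L])
  rows <- fields[-1L]
  row_lines <- idx[-1L]
  n_col <- length(header)
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop_format(sprintf("expected %d tab-separated fields, found %d",
                        n_col, lengths(rows)[bad[1L]]),
                line = row_lines[bad[1L]])
  mat <- matrix(if (length(rows)) unlist(rows) else character(),
                ncol = n_col, byrow = TRUE,
                dimnames = list(NULL, header))
  attr(mat, "lines") <- row_lines
  mat
}

#' @noRd
require_columns <- function(mat, required, what) {
  missing <- setdiff(required, colnames(mat))
  if (length(missing))
    stop_format(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  invisible(mat)
}

# Coerce one character column to numeric; values that are neither numbers
# nor "NA" raise a format error with the offending physical line.
#' @noRd
parse_numeric_column <- function(mat, col, allow_na = FALSE) {
  raw <- mat[, col]
  out <- suppressWarnings(as.numeric(raw))
  bad <- is.na(out) & !(allow_na & toupper(trimws(raw)) == "NA")
  if (any(bad))
    stop_format(sprintf("column '%s': cannot parse value '%s' as a number",
                        col, raw[which(bad)[1L]]),
                line = attr(mat, "lines")[which(bad)[1L]])
  out
}

#' @noRd
parse_logical_column <- function(mat, col) {
  raw <- tolower(trimws(mat[, col]))
  out <- rep(NA, length(raw))
  out[raw %in% c("1", "true")] <- TRUE
  out[raw %in% c("0", "false")] <- FALSE
  if (anyNA(out) && length(raw))
    stop_format(sprintf("column '%s': '%s' is not a boolean (use 0/1/true/false)",
                        col, mat[, col][which(is.na(out))[1L]]),
                line = attr(mat, "lines")[which(is.na(out))[1L]])
  as.logical(out)
}

# Numbers are written with full double precision; booleans as 1/0; NA as "NA".
#' @noRd
format_tsv_value <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), "NA", ifelse(x, "1", "0")))
  if (is.numeric(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                     trim = TRUE, nsmall = 0), "")
    return(out)
  }
  ifelse(is.na(x), "NA", as.character(x))
}

#' @noRd
write_tsv <- function(df, sink) {
  cols <- lapply(df, format_tsv_value)
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character()
  writeLines(c(paste(names(df), collapse = "\t"), body), sink)
  invisible(NULL)
}

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches, one row per
#' spectrum, with columns `spectrum_id`, `peptide`, `protein_acc`, `log_e`
#' (log10 of the search-engine expectation value), `has_label` and
#' `in_target_db` (booleans, `0/1/true/false`), and the four reporter-ion
#' intensities `i114`, `i115`, `i116`, `i117`.
#'
#' @param source Path or connection to a TSV file; `#` comment lines and
#'   blank lines are skipped.
#' @return A `data.frame` with one row per PSM and properly typed columns.
#' @seealso [write_psm_table()], [generate_dataset()]
#' @export
read_psm_table <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, PSM_COLUMNS, "PSM table")
  psm <- data.frame(
    spectrum_id = mat[, "spectrum_id"],
    peptide = mat[, "peptide"],
    protein_acc = mat[, "protein_acc"],
    log_e = parse_numeric_column(mat, "log_e"),
    has_label = parse_logical_column(mat, "has_label"),
    in_target_db = parse_logical_column(mat, "in_target_db"),
    stringsAsFactors = FALSE
  )
  for (col in INTENSITY_COLUMNS) psm[[col]] <- parse_numeric_column(mat, col)
  validate_psm_table(psm, lines = attr(mat, "lines"))
  psm
}

#' @noRd
validate_psm_table <- function(psm, lines = NULL) {
  line_of <- function(i) if (is.null(lines)) NULL else lines[i]
  inten <- as.matrix(psm[INTENSITY_COLUMNS])
  bad <- which(!is.finite(inten) | inten < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_validation("reporter intensities must be finite and >= 0",
                    line = line_of(bad[1L, 1L]))
  dup <- which(duplicated(psm$spectrum_id))
  if (length(dup))
    stop_validation(sprintf("duplicate spectrum_id '%s'", psm$spectrum_id[dup[1L]]),
                    line = line_of(dup[1L]))
  invisible(psm)
}

#' Write a PSM table
#'
#' @param psm A PSM `data.frame` as returned by [read_psm_table()] or
#'   [generate_dataset()].
#' @param sink Path or connection to write to.
#' @export
write_psm_table <- function(psm, sink) {
  validate_psm_table(psm)
  write_tsv(psm[PSM_COLUMNS], sink)
}

#' Construct an annotation map
#'
#' Bundles a protein-to-COG-category map and a protein-to-pathway map.
#' Proteins absent from either map are simply unannotated; they are not an
#' error.
#'
#' @param cog Named character vector: names are protein accessions, values
#'   single COG category letters from [COG_CATEGORIES].
#' @param pathways Named list: names are protein accessions, each element a
#'   non-empty character vector of pathway identifiers.
#' @return An object of class `"annotation_map"`.
#' @export
annotation_map <- function(cog = character(), pathways = list()) {
  cog <- unlist(cog)
  if (length(cog) && is.null(names(cog)))
    stop_validation("'cog' must be named by protein accession")
  bad <- setdiff(unique(cog), COG_CATEGORIES)
  if (length(bad))
    stop_validation("unknown COG category: ", paste(bad, collapse = ", "))
  if (length(pathways)) {
    if (is.null(names(pathways)))
      stop_validation("'pathways' must be named by protein accession")
    if (any(lengths(pathways) == 0L))
      stop_validation("every mapped protein must have a non-empty pathway set")
    pathways <- lapply(pathways, function(p) sort(unique(as.character(p))))
  }
  structure(list(cog = cog, pathways = pathways), class = "annotation_map")
}

#' Read protein annotation maps
#'
#' `read_cog_map()` reads a two-column TSV (`protein_acc`, `cog`);
#' `read_pathway_map()` reads a two-column TSV (`protein_acc`,
#' `pathway_id`) with one row per protein-pathway membership, and
#' `read_annotation()` combines both into an [annotation_map()].
#' Either source may be `NULL` for an empty map.
#'
#' @param source Path or connection to a TSV file.
#' @return A named character vector (`read_cog_map`), a named list of
#'   pathway-id vectors (`read_pathway_map`), or an `annotation_map`.
#' @export
read_cog_map <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, c("protein_acc", "cog"), "COG map")
  cog <- mat[, "cog"]
  names(cog) <- mat[, "protein_acc"]
  dup <- which(duplicated(names(cog)))
  if (length(dup))
    stop_validation(sprintf("protein '%s' mapped to more than one COG category",
                            names(cog)[dup[1L]]),
                    line = attr(mat, "lines")[dup[1L]])
  bad <- which(!(cog %in% COG_CATEGORIES))
  if (length(bad))
    stop_format(sprintf("unknown COG category '%s'", cog[bad[1L]]),
                line = attr(mat, "lines")[bad[1L]])
  cog
}

#' @rdname read_cog_map
#' @export
read_pathway_map <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, c("protein_acc", "pathway_id"), "pathway map")
  split_ids <- split(mat[, "pathway_id"], mat[, "protein_acc"])
  lapply(split_ids, function(p) sort(unique(p)))
}

#' @rdname read_cog_map
#' @param cog_source,pathway_source Paths/connections for the two maps
#'   (either may be `NULL`).
#' @export
read_annotation <- function(cog_source = NULL, pathway_source = NULL) {
  annotation_map(
    cog = if (is.null(cog_source)) character() else read_cog_map(cog_source),
    pathways = if (is.null(pathway_source)) list() else read_pathway_map(pathway_source)
  )
}

#' Write annotation maps
#'
#' @param ann An [annotation_map()].
#' @param cog_sink,pathway_sink Paths/connections to write each map to
#'   (either may be `NULL` to skip).
#' @export
write_annotation <- function(ann, cog_sink = NULL, pathway_sink = NULL) {
  stopifnot(inherits(ann, "annotation_map"))
  if (!is.null(cog_sink))
    write_tsv(data.frame(protein_acc = names(ann$cog),
                         cog = unname(ann$cog),
                         stringsAsFactors = FALSE), cog_sink)
  if (!is.null(pathway_sink)) {
    df <- data.frame(
      protein_acc = rep(names(ann$pathways), lengths(ann$pathways)),
      pathway_id = unlist(ann$pathways, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv(df, pathway_sink)
  }
  invisible(NULL)
}

#' Read and write protein quantitation tables
#'
#' One row per protein per comparison with the pairwise median ratio, the
#' number of contributing spectra, the p-value of the location test and the
#' quantitation status (`quantified`, `insufficient_psm`,
#' `not_significant`).  Rows are ordered by accession then comparison.
#'
#' @param quants A protein quantitation `data.frame` as produced by
#'   [quantify_proteins()].
#' @param sink,source Path or connection.
#' @export
write_protein_table <- function(quants, sink) {
  missing <- setdiff(PROTEIN_COLUMNS, names(quants))
  if (length(missing))
    stop_format("protein table is missing required column(s): ",
                paste(missing, collapse = ", "))
  ord <- order(quants$protein_acc, quants$comparison)
  write_tsv(quants[ord, PROTEIN_COLUMNS, drop = FALSE], sink)
}

#' @rdname write_protein_table
#' @export
read_protein_table <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, PROTEIN_COLUMNS, "protein table")
  data.frame(
    protein_acc = mat[, "protein_acc"],
    comparison = mat[, "comparison"],
    median_ratio = parse_numeric_column(mat, "median_ratio", allow_na = TRUE),
    n_psm = as.integer(parse_numeric_column(mat, "n_psm")),
    p_value = parse_numeric_column(mat, "p_value", allow_na = TRUE),
    status = mat[, "status"],
    stringsAsFactors = FALSE
  )
}

#' Read and write fermentation yield tables
#'
#' Columns: `condition_mM` (exogenous ethanol), `h2_mL_L`, `co2_mL_L`
#' (optional), `ethanol_total_mg_L` (measured total ethanol),
#' `acetate_mg_L`, `cdw_mg_L` (optional).  Optional values are encoded as
#' `NA`; missing optional columns are filled with `NA`.
#'
#' @param source,sink Path or connection.
#' @param records A fermentation `data.frame`.
#' @return `read_fermentation_table()` returns a `data.frame` with the six
#'   declared columns.
#' @export
read_fermentation_table <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, c("condition_mM", "h2_mL_L", "ethanol_total_mg_L",
                         "acetate_mg_L"), "fermentation table")
  out <- data.frame(condition_mM = parse_numeric_column(mat, "condition_mM"))
  for (col in setdiff(FERMENTATION_COLUMNS, "condition_mM"))
    out[[col]] <- if (col %in% colnames(mat))
      parse_numeric_column(mat, col, allow_na = TRUE) else NA_real_
  neg <- as.matrix(out[setdiff(FERMENTATION_COLUMNS, "condition_mM")])
  if (any(neg < 0, na.rm = TRUE))
    stop_validation("fermentation yields must be >= 0")
  out
}

#' @rdname read_fermentation_table
#' @export
write_fermentation_table <- function(records, sink) {
  missing <- setdiff(c("condition_mM", "h2_mL_L", "ethanol_total_mg_L",
                       "acetate_mg_L"), names(records))
  if (length(missing))
    stop_format("fermentation table is missing required column(s): ",
                paste(missing, collapse = ", "))
  for (col in setdiff(FERMENTATION_COLUMNS, names(records)))
    records[[col]] <- NA_real_
  write_tsv(records[FERMENTATION_COLUMNS], sink)
}

#' Read and write a purity matrix
#'
#' The file is a 4x4 TSV with a `channel` row-label column and one column
#' per reporter channel; entry (r, c) is the fraction of channel c's true
#' signal observed in channel r.
#'
#' @param source,sink Path or connection.
#' @param purity A valid 4x4 purity matrix.
#' @export
read_purity_matrix <- function(source) {
  mat <- read_tsv_raw(source)
  require_columns(mat, c("channel", CHANNELS), "purity matrix")
  if (nrow(mat) != 4L || !identical(sort(mat[, "channel"]), sort(CHANNELS)))
    stop_format("purity matrix must have exactly one row per channel 114..117")
  P <- matrix(NA_real_, 4, 4, dimnames = list(CHANNELS, CHANNELS))
  for (col in CHANNELS) P[mat[, "channel"], col] <- parse_numeric_column(mat, col)
  validate_purity_matrix(P)
  P
}

#' @rdname read_purity_matrix
#' @export
write_purity_matrix <- function(purity, sink) {
  validate_purity_matrix(purity)
  df <- data.frame(channel = CHANNELS, stringsAsFactors = FALSE)
  for (col in CHANNELS) df[[col]] <- purity[, col]
  write_tsv(df, sink)
}
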