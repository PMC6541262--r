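#' Read a society table from CSV/TSV
#'
#' Expected layout: a header row with columns `name`, `latitude`, `longitude`,
#' `practices` (practice codes separated by `;` inside one cell), optionally
#' `alt_name`, and one column per roster variable. Empty covariate cells become
#' `NA` and are rejected later by the stages that need complete data.
#'
#' @param path Path to an existing delimited file.
#' @param roster Covariate roster expected in the file; defaults to the 21
#'   canonical variables. Roster columns absent from the file are an error only
#'   if any roster column is present (a pure practice table is accepted, with
#'   covariates flagged absent).
#' @param sep Field separator; `","` or `"\t"`.
#' @return A validated `society_dataset`.
#' @export
load_society_table <- function(path, roster = roster_names(), sep = ",") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "\"", comment.char = ""),
    error = function(e) stop("cannot parse society table (", conditionMessage(e), ")")
  )
  if (nrow(df) == 0 || ncol(df) <= 1)
    stop("schema error: empty or single-column society table")
  required <- c("name", "latitude", "longitude", "practices")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  have_roster <- intersect(roster, names(df))
  covariates <- NULL
  if (length(have_roster) > 0) {
    missing_roster <- setdiff(roster, names(df))
    if (length(missing_roster) > 0)
      stop("schema error: missing roster column(s): ",
           paste(missing_roster, collapse = ", "))
    covariates <- df[, roster, drop = FALSE]
    for (v in roster) covariates[[v]] <- as.numeric(covariates[[v]])
  }
  society_dataset(
    name = as.character(df$name),
    alt_name = if ("alt_name" %in% names(df)) as.character(df$alt_name)
               else rep(NA_character_, nrow(df)),
    latitude = as.numeric(df$latitude),
    longitude = as.numeric(df$longitude),
    practices = lapply(strsplit(as.character(df$practices), ";", fixed = TRUE),
                       trimws),
    covariates = covariates,
    roster = roster
  )
}

#' Write a society table to CSV/TSV
#'
#' Inverse of [load_society_table()]: one row per society, practices serialized
#' as `;`-separated codes in one column, covariates (if present) as roster
#' columns.
#'
#' @param dataset A `society_dataset`.
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_society_table <- function(dataset, path, sep = ",") {
  validate_society_dataset(dataset)
  df <- data.frame(
    name = dataset$name,
    alt_name = dataset$alt_name,
    latitude = dataset$latitude,
    longitude = dataset$longitude,
    practices = vapply(dataset$practices, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  if (!is.null(dataset$covariates)) df <- cbind(df, dataset$covariates)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a result table
#'
#' Generic writer for the pipeline's tabular outputs (pairwise tables, test
#' results, dependence screens, fold-MSE tables...). Numeric cells are written
#' at full double precision so that a write/read round trip is the identity up
#' to >= 15 significant digits.
#'
#' @param table A non-empty data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("result table is empty; nothing to write")
  sep <- if (format == "csv") "," else "\t"
  ok <- tryCatch({
    utils::write.table(table, path, sep = sep, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
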