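#' Write a dataset in the FAERS quarterly ASCII dialect
#'
#' One `$`-delimited text file per table (header row, one record per line,
#' no quoting), named `DEMO.txt`, `DRUG.txt`, ... plus a
#' `ground_truth.json` sidecar when the dataset carries generator ground
#' truth.
#'
#' @param dataset a `synthetic_faers` object, or a bare named list of the
#'   seven tables.
#' @param directory output directory (created if absent).
#' @return invisibly, the named vector of files written.
#' @export
write_faers_ascii <- function(dataset, directory) {
  tables <- if (inherits(dataset, "synthetic_faers")) dataset$tables else dataset
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory '%s'", directory)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(directory, paste0(nm, ".txt"))
    tab <- tables[[nm]]
    ok <- tryCatch({
      utils::write.table(tab, path, sep = "$", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, na = "")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stopf("failed writing '%s': %s", path, conditionMessage(ok))
    files[nm] <- path
  }
  if (inherits(dataset, "synthetic_faers")) {
    gt <- dataset$ground_truth
    path <- file.path(directory, "ground_truth.json")
    jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["ground_truth"] <- path
  }
  invisible(files)
}

#' Read FAERS quarterly ASCII tables
#'
#' Parses the `$`-delimited tables from a directory, keeping DEMO rows whose
#' FDA receipt year (`fda_dt`) falls inside the study window and the child
#' rows attached to them. DEMO, DRUG and REAC are mandatory; OUTC, RPSR,
#' THER and INDI yield empty tables when absent. Lines with fewer fields
#' than the header are skipped and counted.
#'
#' @param directory path containing `DEMO.txt` etc.
#' @param window integer vector `c(from_year, to_year)`; NULL keeps all years.
#' @return list of class `faers_tables`: the seven data.frames plus a `log`
#'   list with `skipped_lines` (per table) and `outside_window` (DEMO rows
#'   dropped by the window filter).
#' @export
read_faers_tables <- function(directory, window = NULL) {
  if (!dir.exists(directory)) stopf("directory '%s' does not exist", directory)
  mandatory <- c("DEMO", "DRUG", "REAC")
  optional <- c("OUTC", "RPSR", "THER", "INDI")
  tables <- list()
  skipped <- stats::setNames(integer(7), c(mandatory, optional))
  for (nm in c(mandatory, optional)) {
    path <- file.path(directory, paste0(nm, ".txt"))
    if (!file.exists(path)) {
      if (nm %in% mandatory) stopf("mandatory table '%s' missing (no %s)", nm, path)
      tables[[nm]] <- data.frame()
      next
    }
    parsed <- read_dollar_file(path)
    tables[[nm]] <- parsed$table
    skipped[nm] <- parsed$skipped
  }

  outside <- 0L
  if (!is.null(window)) {
    yr <- suppressWarnings(as.integer(substr(tables$DEMO$fda_dt, 1, 4)))
    keep <- !is.na(yr) & yr >= window[1] & yr <= window[2]
    outside <- sum(!keep)
    tables$DEMO <- tables$DEMO[keep, , drop = FALSE]
    kept_ids <- tables$DEMO$primaryid
    for (nm in setdiff(names(tables), "DEMO")) {
      if (nrow(tables[[nm]]) && "primaryid" %in% names(tables[[nm]])) {
        tables[[nm]] <- tables[[nm]][tables[[nm]]$primaryid %in% kept_ids, , drop = FALSE]
      }
    }
  }
  tables$log <- list(skipped_lines = as.list(skipped), outside_window = outside)
  class(tables) <- "faers_tables"
  tables
}

# parse one $-delimited file; malformed (short) lines skipped with a count
read_dollar_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("file '%s' is empty (no header)", path)
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    tab <- as.data.frame(stats::setNames(replicate(length(header),
                                                   character(0), simplify = FALSE), header),
                         stringsAsFactors = FALSE)
    return(list(table = tab, skipped = 0L))
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad back up to header length
  nf <- lengths(parts)
  trailing_empty <- nf < length(header) &
    substr(body, nchar(body) - (length(header) - nf) + 1, nchar(body)) ==
      strrep("$", length(header) - nf)
  ok <- nf == length(header) | trailing_empty
  skipped <- sum(!ok)
  parts <- parts[ok]
  m <- t(vapply(parts, function(x) {
    length(x) <- length(header)
    x
  }, character(length(header))))
  m[is.na(m)] <- ""
  tab <- as.data.frame(m, stringsAsFactors = FALSE)
  names(tab) <- header
  list(table = tab, skipped = skipped)
}
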