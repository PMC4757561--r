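#' Construct a growth-regression table
#'
#' A complete-case cross-country table with one outcome column (annualized
#' growth of real GDP per capita), one variable of interest (malaria
#' prevalence in the motivating application), and a set of named adjusting
#' variables. All downstream operations — null-outcome construction, model
#' vibration and the p-hacking search — consume this container.
#'
#' @param data a data frame holding all mapped columns.
#' @param outcome name of the outcome column.
#' @param interest name of the variable-of-interest column.
#' @param adjusters character vector of adjusting-variable column names.
#' @param id_col optional name of a country-identifier column; row names or
#'   row numbers are used when absent.
#' @return an object of class `growth_table`: a data frame restricted to the
#'   mapped columns, with the role mapping in attributes.
#' @export
growth_table <- function(data, outcome, interest, adjusters, id_col = NULL) {
  data <- as.data.frame(data)
  outcome <- match_column(outcome, names(data))
  interest <- match_column(interest, names(data))
  adjusters <- vapply(adjusters, match_column, "", choices = names(data))
  used <- c(outcome, interest, adjusters)
  if (anyDuplicated(used)) stop("column roles overlap: ",
                                paste(used[duplicated(used)], collapse = ", "))
  ids <- if (!is.null(id_col)) {
    as.character(data[[match_column(id_col, names(data))]])
  } else if (!is.null(rownames(data))) {
    rownames(data)
  } else {
    as.character(seq_len(nrow(data)))
  }
  if (anyDuplicated(ids)) stop("country identifiers must be unique")
  tab <- data[, used, drop = FALSE]
  if (anyNA(tab)) stop("missing values in mapped columns; apply complete-case ",
                       "filtering first (see read_growth_csv)")
  for (cn in used) {
    if (!is.numeric(tab[[cn]])) stop("column not numeric: ", cn)
  }
  rownames(tab) <- ids
  structure(tab,
            outcome = outcome, interest = interest,
            adjusters = unname(adjusters), country_ids = ids,
            class = c("growth_table", "data.frame"))
}

# Column-name matching: case-insensitive with "." and "_" interchangeable.
match_column <- function(name, choices) {
  canon <- function(x) gsub("[._]", ".", tolower(x))
  hit <- which(canon(choices) == canon(name))
  if (length(hit) == 0) {
    stop("schema error: column '", name, "' not found; available headers: ",
         paste(choices, collapse = ", "))
  }
  if (length(hit) > 1) stop("ambiguous column name: ", name)
  choices[hit]
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("growth_table: %d countries\n", nrow(x)))
  cat("  outcome:  ", attr(x, "outcome"), "\n")
  cat("  interest: ", attr(x, "interest"), "\n")
  cat("  adjusters:", paste(attr(x, "adjusters"), collapse = ", "), "\n")
  invisible(x)
}

#' Read a growth-regression CSV and map columns to roles
#'
#' Reads a comma-separated file with a header row, one row per country,
#' drops rows with missing values in any mapped column (complete-case
#' filtering; the number dropped is reported via [message()]), and returns a
#' [growth_table()]. Column names are matched case-insensitively with `"."`
#' and `"_"` treated as equivalent.
#'
#' @param path CSV file path.
#' @param outcome,interest,adjusters,id_col column mapping, as in
#'   [growth_table()].
#' @param n_min minimum acceptable number of complete rows (default 50).
#' @return a [growth_table()].
#' @export
read_growth_csv <- function(path, outcome, interest, adjusters,
                            id_col = NULL, n_min = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  cols <- c(outcome, interest, adjusters)
  mapped <- vapply(cols, match_column, "", choices = names(raw))
  keep <- stats::complete.cases(raw[, mapped, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " rows dropped by complete-case filtering")
  }
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) < n_min) {
    stop("insufficient data: ", nrow(raw), " complete rows < n_min = ", n_min)
  }
  rownames(raw) <- NULL
  growth_table(raw, outcome, interest, adjusters, id_col = id_col)
}

#' Write a growth table to CSV
#'
#' The layout round-trips through [read_growth_csv()]: a `country` column of
#' identifiers followed by the outcome, the variable of interest and the
#' adjusters.
#'
#' @param table a [growth_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(table, path) {
  stopifnot(inherits(table, "growth_table"))
  out <- cbind(country = attr(table, "country_ids"), as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
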