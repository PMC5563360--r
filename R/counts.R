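#' Build a transition count table
#'
#' The data behind a discrete-time multi-state model: the number of
#' individuals observed to move from each origin state to each destination
#' state over one cycle, with per-origin denominators.  Destinations listed
#' with a zero count are retained: they define the support of the row's
#' multinomial distribution and therefore its parameter count.
#'
#' @param from,to Character vectors of origin and destination labels.
#' @param count Non-negative integer vector of observed transitions.
#'   Duplicate (from, to) pairs are summed.
#'
#' @return An object of class `count_table`: a data frame with columns
#'   `from`, `to`, `count` and an attribute `row_total` (named vector of
#'   per-origin denominators).
#' @examples
#' # CECaT derived death counts: 126/571 medium risk, 259/754 high risk
#' count_table(from = c("medium", "medium", "high", "high"),
#'             to = c("dead", "alive", "dead", "alive"),
#'             count = c(126, 445, 259, 495))
#' @export
count_table <- function(from, to, count) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to) || length(from) != length(count)) {
    stop("'from', 'to' and 'count' must have equal length")
  }
  if (length(from) == 0L) stop("empty count table")
  if (any(is.na(count)) || any(count < 0) ||
      any(abs(count - round(count)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  count <- as.numeric(round(count))
  df <- stats::aggregate(count ~ from + to,
                         data = data.frame(from, to, count,
                                           stringsAsFactors = FALSE),
                         FUN = sum)
  # preserve first-appearance ordering of origins and destinations
  df <- df[order(match(df$from, unique(from)), match(df$to, unique(to))), ]
  rownames(df) <- NULL
  rt <- tapply(df$count, df$from, sum)
  rt <- stats::setNames(as.numeric(rt), names(rt))
  attr(df, "row_total") <- rt[unique(df$from)]
  class(df) <- c("count_table", "data.frame")
  df
}

#' @export
print.count_table <- function(x, ...) {
  cat("Transition count table (", length(row_totals(x)), " origins)\n",
      sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Per-origin denominators of a count table
#'
#' @param table A [count_table()].
#' @return Named numeric vector of row totals.
#' @export
row_totals <- function(table) {
  attr(table, "row_total")
}

#' Read a transition count table from CSV
#'
#' @param path Path to a CSV file with header `from,to,count`.  Duplicate
#'   (from, to) rows are summed.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  if (!identical(names(df)[1:3], c("from", "to", "count"))) {
    stop("count table CSV must have header 'from,to,count'")
  }
  if (nrow(df) == 0L) stop("empty count table in ", path)
  count_table(df$from, df$to, df$count)
}

#' Write a transition count table to CSV
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("from", "to", "count")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
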