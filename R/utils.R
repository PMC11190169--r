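# Quarter labels are "YYYYQn" with n in 1..4; quarter = ceiling(month / 3).

quarter_rx <- "^[0-9]{4}Q[1-4]$"

#' Quarter label of a calendar date
#'
#' @param date a `Date` vector.
#' @return Character vector of `"YYYYQn"` labels (`NA` for missing dates).
#' @examples
#' quarter_label(as.Date("2023-02-15"))
#' @export
quarter_label <- function(date) {
  stopifnot(inherits(date, "Date"))
  y <- as.integer(format(date, "%Y"))
  q <- ceiling(as.integer(format(date, "%m")) / 3)
  ifelse(is.na(date), NA_character_, paste0(y, "Q", q))
}

# Quarter label -> sortable integer index (year * 4 + quarter - 1).
quarter_index <- function(label) {
  bad <- !is.na(label) & !grepl(quarter_rx, label)
  if (any(bad)) {
    abort(paste0("Invalid quarter label(s): ",
                 paste(unique(label[bad]), collapse = ", "),
                 " (expected \"YYYYQn\")"),
          class = "faersignal_quarter_error")
  }
  as.integer(substr(label, 1, 4)) * 4L + as.integer(substr(label, 6, 6)) - 1L
}

# Consecutive quarter labels from start to end (inclusive).
quarter_seq <- function(start, end) {
  i <- quarter_index(start)
  j <- quarter_index(end)
  if (i > j) abort("start quarter is after end quarter",
                   class = "faersignal_quarter_error")
  idx <- seq(i, j)
  paste0(idx %/% 4L, "Q", idx %% 4L + 1L)
}

# First and last calendar day of a quarter.
quarter_bounds <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  first <- as.Date(sprintf("%d-%02d-01", y, (q - 1L) * 3L + 1L))
  last <- as.Date(sprintf("%d-%02d-01", y + (q == 4L), (q %% 4L) * 3L + 1L)) - 1L
  c(first, last)
}
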