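# Length-at-age dataset container and the CSV dialect used throughout:
# a header row `age,length`, comma separated, lengths in cm, ages in years.

#' Construct a length-at-age dataset
#'
#' @param age Numeric vector of ages in years (>= 0; need not be integers).
#' @param length Numeric vector of lengths in cm (>= 0; a length of exactly 0
#'   is only meaningful for age-0 animals of egg-spawning species).
#' @return A data frame of class `growth_data` with columns `age`, `length`.
#' @examples
#' growth_data(age = c(1, 2, 3), length = c(45, 80, 105))
#' @export
growth_data <- function(age, length) {
  age <- as.numeric(age); length <- as.numeric(length)
  if (length(age) != length(length)) {
    stop("`age` and `length` must have the same number of records", call. = FALSE)
  }
  if (length(age) < 1L) stop("dataset must contain at least one record", call. = FALSE)
  bad <- which(!is.finite(age) | !is.finite(length))
  if (length(bad)) {
    stop(sprintf("missing or non-finite value(s) in record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(age < 0)
  if (length(bad)) {
    stop(sprintf("negative age in record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(length < 0)
  if (length(bad)) {
    stop(sprintf("negative length in record(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(data.frame(age = age, length = length),
            class = c("growth_data", "data.frame"))
}

as_growth_data <- function(x) {
  if (inherits(x, "growth_data")) return(x)
  if (is.data.frame(x)) {
    nm <- tolower(names(x))
    if (all(c("age", "length") %in% nm)) {
      return(growth_data(x[[which(nm == "age")[1]]], x[[which(nm == "length")[1]]]))
    }
  }
  stop("`data` must be a growth_data object or a data frame with columns age, length",
       call. = FALSE)
}

#' Read a length-at-age CSV
#'
#' Expects a header with columns `age` and `length` (case-insensitive; extra
#' columns are ignored), comma-separated, decimal point, UTF-8. Rows with
#' missing or negative values are rejected with row-numbered messages.
#'
#' @param path Path to a CSV file.
#' @return A [growth_data()] data frame.
#' @export
read_growth_data <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("empty dataset: %s", path), call. = FALSE)
  nm <- tolower(names(raw))
  if (!all(c("age", "length") %in% nm)) {
    stop(sprintf("bad header in %s: need columns `age` and `length`, found: %s",
                 path, paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(raw[[which(nm == "age")[1]]]))
  len <- suppressWarnings(as.numeric(raw[[which(nm == "length")[1]]]))
  check_rows <- function(bad, what) {
    if (length(bad)) {
      stop(sprintf("%s in row(s): %s of %s", what,
                   paste(utils::head(bad, 5L), collapse = ", "), path), call. = FALSE)
    }
  }
  check_rows(which(is.na(age) | is.na(len)), "missing or non-numeric value")
  check_rows(which(age < 0), "negative age")
  check_rows(which(len < 0), "negative length")
  growth_data(age, len)
}

#' Write a length-at-age CSV
#'
#' @param data A [growth_data()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_data <- function(data, path) {
  data <- as_growth_data(data)
  utils::write.csv(data.frame(age = data$age, length = data$length),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
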