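#' Read per-quadrat counts from a CSV file
#'
#' Strict single-column dialect: a header line `count`, then one
#' non-negative integer per row. Blank lines are ignored; anything else
#' (decimals, negatives, extra columns, stray text) is a hard error, on the
#' principle that silently coerced field data are worse than a refusal.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one integer column `count`.
#' @seealso [estimate_negbin()], [generate_counts()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop("counts file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || lines[1] != "count") {
    stop("counts file must start with a header line `count`.", call. = FALSE)
  }
  body <- lines[-1]
  bad <- !grepl("^[0-9]+$", body)
  if (any(bad)) {
    idx <- which(bad) + 1
    stop("non-integer count on line(s): ",
         paste(idx[seq_len(min(5, length(idx)))], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(count = as.integer(body))
}
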