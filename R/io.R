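#' Write a tabular artifact as delimited text
#'
#' Plain CSV with one header row; missing values are written as empty
#' fields. The format round-trips losslessly through [read_table()],
#' including NA markers, so downstream stages and reruns see byte-identical
#' inputs.
#'
#' @param data data frame.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  out <- data
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {      # %.17g survives the double round-trip
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tabular artifact written by [write_table()]
#'
#' Validates the field count of every line before parsing and reports the
#' first offending line and column on failure, rather than silently
#' recycling or padding.
#'
#' @param path file path.
#' @return data frame; empty fields become NA.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error: empty file ", path, call. = FALSE)
  counts <- utils::count.fields(textConnection(lines), sep = ",", quote = "\"")
  want <- counts[1]
  bad <- which(counts != want)
  if (length(bad) > 0)
    stop(sprintf("parse error in %s, line %d: expected %d fields, found %d",
                 path, bad[1], want, counts[bad[1]]), call. = FALSE)
  out <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.logical(col) || is.integer(col)) {  # unify storage on double
      out[[j]] <- as.numeric(col)
      next
    }
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      fails <- which(!is.na(col) & is.na(num))
      if (length(fails) > 0)
        stop(sprintf(
          "parse error in %s, line %d, column '%s': non-numeric value '%s'",
          path, fails[1] + 1L, names(out)[j], col[fails[1]]), call. = FALSE)
      out[[j]] <- num
    }
  }
  out
}
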