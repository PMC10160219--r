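# format numeric columns at full precision for text output
fmt_df <- function(df) {
  as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a temporal signal from delimited text
#'
#' Accepts one-column (value) or two-column (time, value) files, tab- or
#' comma-separated, with an optional header row and `#` comment lines.
#' Uniform sampling is validated for two-column input.
#'
#' @param path file path.
#' @return A tibble with columns `time`, `value`.
#' @export
read_signal <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (length(first) == 0L) abort("empty signal file", class = "tcss_invalid_input")
  sep <- if (grepl(",", first[[1]])) "," else ""
  fields <- strsplit(trimws(first[[1]]), if (sep == ",") "," else "[ \t]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- read.table(path, header = header, sep = sep, comment.char = "#")
  if (ncol(df) == 1L) {
    out <- tibble(time = seq_len(nrow(df)) - 1, value = as.numeric(df[[1]]))
  } else {
    out <- tibble(time = as.numeric(df[[1]]), value = as.numeric(df[[2]]))
    signal_values(out)  # validates uniform sampling
  }
  out
}

#' Write a temporal signal as delimited text
#'
#' @param f signal (vector or data frame with time, value).
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_signal <- function(f, path, sep = "\t") {
  df <- tibble(time = signal_times(f), value = signal_values(f))
  write.table(fmt_df(df), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scale-space array as delimited text
#'
#' First column is the time index, remaining columns the scale levels; a `#`
#' comment line carries the layout as JSON for provenance, and the header row
#' lists the tau levels.
#'
#' @param ss a `scale_space` object.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_scale_space <- function(ss, path, sep = "\t") {
  stopifnot(inherits(ss, "scale_space"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# layout: ", layout_to_json(ss$layout)), con)
  df <- data.frame(time = ss$time, ss$L, check.names = FALSE)
  writeLines(paste(colnames(df), collapse = sep), con)
  write.table(fmt_df(df), con, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read back a scale-space matrix written by [write_scale_space()]
#'
#' @param path file path.
#' @return A list with `time`, `L` (matrix) and `layout`.
#' @export
read_scale_space <- function(path) {
  lines <- readLines(path)
  lay <- NULL
  hl <- grep("^# layout: ", lines)
  if (length(hl)) lay <- layout_from_json(sub("^# layout: ", "", lines[hl[1]]))
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   check.names = FALSE)
  list(time = df[[1]], L = as.matrix(df[, -1, drop = FALSE]), layout = lay)
}
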