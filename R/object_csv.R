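#' Read and write per-cell object tables as CSV
#'
#' The on-disk format is a plain CSV with header
#' `id,x_um,y_um[,area_um2,pixel_count,channel,mean_luminosity]` and optional
#' leading comment lines (`# window_um: W H`, `# source: name`) carrying the
#' observation window and source image. Numeric fields are written with 17
#' significant digits so a write/read round trip reproduces all values to
#' full double precision.
#'
#' @param path CSV file path.
#' @return `read_object_csv` returns the object table (tibble with `window`
#'   and `source_image` attributes when present in the file);
#'   `write_object_csv` returns `path` invisibly.
#' @export
read_object_csv <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- header[startsWith(header, "#")]
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("x_um", "y_um")) {
    if (!col %in% names(tab)) {
      stop("object CSV is missing required column `", col, "`",
           call. = FALSE)
    }
    if (nrow(tab) > 0 && !is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("non-numeric ", col, " at row ", bad, call. = FALSE)
    }
  }
  if (!"id" %in% names(tab)) tab$id <- seq_len(nrow(tab))
  if (anyDuplicated(tab$id)) stop("object ids are not unique", call. = FALSE)
  out <- tibble::as_tibble(tab)
  win_line <- grep("^# window_um:", meta, value = TRUE)
  if (length(win_line) == 1L) {
    w <- as.numeric(strsplit(sub("^# window_um:\\s*", "", win_line),
                             "\\s+")[[1]])
    if (length(w) == 2L && all(is.finite(w))) attr(out, "window") <- w
  }
  src_line <- grep("^# source:", meta, value = TRUE)
  if (length(src_line) == 1L) {
    attr(out, "source_image") <- sub("^# source:\\s*", "", src_line)
  }
  out
}

#' @rdname read_object_csv
#' @param table an object table (any data frame with `x_um`, `y_um`).
#' @export
write_object_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  win <- attr(table, "window")
  if (!is.null(win)) {
    writeLines(sprintf("# window_um: %.17g %.17g", win[1], win[2]), con)
  }
  src <- attr(table, "source_image")
  if (!is.null(src)) writeLines(paste0("# source: ", src), con)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
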