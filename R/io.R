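#' Read and write sample-by-marker tables
#'
#' Delimited text with a mandatory header; the separator is auto-detected
#' from the extension (`.csv` comma, anything else tab) unless given.
#' Reserved columns are `sample_id`, `group`, `split`, `stage`; every other
#' column is an autoantibody marker unless it carries the serum-marker
#' prefix `stm_`. On read, `group` and `split` values are normalised
#' case-insensitively and validated against their enumerations
#' (case/benign/normal, train/test), duplicate sample ids are an error, and
#' marker cells must be strictly positive numbers (errors name the row and
#' column).
#'
#' @param path file path.
#' @param sep optional separator overriding auto-detection.
#' @return `read_sample_table()`: validated data frame;
#'   `write_sample_table()`: the path, invisibly.
#' @export
read_sample_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tb <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "\"", comment.char = "",
                   fileEncoding = "UTF-8")
  validate_sample_table(tb)
}

validate_sample_table <- function(tb) {
  for (col in c("sample_id", "group", "split")) {
    if (!col %in% names(tb)) {
      stop("sample table lacks required column '", col, "'", call. = FALSE)
    }
  }
  if (anyDuplicated(tb$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tb$sample_id[duplicated(tb$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  tb$group <- tolower(trimws(tb$group))
  tb$split <- tolower(trimws(tb$split))
  bad_g <- setdiff(unique(tb$group), c("case", "benign", "normal"))
  if (length(bad_g)) {
    stop("unknown group value(s): ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  bad_s <- setdiff(unique(tb$split), c("train", "test"))
  if (length(bad_s)) {
    stop("unknown split value(s): ", paste(bad_s, collapse = ", "),
         call. = FALSE)
  }
  value_cols <- c(marker_columns(tb), serum_columns(tb))
  for (col in value_cols) {
    v <- tb[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop("non-numeric marker cell at row ",
           if (length(bad)) bad[1] else which(is.na(num))[1],
           ", column '", col, "'", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing value(s) in column '", col, "' (first at row ",
           which(is.na(v))[1], ")", call. = FALSE)
    }
    if (any(v <= 0)) {
      stop("non-positive abundance at row ", which(v <= 0)[1],
           ", column '", col, "' (marker values must be strictly positive)",
           call. = FALSE)
    }
  }
  tb
}

#' @rdname read_sample_table
#' @param table a sample table to write.
#' @export
write_sample_table <- function(table, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
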