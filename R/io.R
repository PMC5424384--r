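#' Read a participant records table
#'
#' Reads delimited text (`.csv`, `.tsv`, `.txt`) or, when the `readxl`
#' package is available, a spreadsheet (`.xlsx`). Column names in the file
#' can differ from the canonical ones (`id`, `sleep_min`, `st_min`,
#' `lpa_min`, `mvpa_min`, `sex`, `age`, `imd_decile`, `weight_status`,
#' `zbmi`, `whtr_pct`, `vo2peak`, `waist_cm`, `height_cm`): supply `col_map`
#' as `c(canonical = "file_column", ...)`.
#'
#' Row-level validation: behaviour durations must be positive and finite.
#' Offending rows are dropped (or zero values replaced, under
#' `zero_policy = "replace"`), recorded with their line numbers in the
#' `"validation"` attribute of the result, and summarised via [message()].
#' Missing behaviour columns are fatal.
#'
#' @param path Input file.
#' @param col_map Optional named character vector renaming file columns to
#'   canonical names.
#' @param sheet Sheet name or index for spreadsheet input.
#' @param zero_policy `"error"` (default: zero durations invalidate the row)
#'   or `"replace"` (multiplicative replacement via [replace_zeros()]).
#' @param delta Replacement value for `zero_policy = "replace"`.
#' @param part_cols Canonical behaviour columns, see [default_part_cols()].
#' @return A data frame of validated records; attribute `"validation"` holds
#'   a data frame of rejected/modified rows (`row`, `column`, `value`,
#'   `action`).
#' @export
read_records <- function(path, col_map = NULL, sheet = 1,
                         zero_policy = c("error", "replace"), delta = 0.5,
                         part_cols = default_part_cols()) {
  zero_policy <- match.arg(zero_policy)
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = ,
    txt = utils::read.delim(path, stringsAsFactors = FALSE),
    xlsx = ,
    xls = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("spreadsheet input requires the 'readxl' package")
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    },
    stop("unsupported input format: .", ext)
  )
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0L)
      stop("col_map refers to absent column(s): ", paste(missing_src, collapse = ", "))
    for (canon in names(col_map)) names(raw)[names(raw) == col_map[[canon]]] <- canon
  }
  need <- unname(part_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing behaviour column(s): ", paste(missing_cols, collapse = ", "))

  issues <- data.frame(row = integer(), column = character(),
                       value = numeric(), action = character())
  m <- as.matrix(raw[, need, drop = FALSE])
  storage.mode(m) <- "double"
  bad_row <- rep(FALSE, nrow(m))
  for (j in seq_along(need)) {
    v <- m[, j]
    neg <- which(!is.finite(v) | v < 0)
    zero <- which(v == 0)
    for (i in neg) issues <- rbind(issues, data.frame(
      row = i, column = need[j], value = v[i], action = "rejected"))
    bad_row[neg] <- TRUE
    if (length(zero) > 0L) {
      if (zero_policy == "error") {
        for (i in zero) issues <- rbind(issues, data.frame(
          row = i, column = need[j], value = 0, action = "rejected (zero)"))
        bad_row[zero] <- TRUE
      } else {
        for (i in zero) issues <- rbind(issues, data.frame(
          row = i, column = need[j], value = 0, action = sprintf("zero replaced (delta=%g)", delta)))
      }
    }
  }
  if (zero_policy == "replace") {
    keep <- !bad_row
    if (any(m[keep, , drop = FALSE] == 0))
      m[keep, ] <- replace_zeros(m[keep, , drop = FALSE], delta, quiet = TRUE)
    raw[, need] <- m
  }
  out <- raw[!bad_row, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(issues) > 0L)
    message(sprintf("read_records: %d row(s) rejected, %d value(s) flagged (see attr 'validation')",
                    sum(bad_row), nrow(issues)))
  attr(out, "validation") <- issues
  out
}

#' Waist-to-height ratio as a percentage
#'
#' Central adiposity indicator: 100 * waist / height, both in cm.
#'
#' @param waist_cm,height_cm Positive lengths in centimetres (vectorised).
#' @return Numeric percentage(s).
#' @examples
#' derive_whtr(64.3, 141.2)
#' @export
derive_whtr <- function(waist_cm, height_cm) {
  if (any(!is.finite(waist_cm) | waist_cm <= 0)) stop("waist must be positive")
  if (any(!is.finite(height_cm) | height_cm <= 0)) stop("height must be positive")
  100 * waist_cm / height_cm
}
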