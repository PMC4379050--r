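#' @keywords internal
"_PACKAGE"

# Fixed vocabularies of the two-line, two-day design. User-facing functions
# take lines/days from the sample sheet, so any two-group multi-day design
# works; these are only the defaults the simulator emits.
LINES <- c("Ross708", "Illinois")
DAYS <- c("D6", "D21")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_meta <- function(meta) {
  need <- c("sample_id", "line", "day", "total_mapped_reads")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop2("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop2("duplicate sample_id in sample sheet")
  if (any(!is.finite(meta$total_mapped_reads)) ||
      any(meta$total_mapped_reads <= 0))
    stop2("total_mapped_reads must be finite and > 0 for every sample")
  invisible(meta)
}

# samples of a given day (and optionally line); errors if empty
meta_samples <- function(meta, day, line = NULL) {
  keep <- meta$day == day
  if (!is.null(line)) keep <- keep & meta$line == line
  ids <- meta$sample_id[keep]
  if (length(ids) == 0)
    stop2("no samples for day '", day, "'",
          if (!is.null(line)) paste0(", line '", line, "'"))
  ids
}

# the two line labels present in a sample sheet, reference line first when
# the default vocabulary is used
meta_lines <- function(meta) {
  ln <- unique(meta$line)
  if (length(ln) != 2)
    stop2("expected exactly 2 lines in the sample sheet, found ",
          length(ln), ": ", paste(ln, collapse = ", "))
  if (setequal(ln, LINES)) LINES else sort(ln)
}

# row-wise means over a column subset of a matrix (0-col safe)
row_group_means <- function(m, cols) {
  rowMeans(m[, cols, drop = FALSE])
}
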