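#' MSP abundance tables
#'
#' An MSPs x samples abundance table, raw (marker-gene means) or normalized
#' per sample. A per-MSP provenance table (catalogue of origin, and for
#' merged species the id of the dropped counterpart) can ride along as an
#' attribute; it survives the writer/reader round trip via `#`-prefixed
#' metadata lines.
#'
#' @param abundance A data frame whose first column is `msp_id` and whose
#'   remaining columns are numeric per-sample abundances.
#' @param normalized Logical; `TRUE` when each sample column has been divided
#'   by its own sum.
#' @param origin Optional tibble `(msp_id, catalogue, merged_from)` recording
#'   each MSP's catalogue of origin after merging.
#' @return A tibble of class `oralgut_msp_tbl`.
#' @export
msp_table <- function(abundance, normalized = FALSE, origin = NULL) {
  abundance <- as_tibble(abundance)
  if (names(abundance)[1] != "msp_id") {
    names(abundance)[1] <- "msp_id"
  }
  abundance$msp_id <- as.character(abundance$msp_id)
  samples <- sample_cols(abundance)
  if (length(samples) == 0) {
    abort_format("MSP table has no sample columns (empty table).")
  }
  m <- as.matrix(abundance[, samples, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    abort_format("MSP abundances must be finite and non-negative.")
  }
  if (anyDuplicated(abundance$msp_id)) {
    abort_format("Duplicated msp_id in MSP table.")
  }
  if (isTRUE(normalized)) {
    sums <- colSums(m)
    live <- sums > 0
    if (any(abs(sums[live] - 1) > 1e-9)) {
      abort_format("Normalized table has sample columns not summing to 1.")
    }
  }
  structure(
    abundance,
    normalized = isTRUE(normalized),
    origin = origin,
    class = c("oralgut_msp_tbl", class(tibble()))
  )
}

#' @rdname msp_table
#' @param x An MSP table.
#' @export
is_normalized <- function(x) {
  isTRUE(attr(x, "normalized"))
}

#' Write / read an MSP abundance table as TSV
#'
#' The normalized flag is persisted in a `# normalized=true|false` header
#' comment; per-MSP provenance, when present, in `# origin:` lines. Written
#' tables round-trip: `read_msp_table(write_msp_table(x, p))` reproduces `x`
#' to better than 1e-12 per cell.
#'
#' @param x An [msp_table()].
#' @param path Output path.
#' @export
write_msp_table <- function(x, path) {
  stopifnot(inherits(x, "oralgut_msp_tbl"))
  samples <- sample_cols(x)
  if (length(samples) == 0 || nrow(x) == 0) {
    abort_input("Refusing to write an empty table.")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# normalized=", tolower(is_normalized(x))), con)
  origin <- attr(x, "origin")
  if (!is.null(origin)) {
    writeLines(paste0(
      "# origin: ", origin$msp_id, "\t", origin$catalogue, "\t",
      ifelse(is.na(origin$merged_from), ".", origin$merged_from)
    ), con)
  }
  body <- as_tibble(x)
  writeLines(paste(names(body), collapse = "\t"), con)
  m <- tbl_to_matrix(body)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_msp_table
#' @export
read_msp_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#")]
  normalized <- any(grepl("^#\\s*normalized=true\\s*$", meta))
  origin <- NULL
  olines <- meta[startsWith(meta, "# origin: ")]
  if (length(olines) > 0) {
    parts <- strsplit(sub("^# origin: ", "", olines), "\t", fixed = TRUE)
    origin <- tibble(
      msp_id = vapply(parts, `[`, character(1), 1),
      catalogue = vapply(parts, `[`, character(1), 2),
      merged_from = vapply(parts, `[`, character(1), 3)
    )
    origin$merged_from[origin$merged_from == "."] <- NA_character_
  }
  tbl <- read_clean_tsv(path)
  names(tbl)[1] <- "msp_id"
  msp_table(tbl, normalized = normalized, origin = origin)
}
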