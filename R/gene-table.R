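#' Gene abundance tables
#'
#' The pipeline's entry format: a genes x samples table of non-negative read
#' counts produced by mapping each sample's reads against the gut and oral
#' gene catalogues. Reads that map to no catalogue gene (host or unknown
#' sequence) are carried as a per-sample "unassigned" count so that mapping
#' rates can be reported; on disk they live in a sentinel `__unassigned__`
#' row.
#'
#' @param counts A data frame whose first column is `gene_id` and whose
#'   remaining columns are numeric per-sample counts.
#' @param unassigned Optional named numeric vector (one entry per sample) of
#'   reads assigned to no gene.
#' @return A tibble of class `oralgut_gene_tbl` with the `unassigned`
#'   attribute attached.
#' @export
gene_table <- function(counts, unassigned = NULL) {
  counts <- as_tibble(counts)
  if (names(counts)[1] != "gene_id") {
    names(counts)[1] <- "gene_id"
  }
  counts$gene_id <- as.character(counts$gene_id)
  samples <- sample_cols(counts)
  if (length(samples) == 0) {
    abort_format("Gene table has no sample columns.")
  }
  m <- as.matrix(counts[, samples, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    abort_format("Gene table counts must be finite numbers.")
  }
  if (any(m < 0)) {
    abort_format("Gene table contains negative counts.")
  }
  dup <- unique(counts$gene_id[duplicated(counts$gene_id)])
  if (length(dup) > 0) {
    abort_format(paste0(
      "Duplicated gene_id in gene table: ",
      paste(head(dup, 5), collapse = ", "), "."
    ))
  }
  if (!is.null(unassigned)) {
    if (is.null(names(unassigned))) {
      names(unassigned) <- samples
    }
    if (!setequal(names(unassigned), samples)) {
      abort_format("`unassigned` names must match the sample columns.")
    }
    unassigned <- unassigned[samples]
    if (any(unassigned < 0)) {
      abort_format("`unassigned` counts must be non-negative.")
    }
  }
  structure(
    counts,
    unassigned = unassigned,
    class = c("oralgut_gene_tbl", class(tibble()))
  )
}

#' @rdname gene_table
#' @param x A gene table.
#' @return `unassigned_counts()` returns the per-sample unassigned read
#'   counts (zeros when the table carries none).
#' @export
unassigned_counts <- function(x) {
  stopifnot(inherits(x, "oralgut_gene_tbl"))
  ua <- attr(x, "unassigned")
  if (is.null(ua)) {
    setNames(rep(0, length(sample_cols(x))), sample_cols(x))
  } else {
    ua
  }
}

#' Read a gene abundance table from TSV
#'
#' Expects a header row of sample ids, a first column `gene_id`, and numeric
#' cells; `#`-prefixed lines are comments. A `__unassigned__` row, if
#' present, is moved into the table's unassigned field.
#'
#' @param path Path to the TSV file.
#' @return An [gene_table()] object, row order of the file preserved.
#' @export
read_gene_table <- function(path) {
  tbl <- read_clean_tsv(path)
  if (ncol(tbl) < 2) {
    abort_format(paste0("'", path, "' has no sample columns."))
  }
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  ua <- NULL
  sentinel <- tbl$gene_id == "__unassigned__"
  if (any(sentinel)) {
    if (sum(sentinel) > 1) {
      abort_format("More than one __unassigned__ row.")
    }
    ua_row <- tbl[sentinel, -1, drop = FALSE]
    ua <- setNames(as.numeric(ua_row[1, ]), names(ua_row))
    tbl <- tbl[!sentinel, , drop = FALSE]
  }
  gene_table(tbl, unassigned = ua)
}

#' @rdname read_gene_table
#' @param x A gene table to write.
#' @export
write_gene_table <- function(x, path) {
  stopifnot(inherits(x, "oralgut_gene_tbl"))
  out <- as_tibble(x)
  ua <- attr(x, "unassigned")
  if (!is.null(ua)) {
    ua_row <- as_tibble(as.list(ua))
    ua_row <- bind_cols(tibble(gene_id = "__unassigned__"), ua_row)
    out <- bind_rows(out, ua_row)
  }
  readr::write_tsv(out, path)
  invisible(path)
}
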