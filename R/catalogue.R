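#' Gene catalogue objects
#'
#' A gene catalogue maps every reference gene to its metagenomic species
#' pangenome (MSP), flags the fixed subset of marker genes whose mean
#' abundance estimates the species abundance, carries a relative length
#' weight, and records which catalogue (gut or oral) the gene comes from.
#' Overlap pairs declare that a gut-catalogue MSP and an oral-catalogue MSP
#' represent the same species, so the two per-catalogue abundance tables can
#' be merged without double counting.
#'
#' @param genes A data frame with columns `gene_id`, `msp_id`,
#'   `is_marker` (logical or 0/1), `length_weight` (positive), and
#'   `catalogue` (`"gut"` or `"oral"`).
#' @param overlaps A data frame with columns `gut_msp_id`, `oral_msp_id`
#'   (may have zero rows).
#' @param markers_per_msp Declared number of marker genes per MSP
#'   (default 100, must be >= 10).
#' @return An object of class `oralgut_catalogue`: a list with elements
#'   `genes` (tibble), `overlaps` (tibble) and `markers_per_msp`.
#' @seealso [validate_catalogue()], [build_catalogue_pair()]
#' @export
gene_catalogue <- function(genes, overlaps = NULL, markers_per_msp = 100) {
  if (markers_per_msp < 10) {
    abort_config("`markers_per_msp` must be at least 10.")
  }
  genes <- as_tibble(genes)
  need <- c("gene_id", "msp_id", "is_marker", "length_weight", "catalogue")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort_format(paste0(
      "Catalogue is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  genes <- mutate(genes,
    gene_id = as.character(.data$gene_id),
    msp_id = as.character(.data$msp_id),
    is_marker = as.logical(.data$is_marker),
    length_weight = as.numeric(.data$length_weight),
    catalogue = as.character(.data$catalogue)
  )
  if (is.null(overlaps)) {
    overlaps <- tibble(gut_msp_id = character(), oral_msp_id = character())
  }
  overlaps <- as_tibble(overlaps)
  if (!all(c("gut_msp_id", "oral_msp_id") %in% names(overlaps))) {
    abort_format("Overlap table needs columns `gut_msp_id` and `oral_msp_id`.")
  }
  overlaps <- mutate(overlaps,
    gut_msp_id = as.character(.data$gut_msp_id),
    oral_msp_id = as.character(.data$oral_msp_id)
  )
  structure(
    list(
      genes = genes,
      overlaps = overlaps,
      markers_per_msp = as.integer(markers_per_msp)
    ),
    class = "oralgut_catalogue"
  )
}

#' @export
print.oralgut_catalogue <- function(x, ...) {
  by_cat <- table(distinct(x$genes, .data$msp_id, .data$catalogue)$catalogue)
  cat("<oralgut gene catalogue>\n")
  cat("  genes:   ", nrow(x$genes), "\n", sep = "")
  cat("  MSPs:    ", paste(names(by_cat), unname(by_cat), collapse = ", "),
      "\n", sep = "")
  cat("  overlaps:", nrow(x$overlaps), "\n")
  cat("  markers/MSP:", x$markers_per_msp, "\n")
  invisible(x)
}

#' Validate a gene catalogue against its structural invariants
#'
#' Checks, without mutating its input: gene ids unique across both
#' catalogues; every MSP confined to one catalogue, with at least one gene
#' and exactly the declared number of marker genes; length weights strictly
#' positive; catalogue labels in `{gut, oral}`; each overlap pair referencing
#' one existing gut MSP and one existing oral MSP, each MSP used in at most
#' one pair.
#'
#' @param cat An [gene_catalogue()] object.
#' @return A tibble of violations with columns `check` and `message`;
#'   zero rows when every invariant holds.
#' @export
validate_catalogue <- function(cat) {
  stopifnot(inherits(cat, "oralgut_catalogue"))
  v <- list()
  add <- function(check, message) {
    v[[length(v) + 1]] <<- tibble(check = check, message = message)
  }

  dup <- unique(cat$genes$gene_id[duplicated(cat$genes$gene_id)])
  for (g in dup) {
    add("duplicate_gene", paste0("gene_id '", g, "' appears more than once"))
  }
  bad_cat <- unique(cat$genes$catalogue[!cat$genes$catalogue %in% c("gut", "oral")])
  for (b in bad_cat) {
    add("bad_catalogue", paste0("unknown catalogue label '", b, "'"))
  }
  bad_lw <- unique(cat$genes$msp_id[!is.finite(cat$genes$length_weight) |
                                      cat$genes$length_weight <= 0])
  for (m in bad_lw) {
    add("bad_length_weight",
        paste0("MSP '", m, "' has non-positive or non-finite length weights"))
  }

  per_msp <- summarise(
    group_by(cat$genes, .data$msp_id),
    n_genes = n(),
    n_markers = sum(.data$is_marker),
    n_cat = length(unique(.data$catalogue)),
    .groups = "drop"
  )
  for (i in which(per_msp$n_markers != cat$markers_per_msp)) {
    add("marker_count", paste0(
      "MSP '", per_msp$msp_id[i], "' has ", per_msp$n_markers[i],
      " marker genes, expected ", cat$markers_per_msp
    ))
  }
  for (i in which(per_msp$n_cat > 1)) {
    add("msp_split", paste0(
      "MSP '", per_msp$msp_id[i], "' spans both catalogues"
    ))
  }

  msp_cat <- distinct(cat$genes, .data$msp_id, .data$catalogue)
  gut_ids <- msp_cat$msp_id[msp_cat$catalogue == "gut"]
  oral_ids <- msp_cat$msp_id[msp_cat$catalogue == "oral"]
  ov <- cat$overlaps
  if (nrow(ov) > 0) {
    for (i in seq_len(nrow(ov))) {
      if (!ov$gut_msp_id[i] %in% gut_ids) {
        add("overlap_ref", paste0(
          "overlap pair ", i, ": '", ov$gut_msp_id[i],
          "' is not a gut-catalogue MSP"
        ))
      }
      if (!ov$oral_msp_id[i] %in% oral_ids) {
        add("overlap_ref", paste0(
          "overlap pair ", i, ": '", ov$oral_msp_id[i],
          "' is not an oral-catalogue MSP"
        ))
      }
    }
    for (g in unique(ov$gut_msp_id[duplicated(ov$gut_msp_id)])) {
      add("overlap_dup", paste0("gut MSP '", g, "' used in more than one pair"))
    }
    for (o in unique(ov$oral_msp_id[duplicated(ov$oral_msp_id)])) {
      add("overlap_dup", paste0("oral MSP '", o, "' used in more than one pair"))
    }
  }

  if (length(v) == 0) {
    tibble(check = character(), message = character())
  } else {
    bind_rows(v)
  }
}

#' Read and write catalogue, overlap, taxonomy and sample-metadata tables
#'
#' Plain-text TSV interchange for the pipeline's side tables. All files are
#' tab-separated, UTF-8, `.` decimal, with `#`-prefixed comment lines.
#' The catalogue file has columns `gene_id, msp_id, is_marker (0/1),
#' length_weight, catalogue (gut|oral)`; the overlap file `gut_msp_id,
#' oral_msp_id`; taxonomy `msp_id, species, genus, family, phylum`;
#' sample metadata `sample_id, donor, sample_type, day, is_baseline`.
#'
#' @param path File path.
#' @param overlaps_path Optional path of the overlap-pair TSV.
#' @param markers_per_msp Declared marker count, stored on the object.
#' @return `read_catalogue()` returns an [gene_catalogue()];
#'   `read_taxonomy()` and `read_sample_meta()` return tibbles.
#' @name catalogue_io
NULL

#' @rdname catalogue_io
#' @export
read_catalogue <- function(path, overlaps_path = NULL, markers_per_msp = 100) {
  genes <- read_clean_tsv(path)
  overlaps <- if (!is.null(overlaps_path)) read_clean_tsv(overlaps_path)
  gene_catalogue(genes, overlaps, markers_per_msp = markers_per_msp)
}

#' @rdname catalogue_io
#' @param cat A catalogue object to write.
#' @export
write_catalogue <- function(cat, path, overlaps_path = NULL) {
  stopifnot(inherits(cat, "oralgut_catalogue"))
  genes <- mutate(cat$genes, is_marker = as.integer(.data$is_marker))
  readr::write_tsv(genes, path)
  if (!is.null(overlaps_path)) {
    readr::write_tsv(cat$overlaps, overlaps_path)
  }
  invisible(path)
}

#' @rdname catalogue_io
#' @export
read_taxonomy <- function(path) {
  tax <- read_clean_tsv(path)
  need <- c("msp_id", "species", "genus", "family", "phylum")
  missing <- setdiff(need, names(tax))
  if (length(missing) > 0) {
    abort_format(paste0(
      "Taxonomy file is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(tax$msp_id)) {
    abort_format("Taxonomy file has duplicated msp_id values.")
  }
  tax
}

#' @rdname catalogue_io
#' @export
read_sample_meta <- function(path) {
  meta <- read_clean_tsv(path)
  need <- c("sample_id", "donor", "sample_type", "day", "is_baseline")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort_format(paste0(
      "Sample metadata is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  mutate(meta,
    sample_id = as.character(.data$sample_id),
    donor = as.character(.data$donor),
    sample_type = as.character(.data$sample_type),
    day = suppressWarnings(as.integer(.data$day)),
    is_baseline = as.logical(.data$is_baseline)
  )
}

# shared strict TSV reader: dies on ragged rows, honours '#' comments
read_clean_tsv <- function(path) {
  # readr warns on parsing issues; we inspect problems() and escalate to a
  # classed format error instead
  out <- suppressWarnings(readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    na = c("", "NA")
  ))
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    abort_format(paste0(
      "Malformed TSV '", path, "': e.g. row ", pr$row[1], ", ", pr$expected[1],
      " expected but ", pr$actual[1], " found."
    ))
  }
  out
}

# Validate sample metadata invariants (one baseline stool + one baseline raw
# saliva per donor; bioreactor samples carry a day).
check_sample_meta <- function(meta) {
  for (d in unique(meta$donor)) {
    md <- meta[meta$donor == d, ]
    n_stool <- sum(md$sample_type == "stool" & md$is_baseline)
    n_sal <- sum(md$sample_type == "raw_saliva" & md$is_baseline)
    if (n_stool != 1 || n_sal != 1) {
      abort_input(paste0(
        "Donor '", d, "' must have exactly one baseline stool and one ",
        "baseline raw_saliva sample (found ", n_stool, " and ", n_sal, ")."
      ))
    }
    bior <- md[md$sample_type %in% c("luminal", "mucosal"), ]
    if (nrow(bior) > 0 && anyNA(bior$day)) {
      abort_input(paste0("Donor '", d, "': luminal/mucosal samples need a day."))
    }
  }
  invisible(meta)
}
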