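#' Quantify MSP abundances from gene counts
#'
#' Implements the marker-gene quantification rule: the abundance of an MSP
#' in a sample is the arithmetic mean of all of its marker genes' abundances
#' (zeros included), provided at least `min_marker_fraction` of those marker
#' genes are detected (abundance strictly positive) in that sample — the
#' detection boundary is inclusive, `d >= ceiling(fraction * n_markers)`.
#' Below the threshold the MSP's abundance is set to 0. Non-marker genes are
#' ignored.
#'
#' @param genes An [gene_table()]; every marker gene of the catalogue must
#'   be present as a row.
#' @param cat An [gene_catalogue()].
#' @param min_marker_fraction Detection threshold as a fraction of the
#'   MSP's marker genes, in `(0, 1]` (default 0.10).
#' @param length_normalize Divide each gene's count by its length weight
#'   before averaging (off by default; raw counts are used).
#' @return A named list with one raw [msp_table()] per catalogue
#'   (`$gut`, `$oral`; a catalogue with no MSPs yields `NULL`).
#' @export
quantify_msp <- function(genes, cat, min_marker_fraction = 0.10,
                         length_normalize = FALSE) {
  stopifnot(inherits(genes, "oralgut_gene_tbl"),
            inherits(cat, "oralgut_catalogue"))
  if (min_marker_fraction <= 0 || min_marker_fraction > 1) {
    abort_config("`min_marker_fraction` must lie in (0, 1].")
  }
  counts <- tbl_to_matrix(as_tibble(genes))
  markers <- cat$genes[cat$genes$is_marker, , drop = FALSE]
  missing <- setdiff(markers$gene_id, rownames(counts))
  if (length(missing) > 0) {
    abort_input(paste0(
      "Marker gene(s) missing from the gene table: ",
      paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else "", "."
    ))
  }
  out <- list()
  for (w in c("gut", "oral")) {
    mk <- markers[markers$catalogue == w, , drop = FALSE]
    if (nrow(mk) == 0) {
      out[[w]] <- NULL
      next
    }
    m <- counts[mk$gene_id, , drop = FALSE]
    if (length_normalize) {
      m <- m / mk$length_weight
    }
    grp <- mk$msp_id
    n_markers <- as.vector(table(grp)[unique(grp)])
    names(n_markers) <- unique(grp)
    sums <- rowsum(m, grp, reorder = FALSE)
    det <- rowsum((m > 0) * 1, grp, reorder = FALSE)
    n_mk <- n_markers[rownames(sums)]
    mean_ab <- sums / n_mk
    detected <- det >= ceiling(min_marker_fraction * n_mk)
    ab <- mean_ab * detected
    out[[w]] <- msp_table(
      matrix_to_tbl(ab, "msp_id"),
      normalized = FALSE,
      origin = tibble(msp_id = rownames(ab), catalogue = w,
                      merged_from = NA_character_)
    )
  }
  out
}

#' Merge the gut and oral MSP tables into one species table
#'
#' The merged table contains every gut MSP and every oral MSP except that,
#' for each declared overlap pair (one gut MSP and one oral MSP that
#' represent the same species), the oral member is dropped and the retained
#' gut identifier's abundance is combined per sample according to `rule`:
#' the elementwise maximum of the pair (default; never discards signal, no
#' double counting), the gut value alone, or their sum. Provenance of every
#' retained MSP is recorded in the result's `origin` attribute.
#'
#' @param gut,oral Raw [msp_table()]s with identical sample sets.
#' @param overlaps A tibble `(gut_msp_id, oral_msp_id)`.
#' @param rule Overlap combination rule: `"max"`, `"keep-gut"` or `"sum"`.
#' @return A single raw [msp_table()] with
#'   `nrow = nrow(gut) + nrow(oral) - nrow(overlaps)`.
#' @export
merge_msp_tables <- function(gut, oral, overlaps, rule = c("max", "keep-gut", "sum")) {
  rule <- match.arg(rule)
  stopifnot(inherits(gut, "oralgut_msp_tbl"), inherits(oral, "oralgut_msp_tbl"))
  if (!setequal(sample_cols(gut), sample_cols(oral))) {
    abort_input("Gut and oral tables must cover the same samples.")
  }
  overlaps <- as_tibble(overlaps)
  bad_g <- setdiff(overlaps$gut_msp_id, gut$msp_id)
  bad_o <- setdiff(overlaps$oral_msp_id, oral$msp_id)
  if (length(bad_g) + length(bad_o) > 0) {
    abort_input(paste0(
      "Overlap pair references unknown MSP(s): ",
      paste(head(c(bad_g, bad_o), 5), collapse = ", "), "."
    ))
  }
  gm <- tbl_to_matrix(as_tibble(gut))
  om <- tbl_to_matrix(as_tibble(oral))[, colnames(gm), drop = FALSE]

  merged <- gm
  merged_from <- setNames(rep(NA_character_, nrow(gm)), rownames(gm))
  if (nrow(overlaps) > 0) {
    pair_oral <- om[overlaps$oral_msp_id, , drop = FALSE]
    pair_gut <- gm[overlaps$gut_msp_id, , drop = FALSE]
    combined <- switch(rule,
      "max" = pmax(pair_gut, pair_oral),
      "keep-gut" = pair_gut,
      "sum" = pair_gut + pair_oral
    )
    merged[overlaps$gut_msp_id, ] <- combined
    merged_from[overlaps$gut_msp_id] <- overlaps$oral_msp_id
  }
  oral_keep <- om[setdiff(rownames(om), overlaps$oral_msp_id), , drop = FALSE]
  all_m <- rbind(merged, oral_keep)
  origin <- tibble(
    msp_id = rownames(all_m),
    catalogue = c(rep("gut", nrow(merged)), rep("oral", nrow(oral_keep))),
    merged_from = c(unname(merged_from), rep(NA_character_, nrow(oral_keep)))
  )
  msp_table(matrix_to_tbl(all_m, "msp_id"), normalized = FALSE, origin = origin)
}

#' Normalize an MSP table per sample
#'
#' Divides every sample column by the summed abundance of the MSPs detected
#' in that sample, so each column of the result sums to 1.
#'
#' @param table A raw [msp_table()].
#' @return The normalized [msp_table()] (`normalized` flag set).
#' @export
normalize_msp <- function(table) {
  stopifnot(inherits(table, "oralgut_msp_tbl"))
  if (is_normalized(table)) {
    abort_input("Table is already normalized.")
  }
  m <- tbl_to_matrix(as_tibble(table))
  sums <- colSums(m)
  dead <- colnames(m)[sums <= 0]
  if (length(dead) > 0) {
    abort_input(paste0(
      "No detected MSP in sample(s): ", paste(dead, collapse = ", "), "."
    ))
  }
  m <- sweep(m, 2, sums, "/")
  msp_table(matrix_to_tbl(m, "msp_id"), normalized = TRUE,
            origin = attr(table, "origin"))
}

#' Per-sample MSP richness
#'
#' Counts the MSPs detected (abundance strictly positive) in each sample,
#' conventionally on the merged MSP table.
#'
#' @param table An [msp_table()], raw or normalized.
#' @return A tibble `(sample_id, richness)`.
#' @export
msp_richness <- function(table) {
  stopifnot(inherits(table, "oralgut_msp_tbl"))
  m <- tbl_to_matrix(as_tibble(table))
  tibble(sample_id = colnames(m), richness = as.integer(colSums(m > 0)))
}

#' Downsample every sample of a gene table to a fixed read depth
#'
#' Rarefies each sample to `depth` reads by drawing without replacement from
#' that sample's reads — a multivariate hypergeometric draw over the gene
#' rows plus the unassigned pool — so sequencing effort is equalized before
#' profiling. Column totals (assigned + unassigned) equal `depth` exactly.
#'
#' @param genes An [gene_table()] with integer counts.
#' @param depth Target reads per sample; every sample must have at least
#'   `depth` reads.
#' @param seed Integer seed.
#' @return The downsampled [gene_table()].
#' @export
downsample_genes <- function(genes, depth, seed) {
  stopifnot(inherits(genes, "oralgut_gene_tbl"))
  m <- tbl_to_matrix(as_tibble(genes))
  if (any(m %% 1 != 0)) {
    abort_input("Downsampling needs integer counts.")
  }
  ua <- unassigned_counts(genes)
  totals <- colSums(m) + ua
  short <- colnames(m)[totals < depth]
  if (length(short) > 0) {
    abort_input(paste0(
      "Sample(s) with fewer than ", depth, " reads: ",
      paste(short, collapse = ", "), "."
    ))
  }
  out <- m
  ua_out <- ua
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      v <- c(m[, j], ua[j])
      total <- sum(v)
      if (total == depth) next
      idx <- sample.int(total, depth)
      cum <- cumsum(v)
      cat_idx <- findInterval(idx - 1, cum) + 1L
      new <- tabulate(cat_idx, nbins = length(v))
      out[, j] <- new[-length(new)]
      ua_out[j] <- new[length(new)]
    }
  })
  gene_table(matrix_to_tbl(out, "gene_id"),
             unassigned = if (is.null(attr(genes, "unassigned"))) NULL else ua_out)
}

#' Per-sample mapping rates onto each catalogue
#'
#' The fraction of each sample's total reads (assigned + unassigned) that
#' landed on genes of the gut catalogue, on genes of the oral catalogue, and
#' on neither; the three fractions sum to 1 per sample.
#'
#' @param genes An [gene_table()] whose unassigned field is present.
#' @param cat An [gene_catalogue()].
#' @return A tibble `(sample_id, gut, oral, unassigned)`.
#' @export
mapping_rate <- function(genes, cat) {
  stopifnot(inherits(genes, "oralgut_gene_tbl"),
            inherits(cat, "oralgut_catalogue"))
  if (is.null(attr(genes, "unassigned"))) {
    abort_input("Gene table carries no unassigned counts.")
  }
  m <- tbl_to_matrix(as_tibble(genes))
  ua <- unassigned_counts(genes)
  cat_of <- setNames(cat$genes$catalogue, cat$genes$gene_id)[rownames(m)]
  if (anyNA(cat_of)) {
    abort_input("Gene table contains genes absent from the catalogue.")
  }
  gut <- colSums(m[cat_of == "gut", , drop = FALSE])
  oral <- colSums(m[cat_of == "oral", , drop = FALSE])
  totals <- gut + oral + ua
  tibble(
    sample_id = colnames(m),
    gut = unname(gut / totals),
    oral = unname(oral / totals),
    unassigned = unname(ua / totals)
  )
}
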