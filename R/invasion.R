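#' Assign each MSP an ecological niche from the baseline samples
#'
#' A species' niche is read off its strict occurrence in the two baseline
#' samples collected before (or independently of) the bioreactor run:
#' detected (abundance > `floor`) in baseline stool only -> `gut`; in
#' baseline raw saliva only -> `oral`; detected in both, or in neither ->
#' `ND` (not determined). Multi-donor tables are processed per donor, each
#' against its own pair of baselines.
#'
#' @param merged A merged [msp_table()] (raw or normalized) containing the
#'   baseline samples.
#' @param meta Sample metadata tibble with columns `sample_id`, `donor`,
#'   `sample_type`, `day`, `is_baseline`; exactly one baseline `stool` and
#'   one baseline `raw_saliva` per donor.
#' @param floor Detection floor for the baselines (default 0: strictly
#'   positive abundance counts as detected).
#' @return A tibble `(donor, msp_id, niche)` covering every MSP of the
#'   table for every donor, `niche` one of `"gut"`, `"oral"`, `"ND"`.
#' @export
assign_niches <- function(merged, meta, floor = 0) {
  stopifnot(inherits(merged, "oralgut_msp_tbl"))
  meta <- as_tibble(meta)
  check_sample_meta(meta)
  m <- tbl_to_matrix(as_tibble(merged))
  out <- list()
  for (d in unique(meta$donor)) {
    md <- meta[meta$donor == d, ]
    stool_id <- md$sample_id[md$sample_type == "stool" & md$is_baseline]
    sal_id <- md$sample_id[md$sample_type == "raw_saliva" & md$is_baseline]
    if (!stool_id %in% colnames(m) || !sal_id %in% colnames(m)) {
      abort_input(paste0(
        "Baseline sample(s) of donor '", d, "' missing from the MSP table."
      ))
    }
    in_stool <- m[, stool_id] > floor
    in_sal <- m[, sal_id] > floor
    niche <- ifelse(in_stool & !in_sal, "gut",
                    ifelse(in_sal & !in_stool, "oral", "ND"))
    out[[d]] <- tibble(donor = d, msp_id = rownames(m), niche = unname(niche))
  }
  bind_rows(out)
}

#' Niche-split richness and relative abundance per sample
#'
#' For every sample, the number of detected MSPs and their summed relative
#' abundance are split by ecological niche (gut, oral, ND). The three
#' richness values sum to the sample's total richness; with a normalized
#' table the three abundance shares sum to 1 for any sample with detections.
#'
#' @param merged A merged [msp_table()] (normalized for meaningful
#'   abundance shares; shares are computed relative to each column's sum).
#' @param niches Output of [assign_niches()].
#' @param meta Sample metadata tibble.
#' @return A long tibble `(sample_id, donor, sample_type, day, niche,
#'   richness, rel_abundance)` with `niche` ordered gut, oral, ND.
#' @export
niche_series <- function(merged, niches, meta) {
  stopifnot(inherits(merged, "oralgut_msp_tbl"))
  meta <- as_tibble(meta)
  m <- tbl_to_matrix(as_tibble(merged))
  levels <- c("gut", "oral", "ND")
  out <- list()
  for (d in unique(meta$donor)) {
    nd <- niches[niches$donor == d, ]
    missing <- setdiff(rownames(m), nd$msp_id)
    if (length(missing) > 0) {
      abort_input(paste0(
        "Niche map of donor '", d, "' does not cover MSP(s): ",
        paste(head(missing, 5), collapse = ", "), "."
      ))
    }
    lab <- setNames(nd$niche, nd$msp_id)[rownames(m)]
    md <- meta[meta$donor == d & meta$sample_id %in% colnames(m), ]
    for (i in seq_len(nrow(md))) {
      s <- md$sample_id[i]
      v <- m[, s]
      tot <- sum(v)
      rich <- tapply(v > 0, factor(lab, levels = levels), sum)
      ab <- tapply(v, factor(lab, levels = levels), sum)
      out[[length(out) + 1]] <- tibble(
        sample_id = s, donor = d, sample_type = md$sample_type[i],
        day = md$day[i], niche = levels,
        richness = as.integer(ifelse(is.na(rich), 0, rich)),
        rel_abundance = as.numeric(ifelse(is.na(ab), 0, ab)) /
          ifelse(tot > 0, tot, 1)
      )
    }
  }
  bind_rows(out)
}

#' Track oral invader species across the bioreactor compartments
#'
#' An oral invader is an oral-niche MSP detected in at least one luminal or
#' mucosal sample on any day. For each donor the function returns the
#' per-sample normalized abundance of every invader across all bioreactor
#' samples, and a per-compartment, per-day count of detected oral MSPs
#' annotated with the invasion phase (`pre` for days before
#' `first_injection_day`, `post` otherwise). Invaders already detected in a
#' pre-injection bioreactor sample are flagged `pre_existing`.
#'
#' @param merged A *normalized* merged [msp_table()].
#' @param niches Output of [assign_niches()].
#' @param meta Sample metadata tibble (must contain luminal/mucosal
#'   samples).
#' @param first_injection_day First saliva injection day (default 9);
#'   samples with `day < first_injection_day` are pre-invasion.
#' @return A list with `invader_matrix` (long tibble `donor, msp_id,
#'   pre_existing, sample_id, sample_type, day, abundance`) and
#'   `invader_summary` (tibble `donor, sample_type, day, phase,
#'   n_oral_detected`).
#' @export
detect_oral_invaders <- function(merged, niches, meta, first_injection_day = 9) {
  stopifnot(inherits(merged, "oralgut_msp_tbl"))
  if (!is_normalized(merged)) {
    abort_input("`merged` must be a normalized table.")
  }
  meta <- as_tibble(meta)
  m <- tbl_to_matrix(as_tibble(merged))
  mat_rows <- list()
  summ_rows <- list()
  for (d in unique(meta$donor)) {
    md <- meta[meta$donor == d &
                 meta$sample_type %in% c("luminal", "mucosal") &
                 meta$sample_id %in% colnames(m), ]
    if (nrow(md) == 0) {
      abort_input(paste0("No bioreactor samples for donor '", d, "'."))
    }
    nd <- niches[niches$donor == d, ]
    oral_msps <- nd$msp_id[nd$niche == "oral"]
    sub <- m[intersect(oral_msps, rownames(m)), md$sample_id, drop = FALSE]
    detected_any <- rownames(sub)[rowSums(sub > 0) > 0]
    pre_samples <- md$sample_id[md$day < first_injection_day]
    pre_existing <- rownames(sub)[rowSums(sub[, pre_samples, drop = FALSE] > 0) > 0]
    if (length(detected_any) > 0) {
      long <- as_tibble(sub[detected_any, , drop = FALSE], rownames = "msp_id") |>
        tidyr::pivot_longer(-"msp_id", names_to = "sample_id",
                            values_to = "abundance")
      mat_rows[[d]] <- long |>
        left_join(select(md, "sample_id", "sample_type", "day"), by = "sample_id") |>
        mutate(donor = d, pre_existing = .data$msp_id %in% pre_existing) |>
        select("donor", "msp_id", "pre_existing", "sample_id",
               "sample_type", "day", "abundance")
    }
    summ_rows[[d]] <- tibble(
      donor = d,
      sample_type = md$sample_type,
      day = md$day,
      phase = ifelse(md$day < first_injection_day, "pre", "post"),
      n_oral_detected = as.integer(colSums(sub[, md$sample_id, drop = FALSE] > 0))
    )
  }
  empty_matrix <- tibble(
    donor = character(), msp_id = character(), pre_existing = logical(),
    sample_id = character(), sample_type = character(), day = integer(),
    abundance = double()
  )
  list(
    invader_matrix = bind_rows(c(list(empty_matrix), mat_rows)),
    invader_summary = bind_rows(summ_rows)
  )
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))` on the
#' normalized per-sample compositions; symmetric, zero on the diagonal,
#' values in `[0, 1]` with 1 for disjoint support.
#'
#' @param table A *normalized* [msp_table()].
#' @return A tibble, first column `sample_id`, then one column per sample
#'   with the pairwise dissimilarities.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "oralgut_msp_tbl"))
  if (!is_normalized(table)) {
    abort_input("Bray-Curtis requires a normalized table.")
  }
  m <- tbl_to_matrix(as_tibble(table))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  matrix_to_tbl(d, "sample_id")
}

#' Aggregate a normalized MSP table at a taxonomic rank
#'
#' Sums the normalized abundances of all MSPs sharing the same value of the
#' chosen rank; MSPs missing from the taxonomy, or with an empty rank value,
#' are pooled under `"unclassified"` (missing MSPs trigger a warning, not an
#' error). Per-sample column sums are preserved.
#'
#' @param table A *normalized* [msp_table()].
#' @param tax Taxonomy tibble `(msp_id, species, genus, family, phylum)`.
#' @param rank One of `"phylum"`, `"family"`, `"genus"`.
#' @return A tibble, first column named after `rank`, one column per
#'   sample.
#' @export
aggregate_by_rank <- function(table, tax, rank = c("phylum", "family", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "oralgut_msp_tbl"))
  if (!is_normalized(table)) {
    abort_input("Rank aggregation requires a normalized table.")
  }
  m <- tbl_to_matrix(as_tibble(table))
  tax <- as_tibble(tax)
  lab <- setNames(as.character(tax[[rank]]), tax$msp_id)[rownames(m)]
  n_missing <- sum(!rownames(m) %in% tax$msp_id)
  if (n_missing > 0) {
    warn(paste0(n_missing, " MSP(s) absent from the taxonomy; ",
                "pooled as 'unclassified'."))
  }
  lab[is.na(lab) | lab == ""] <- "unclassified"
  agg <- rowsum(m, lab, reorder = TRUE)
  out <- matrix_to_tbl(agg, rank)
  out
}

#' Spearman correlation of invader abundances between two samples
#'
#' Rank-correlates the abundances of a set of invader MSPs in a source
#' sample (typically the enriched saliva) against a target sample (typically
#' a mucosal sample), with average-rank tie handling and a two-sided p-value
#' from the t approximation (an exact p-value can be requested for small
#' invader sets).
#'
#' @param table An [msp_table()] containing both samples.
#' @param source_sample,target_sample Sample ids.
#' @param invaders Character vector of MSP ids (at least 3).
#' @param exact Use the exact null distribution (only sensible for
#'   `length(invaders) <= 10`; default `FALSE`, the t approximation).
#' @return A tibble `(source, target, rho, p_value, n)`.
#' @export
invader_correlation <- function(table, source_sample, target_sample,
                                invaders, exact = FALSE) {
  stopifnot(inherits(table, "oralgut_msp_tbl"))
  invaders <- unique(as.character(invaders))
  if (length(invaders) < 3) {
    abort_input("Correlation undefined: fewer than 3 invaders.")
  }
  m <- tbl_to_matrix(as_tibble(table))
  missing <- setdiff(invaders, rownames(m))
  if (length(missing) > 0) {
    abort_input(paste0("Invader MSP(s) absent from the table: ",
                       paste(head(missing, 5), collapse = ", "), "."))
  }
  for (s in c(source_sample, target_sample)) {
    if (!s %in% colnames(m)) {
      abort_input(paste0("Sample '", s, "' absent from the table."))
    }
  }
  x <- m[invaders, source_sample]
  y <- m[invaders, target_sample]
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact, alternative = "two.sided")
  )
  tibble(
    source = source_sample, target = target_sample,
    rho = unname(ct$estimate), p_value = ct$p.value, n = length(invaders)
  )
}
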