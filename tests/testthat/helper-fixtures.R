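# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no fixture files.

# A tiny hand-built catalogue: n_gut/n_oral/n_shared MSPs, `markers` marker
# genes and `extra` non-marker genes each, unit length weights.
tiny_catalogue <- function(n_gut = 2, n_oral = 2, n_shared = 1,
                           markers = 10, extra = 0) {
  msp <- function(ids, cat) {
    g <- markers + extra
    if (length(ids) == 0) {
      return(tibble::tibble(gene_id = character(), msp_id = character(),
                            is_marker = logical(), length_weight = numeric(),
                            catalogue = character()))
    }
    tibble::tibble(
      gene_id = paste0(rep(ids, each = g), "_g", seq_len(g)),
      msp_id = rep(ids, each = g),
      is_marker = rep(seq_len(g) <= markers, length(ids)),
      length_weight = 1,
      catalogue = cat
    )
  }
  gut_ids <- c(sprintf("G%02d", seq_len(n_gut)),
               sprintf("GS%02d", seq_len(n_shared)))
  oral_ids <- c(sprintf("O%02d", seq_len(n_oral)),
                sprintf("OS%02d", seq_len(n_shared)))
  genes <- dplyr::bind_rows(msp(gut_ids, "gut"), msp(oral_ids, "oral"))
  overlaps <- tibble::tibble(
    gut_msp_id = sprintf("GS%02d", seq_len(n_shared)),
    oral_msp_id = sprintf("OS%02d", seq_len(n_shared))
  )
  gene_catalogue(genes, overlaps, markers_per_msp = markers)
}

# Gene table over a catalogue's genes with supplied per-sample count vectors.
genes_from_counts <- function(cat, counts, unassigned = NULL) {
  stopifnot(nrow(counts) == nrow(cat$genes))
  tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = cat$genes$gene_id),
    tibble::as_tibble(counts)
  )
  gene_table(tbl, unassigned = unassigned)
}

# Random gene counts for a catalogue: per MSP and sample, each marker is
# positive with probability `p_pos`; positives get uniform values. Sparsity
# straddles the detection boundary by design.
random_gene_counts <- function(cat, n_samples = 3, p_pos = NULL) {
  n <- nrow(cat$genes)
  m <- matrix(0, n, n_samples,
              dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    p <- if (is.null(p_pos)) runif(1, 0.02, 0.5) else p_pos
    pos <- runif(n) < p
    m[pos, j] <- round(runif(sum(pos), 0.5, 20), 3)
  }
  m
}

# Wide abundance tibble -> matrix with MSP rownames.
msp_matrix <- function(tbl) {
  m <- as.matrix(tibble::as_tibble(tbl)[, -1])
  rownames(m) <- tbl[[1]]
  m
}

# Independent oracle for the quantification rule: explicit per-MSP loop.
oracle_quantify <- function(counts, cat, which_cat, fraction = 0.10) {
  rownames(counts) <- cat$genes$gene_id
  mk <- cat$genes[cat$genes$is_marker & cat$genes$catalogue == which_cat, ]
  msps <- unique(mk$msp_id)
  out <- matrix(0, length(msps), ncol(counts),
                dimnames = list(msps, colnames(counts)))
  for (m in msps) {
    gene_ids <- mk$gene_id[mk$msp_id == m]
    for (j in seq_len(ncol(counts))) {
      vals <- counts[gene_ids, j]
      d <- sum(vals > 0)
      if (d >= ceiling(fraction * length(vals))) {
        out[m, j] <- mean(vals)
      }
    }
  }
  out
}

# Independent oracle for the merge rule: drop the oral member of each pair,
# combine into the gut id elementwise.
oracle_merge <- function(gut_m, oral_m, overlaps, rule = "max") {
  keep_oral <- setdiff(rownames(oral_m), overlaps$oral_msp_id)
  out <- rbind(gut_m, oral_m[keep_oral, , drop = FALSE])
  if (nrow(overlaps) > 0) {
    for (i in seq_len(nrow(overlaps))) {
      g <- overlaps$gut_msp_id[i]
      o <- overlaps$oral_msp_id[i]
      out[g, ] <- switch(rule,
        max = pmax(gut_m[g, ], oral_m[o, ]),
        sum = gut_m[g, ] + oral_m[o, ],
        `keep-gut` = gut_m[g, ]
      )
    }
  }
  out
}

# A small normalized MSP table plus matching metadata for the niche tests.
# Columns: baseline stool, baseline raw saliva, then bioreactor samples
# given as a named list sample_id -> c(type, day).
niche_fixture <- function(abund, bioreactor, donor = "D1") {
  tbl <- msp_table(abund, normalized = TRUE)
  meta <- dplyr::bind_rows(
    tibble::tibble(sample_id = "stool", donor = donor, sample_type = "stool",
                   day = NA_integer_, is_baseline = TRUE),
    tibble::tibble(sample_id = "saliva", donor = donor,
                   sample_type = "raw_saliva", day = NA_integer_,
                   is_baseline = TRUE),
    dplyr::bind_rows(lapply(names(bioreactor), function(s) {
      tibble::tibble(sample_id = s, donor = donor,
                     sample_type = bioreactor[[s]][[1]],
                     day = as.integer(bioreactor[[s]][[2]]),
                     is_baseline = FALSE)
    }))
  )
  list(table = tbl, meta = meta)
}

# ---- cached study-condition runs for the end-to-end checks -----------------
# The default scenario at two mucosal-affinity settings, scored against the
# planted truth. Expensive, so computed once per test session.

.sim_cache <- new.env(parent = emptyenv())

score_run <- function(seed, affinity = 5) {
  cfg <- sim_config(seed = seed, oral_mucosal_affinity = affinity)
  exp <- simulate_experiment(cfg)
  q <- quantify_msp(exp$genes, exp$catalogue)
  merged <- merge_msp_tables(q$gut, q$oral, exp$catalogue$overlaps)
  norm <- normalize_msp(merged)
  niches <- assign_niches(norm, exp$meta)
  inv <- detect_oral_invaders(norm, niches, exp$meta)

  truth <- exp$truth
  sp2msp <- stats::setNames(truth$niche$msp_id, truth$niche$species_id)
  truth_lab <- stats::setNames(truth$niche$niche, truth$niche$msp_id)
  lab <- stats::setNames(niches$niche, niches$msp_id)

  detected <- unique(inv$invader_matrix$msp_id)
  planted_inv <- unname(sp2msp[truth$planted_invaders])
  recall_set <- unname(sp2msp[
    truth$planted_oral$species_id[truth$planted_oral$max_mucosal_rel >= 1e-3]
  ])

  # label accuracy over species planted at >= 1e-3 in every baseline they
  # occupy
  st <- truth$stool
  sal <- truth$saliva
  sp <- names(st)
  tl <- truth_lab[sp2msp[sp]]
  eligible <- sp[
    (tl == "gut" & st >= 1e-3) |
      (tl == "oral" & sal >= 1e-3) |
      (tl == "ND" & st >= 1e-3 & sal >= 1e-3)
  ]
  acc <- mean(lab[sp2msp[eligible]] == truth_lab[sp2msp[eligible]])

  post <- inv$invader_matrix[
    inv$invader_matrix$day >= 9 & inv$invader_matrix$abundance > 0, ]
  list(
    recall = if (length(recall_set) > 0) mean(recall_set %in% detected) else NA,
    n_false = sum(!detected %in% planted_inv),
    label_accuracy = acc,
    muc_count = length(unique(post$msp_id[post$sample_type == "mucosal"])),
    lum_count = length(unique(post$msp_id[post$sample_type == "luminal"]))
  )
}

scored_runs <- function(affinity = 5, n_seeds = 25) {
  key <- paste0("aff", affinity, "_n", n_seeds)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- dplyr::bind_rows(
      lapply(seq_len(n_seeds), function(s) {
        tibble::as_tibble(score_run(seed = s, affinity = affinity))
      })
    )
  }
  .sim_cache[[key]]
}
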