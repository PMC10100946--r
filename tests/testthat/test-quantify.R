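make_marker_counts <- function(cat, fill = 0) {
  matrix(fill, nrow(cat$genes), 2,
         dimnames = list(NULL, c("s1", "s2")))
}

test_that("marker-mean quantification honours the 10% detection rule", {
  cat <- tiny_catalogue(n_gut = 1, n_oral = 0, n_shared = 0,
                        markers = 100, extra = 0)

  # all markers at 5.0 -> abundance 5.0
  m <- make_marker_counts(cat, fill = 5)
  q <- quantify_msp(genes_from_counts(cat, m), cat)
  expect_equal(unname(msp_matrix(q$gut)["G01", ]), c(5, 5),
               ignore_attr = TRUE)

  # 9 of 100 markers positive -> below threshold -> 0
  m <- make_marker_counts(cat, 0)
  m[1:9, 1] <- 3
  q <- quantify_msp(genes_from_counts(cat, m), cat)
  expect_equal(msp_matrix(q$gut)["G01", "s1"], 0, ignore_attr = TRUE)

  # exactly 10 of 100 at 3.0 -> boundary inclusive -> mean = 0.30
  m <- make_marker_counts(cat, 0)
  m[1:10, 1] <- 3
  q <- quantify_msp(genes_from_counts(cat, m), cat)
  expect_equal(msp_matrix(q$gut)["G01", "s1"], 0.30, ignore_attr = TRUE)
})

test_that("non-marker genes never contribute and missing markers are fatal", {
  cat <- tiny_catalogue(n_gut = 1, n_oral = 0, n_shared = 0,
                        markers = 10, extra = 10)
  m <- make_marker_counts(cat, 0)
  m[cat$genes$is_marker, 1] <- 2      # markers at 2
  m[!cat$genes$is_marker, 1] <- 1000  # huge non-marker signal, ignored
  q <- quantify_msp(genes_from_counts(cat, m), cat)
  expect_equal(msp_matrix(q$gut)["G01", "s1"], 2, ignore_attr = TRUE)

  gt <- genes_from_counts(cat, m)
  crippled <- gene_table(tibble::as_tibble(gt)[-1, ]) # drop a marker row
  expect_error(quantify_msp(crippled, cat), cat$genes$gene_id[1],
               class = "oralgut_input_error")
})

test_that("quantification equals the brute-force per-MSP oracle", {
  set.seed(7)
  for (i in 1:10) {
    cat <- tiny_catalogue(n_gut = 3, n_oral = 2, n_shared = 1, markers = 10)
    counts <- random_gene_counts(cat, n_samples = 3)
    q <- quantify_msp(genes_from_counts(cat, counts), cat)
    for (w in c("gut", "oral")) {
      got <- as.matrix(q[[w]][, -1])
      rownames(got) <- q[[w]]$msp_id
      want <- oracle_quantify(counts, cat, w)
      expect_equal(got[rownames(want), ], want, ignore_attr = TRUE)
    }
  }
})

test_that("merge drops the oral member and keeps the elementwise maximum", {
  gut <- msp_table(tibble::tibble(msp_id = c("g1", "g2", "gs"),
                                  s1 = c(1, 0, 2), s2 = c(0, 1, 4)))
  oral <- msp_table(tibble::tibble(msp_id = c("o1", "o2", "os"),
                                   s1 = c(3, 0, 5), s2 = c(0, 2, 1)))
  ov <- tibble::tibble(gut_msp_id = "gs", oral_msp_id = "os")
  merged <- merge_msp_tables(gut, oral, ov)
  expect_equal(nrow(merged), 5) # 3 + 3 - 1
  m <- as.matrix(merged[, -1])
  rownames(m) <- merged$msp_id
  expect_false("os" %in% rownames(m))
  expect_equal(m["gs", ], c(s1 = 5, s2 = 4)) # max(2,5), max(4,1)
  origin <- attr(merged, "origin")
  expect_equal(origin$merged_from[origin$msp_id == "gs"], "os")

  # disjoint union when no overlaps
  merged0 <- merge_msp_tables(gut, oral, ov[0, ])
  expect_equal(nrow(merged0), 6)

  expect_error(merge_msp_tables(gut, oral,
                                tibble::tibble(gut_msp_id = "nope",
                                               oral_msp_id = "os")),
               class = "oralgut_input_error")
  oral_bad <- msp_table(tibble::tibble(msp_id = "o1", other = 1))
  expect_error(merge_msp_tables(gut, oral_bad, ov[0, ]),
               class = "oralgut_input_error")
})

test_that("merge agrees with the drop-then-max oracle on random instances", {
  set.seed(11)
  for (i in 1:20) {
    n_g <- sample(2:6, 1)
    n_o <- sample(2:6, 1)
    n_ov <- sample(0:min(n_g, n_o), 1)
    gm <- matrix(round(runif(n_g * 3, 0, 10), 3), n_g,
                 dimnames = list(paste0("g", 1:n_g), paste0("s", 1:3)))
    om <- matrix(round(runif(n_o * 3, 0, 10), 3), n_o,
                 dimnames = list(paste0("o", 1:n_o), paste0("s", 1:3)))
    ov <- tibble::tibble(
      gut_msp_id = sample(rownames(gm), n_ov),
      oral_msp_id = sample(rownames(om), n_ov)
    )
    rule <- sample(c("max", "keep-gut", "sum"), 1)
    merged <- merge_msp_tables(
      msp_table(tibble::tibble(msp_id = rownames(gm), tibble::as_tibble(gm))),
      msp_table(tibble::tibble(msp_id = rownames(om), tibble::as_tibble(om))),
      ov, rule = rule
    )
    want <- oracle_merge(gm, om, ov, rule = rule)
    got <- as.matrix(merged[, -1])
    rownames(got) <- merged$msp_id
    expect_equal(nrow(got), n_g + n_o - n_ov)
    expect_equal(got[rownames(want), ], want)
  }
})

test_that("per-sample normalization divides by the detected-species sum", {
  t <- msp_table(tibble::tibble(msp_id = c("a", "b", "c"),
                                s1 = c(2, 3, 5), s2 = c(7, 0, 0)))
  n <- normalize_msp(t)
  expect_true(is_normalized(n))
  expect_equal(n$s1, c(0.2, 0.3, 0.5))
  expect_equal(n$s2, c(1, 0, 0))
  expect_error(normalize_msp(n), "already", class = "oralgut_input_error")

  t0 <- msp_table(tibble::tibble(msp_id = c("a", "b"),
                                 good = c(1, 1), dead = c(0, 0)))
  expect_error(normalize_msp(t0), "dead", class = "oralgut_input_error")

  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rexp(20), 5, 4, dimnames = list(paste0("m", 1:5),
                                                paste0("s", 1:4)))
    n <- normalize_msp(msp_table(tibble::tibble(msp_id = rownames(m),
                                                tibble::as_tibble(m))))
    expect_true(all(abs(colSums(as.matrix(n[, -1])) - 1) < 1e-12))
  }
})

test_that("richness counts strictly positive MSPs per sample", {
  t <- msp_table(tibble::tibble(msp_id = c("a", "b", "c"),
                                s1 = c(0, 0.1, 0.3), s2 = c(0, 0, 0)))
  r <- msp_richness(t)
  expect_equal(r$richness, c(2L, 0L))
  set.seed(5)
  m <- matrix(rbinom(40, 1, 0.4) * runif(40), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("s", 1:5)))
  r <- msp_richness(msp_table(tibble::tibble(msp_id = rownames(m),
                                             tibble::as_tibble(m))))
  expect_equal(r$richness, unname(apply(m, 2, function(v) sum(v > 0))))
})

test_that("downsampling preserves totals exactly and is unbiased", {
  gt <- gene_table(tibble::tibble(gene_id = c("g1", "g2"),
                                  sA = c(50, 50), sB = c(10, 0)),
                   unassigned = c(sA = 0, sB = 0))
  # depth equal to a sample's total: column untouched
  out <- downsample_genes(gt, 10, seed = 1)
  expect_equal(out$sB, c(10, 0))
  expect_equal(sum(out$sA), 10)

  expect_error(downsample_genes(gt, 60, seed = 1), "sB",
               class = "oralgut_input_error")
  frac <- gene_table(tibble::tibble(gene_id = "g", s = 1.5))
  expect_error(downsample_genes(frac, 1, 1), "integer",
               class = "oralgut_input_error")

  # gene holding half the reads keeps half in expectation (hypergeometric)
  gt_a <- gene_table(tibble::tibble(gene_id = c("g1", "g2"),
                                    sA = c(50, 50)))
  draws <- vapply(1:1000, function(s) {
    downsample_genes(gt_a, 50, seed = s)$sA[1]
  }, numeric(1))
  se <- sqrt(50 * 0.5 * 0.5 * (100 - 50) / (100 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 25), 3 * se)

  # unassigned pool participates in the draw
  gt2 <- gene_table(tibble::tibble(gene_id = "g1", sA = 40),
                    unassigned = c(sA = 60))
  out <- downsample_genes(gt2, 30, seed = 2)
  expect_equal(out$sA + unname(unassigned_counts(out)), 30)
})

test_that("mapping rates partition every sample's reads", {
  cat <- tiny_catalogue(n_gut = 1, n_oral = 1, n_shared = 0, markers = 10)
  counts <- matrix(0, nrow(cat$genes), 2,
                   dimnames = list(NULL, c("all_gut", "mix")))
  counts[cat$genes$catalogue == "gut", "all_gut"] <- 5 # 50 reads on gut
  counts[cat$genes$catalogue == "gut", "mix"] <- 5     # 50 gut
  counts[cat$genes$catalogue == "oral", "mix"] <- 3    # 30 oral
  gt <- genes_from_counts(cat, counts, unassigned = c(all_gut = 0, mix = 20))
  mr <- mapping_rate(gt, cat)
  expect_equal(mr$gut, c(1, 0.5))
  expect_equal(mr$oral, c(0, 0.3))
  expect_equal(mr$unassigned, c(0, 0.2))
  expect_true(all(abs(mr$gut + mr$oral + mr$unassigned - 1) < 1e-12))

  no_ua <- genes_from_counts(cat, counts)
  expect_error(mapping_rate(no_ua, cat), class = "oralgut_input_error")
})

test_that("quantification is equivariant under per-sample scaling", {
  set.seed(13)
  cat <- tiny_catalogue(n_gut = 3, n_oral = 2, n_shared = 1, markers = 10)
  counts <- random_gene_counts(cat, n_samples = 2, p_pos = 0.3)
  c_scale <- 7.5
  scaled <- counts
  scaled[, 1] <- scaled[, 1] * c_scale

  q1 <- quantify_msp(genes_from_counts(cat, counts), cat)
  q2 <- quantify_msp(genes_from_counts(cat, scaled), cat)
  for (w in c("gut", "oral")) {
    a1 <- as.matrix(q1[[w]][, -1])
    a2 <- as.matrix(q2[[w]][, -1])
    expect_equal(a2[, 1], a1[, 1] * c_scale, tolerance = 1e-12)
    expect_equal(a2[, 2], a1[, 2])
    expect_equal(a2 > 0, a1 > 0) # detection pattern unchanged
  }
  m1 <- merge_msp_tables(q1$gut, q1$oral, cat$overlaps)
  m2 <- merge_msp_tables(q2$gut, q2$oral, cat$overlaps)
  expect_equal(msp_richness(m1), msp_richness(m2))
  if (all(colSums(as.matrix(m1[, -1])) > 0)) {
    expect_equal(tibble::as_tibble(normalize_msp(m1))[-1],
                 tibble::as_tibble(normalize_msp(m2))[-1],
                 tolerance = 1e-12)
  }
})

test_that("abundance is positive exactly when the detection rule passed", {
  set.seed(17)
  cat <- tiny_catalogue(n_gut = 4, n_oral = 3, n_shared = 0, markers = 10)
  counts <- random_gene_counts(cat, n_samples = 4)
  q <- quantify_msp(genes_from_counts(cat, counts), cat)
  rownames(counts) <- cat$genes$gene_id
  for (w in c("gut", "oral")) {
    ab <- as.matrix(q[[w]][, -1])
    rownames(ab) <- q[[w]]$msp_id
    mk <- cat$genes[cat$genes$is_marker & cat$genes$catalogue == w, ]
    for (m in unique(mk$msp_id)) {
      d <- colSums(counts[mk$gene_id[mk$msp_id == m], , drop = FALSE] > 0)
      expect_equal(unname(ab[m, ] > 0), unname(d >= 1)) # ceil(0.1*10) = 1
    }
  }
})
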