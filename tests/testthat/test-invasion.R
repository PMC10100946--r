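test_that("niche assignment follows the strict-occurrence rule", {
  fx <- niche_fixture(
    tibble::tibble(
      msp_id = c("m_gut", "m_oral", "m_both", "m_neither"),
      stool = c(0.2, 0, 0.8, 0),
      saliva = c(0, 0.9, 0.1, 0),
      lum_d9 = c(0.5, 0.25, 0.25, 0)
    ),
    bioreactor = list(lum_d9 = list("luminal", 9))
  )
  ni <- assign_niches(fx$table, fx$meta)
  lab <- setNames(ni$niche, ni$msp_id)
  expect_equal(lab[["m_gut"]], "gut")     # stool only
  expect_equal(lab[["m_oral"]], "oral")   # saliva only
  expect_equal(lab[["m_both"]], "ND")     # detected in both
  expect_equal(lab[["m_neither"]], "ND")  # detected in neither
  expect_equal(nrow(ni), 4) # total map

  # missing baseline is an input error
  broken_meta <- fx$meta[fx$meta$sample_type != "raw_saliva", ]
  expect_error(assign_niches(fx$table, broken_meta),
               class = "oralgut_input_error")
})

test_that("a detection floor can tighten baseline occurrence", {
  fx <- niche_fixture(
    tibble::tibble(msp_id = c("m1", "m2"),
                   stool = c(0.99, 0.01), saliva = c(0.5, 0.5),
                   lum_d1 = c(1, 0)),
    bioreactor = list(lum_d1 = list("luminal", 1))
  )
  expect_equal(assign_niches(fx$table, fx$meta)$niche, c("ND", "ND"))
  # with a floor above m2's stool signal it becomes saliva-only
  ni <- assign_niches(fx$table, fx$meta, floor = 0.05)
  expect_equal(setNames(ni$niche, ni$msp_id)[["m2"]], "oral")
})

test_that("niche series counts and shares add up by construction", {
  fx <- niche_fixture(
    tibble::tibble(
      msp_id = c("g1", "g2", "g3", "o1", "n1", "n2"),
      stool = c(0.2, 0.2, 0.2, 0, 0.2, 0.2),
      saliva = c(0, 0, 0, 0.6, 0.2, 0.2),
      lum_d5 = c(0.25, 0.20, 0.05, 0.25, 0.15, 0.10)
    ),
    bioreactor = list(lum_d5 = list("luminal", 5))
  )
  ni <- assign_niches(fx$table, fx$meta)
  ser <- niche_series(fx$table, ni, fx$meta)
  lum <- ser[ser$sample_id == "lum_d5", ]
  expect_equal(setNames(lum$richness, lum$niche),
               c(gut = 3L, oral = 1L, ND = 2L))
  expect_equal(sum(lum$richness), 6)
  expect_equal(sum(lum$rel_abundance), 1)
  expect_equal(lum$rel_abundance[lum$niche == "oral"], 0.25)

  # brute-force per-MSP scan over every sample and niche
  lab <- setNames(ni$niche, ni$msp_id)
  mat <- as.matrix(tibble::as_tibble(fx$table)[, -1])
  rownames(mat) <- fx$table$msp_id
  for (s in colnames(mat)) {
    here <- ser[ser$sample_id == s, ]
    for (nk in c("gut", "oral", "ND")) {
      members <- names(lab)[lab == nk]
      expect_identical(here$richness[here$niche == nk],
                       sum(mat[members, s] > 0))
      expect_equal(here$rel_abundance[here$niche == nk],
                   sum(mat[members, s]) / sum(mat[, s]))
    }
  }

  incomplete <- ni[ni$msp_id != "g1", ]
  expect_error(niche_series(fx$table, incomplete, fx$meta), "g1",
               class = "oralgut_input_error")
})

test_that("baseline samples contain no cross-niche richness", {
  # forced by the assignment rule: anything detected in stool cannot be
  # oral, anything detected in saliva cannot be gut
  set.seed(29)
  for (i in 1:10) {
    n <- 12
    stool <- rbinom(n, 1, 0.5) * runif(n)
    saliva <- rbinom(n, 1, 0.5) * runif(n)
    if (sum(stool) == 0 || sum(saliva) == 0) next
    fx <- niche_fixture(
      tibble::tibble(msp_id = paste0("m", 1:n),
                     stool = stool / sum(stool),
                     saliva = saliva / sum(saliva),
                     lum_d1 = rep(1 / n, n)),
      bioreactor = list(lum_d1 = list("luminal", 1))
    )
    ni <- assign_niches(fx$table, fx$meta)
    ser <- niche_series(fx$table, ni, fx$meta)
    expect_equal(ser$richness[ser$sample_id == "stool" & ser$niche == "oral"], 0L)
    expect_equal(ser$richness[ser$sample_id == "saliva" & ser$niche == "gut"], 0L)
  }
})

test_that("oral invaders are tracked per compartment with phase flags", {
  fx <- niche_fixture(
    tibble::tibble(
      msp_id = c("g1", "o_inv", "o_quiet", "o_pre"),
      stool = c(1, 0, 0, 0),
      saliva = c(0, 0.4, 0.3, 0.3),
      lum_d5 = c(0.9, 0, 0, 0.1),
      lum_d9 = c(1, 0, 0, 0),
      muc_d10 = c(0.6, 0.4, 0, 0)
    ),
    bioreactor = list(lum_d5 = list("luminal", 5),
                      lum_d9 = list("luminal", 9),
                      muc_d10 = list("mucosal", 10))
  )
  ni <- assign_niches(fx$table, fx$meta)
  inv <- detect_oral_invaders(fx$table, ni, fx$meta, first_injection_day = 9)

  got <- unique(inv$invader_matrix$msp_id)
  expect_setequal(got, c("o_inv", "o_pre")) # o_quiet never in bioreactor
  expect_false("g1" %in% got)               # gut species are not invaders

  pre <- unique(inv$invader_matrix$pre_existing[
    inv$invader_matrix$msp_id == "o_pre"])
  expect_true(pre)
  expect_false(unique(inv$invader_matrix$pre_existing[
    inv$invader_matrix$msp_id == "o_inv"]))

  sm <- inv$invader_summary
  expect_equal(sm$n_oral_detected[sm$sample_type == "mucosal" & sm$day == 10], 1L)
  expect_equal(sm$n_oral_detected[sm$sample_type == "luminal" & sm$day == 9], 0L)
  expect_equal(sm$phase[sm$day == 5], "pre")
  expect_equal(sm$phase[sm$day == 10], "post")

  raw <- msp_table(tibble::as_tibble(fx$table), normalized = FALSE)
  expect_error(detect_oral_invaders(raw, ni, fx$meta),
               class = "oralgut_input_error")
  no_bior <- fx$meta[fx$meta$is_baseline, ]
  expect_error(detect_oral_invaders(fx$table, ni, no_bior),
               class = "oralgut_input_error")
})

test_that("Bray-Curtis matches the hand formula and is a dissimilarity", {
  t <- msp_table(tibble::tibble(
    msp_id = c("a", "b", "c"),
    x = c(0.5, 0.5, 0),
    y = c(0, 0.5, 0.5),
    z = c(0.5, 0.5, 0),
    w = c(0, 0, 1)
  ), normalized = TRUE)
  bc <- bray_curtis_matrix(t)
  m <- as.matrix(bc[, -1])
  rownames(m) <- bc$sample_id
  expect_equal(m["x", "y"], 0.5) # 1 - 2*0.5/2
  expect_equal(m["x", "z"], 0)   # identical columns
  expect_equal(m["x", "w"], 1)   # disjoint support
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0 & m <= 1))

  raw <- msp_table(tibble::as_tibble(t), normalized = FALSE)
  expect_error(bray_curtis_matrix(raw), class = "oralgut_input_error")

  # random normalized tables stay valid dissimilarities
  set.seed(31)
  for (i in 1:10) {
    r <- matrix(rexp(24), 6, 4, dimnames = list(paste0("m", 1:6),
                                                paste0("s", 1:4)))
    r <- sweep(r, 2, colSums(r), "/")
    bc <- bray_curtis_matrix(msp_table(
      tibble::tibble(msp_id = rownames(r), tibble::as_tibble(r)),
      normalized = TRUE
    ))
    mm <- as.matrix(bc[, -1])
    expect_equal(mm, t(mm), ignore_attr = TRUE)
    expect_true(all(diag(mm) == 0))
    expect_true(all(mm >= 0 & mm <= 1 + 1e-12))
  }
})

test_that("rank aggregation pools unclassified MSPs and conserves mass", {
  t <- msp_table(tibble::tibble(
    msp_id = c("m1", "m2", "m3", "m4"),
    s1 = c(0.3, 0.2, 0.4, 0.1),
    s2 = c(0.25, 0.25, 0.25, 0.25)
  ), normalized = TRUE)
  tax <- tibble::tibble(
    msp_id = c("m1", "m2", "m3"),
    species = letters[1:3], genus = "G", family = "F",
    phylum = c("P1", "P1", "")
  )
  expect_warning(agg <- aggregate_by_rank(t, tax, "phylum"), "unclassified")
  m <- as.matrix(agg[, -1])
  rownames(m) <- agg$phylum
  expect_equal(m["P1", "s1"], 0.5) # 0.3 + 0.2
  expect_equal(m["unclassified", "s1"], 0.5) # empty rank + missing MSP
  expect_equal(colSums(m), c(s1 = 1, s2 = 1), tolerance = 1e-12)

  # conservation on random tables with full taxonomy (no warning)
  set.seed(37)
  for (i in 1:5) {
    r <- matrix(rexp(30), 6, 5, dimnames = list(paste0("m", 1:6),
                                                paste0("s", 1:5)))
    r <- sweep(r, 2, colSums(r), "/")
    tt <- msp_table(tibble::tibble(msp_id = rownames(r),
                                   tibble::as_tibble(r)), normalized = TRUE)
    tax <- tibble::tibble(msp_id = rownames(r), species = rownames(r),
                          genus = "g", family = "f",
                          phylum = sample(c("A", "B", "C"), 6, replace = TRUE))
    agg <- aggregate_by_rank(tt, tax, "phylum")
    expect_equal(unname(colSums(as.matrix(agg[, -1]))), rep(1, 5),
                 tolerance = 1e-12)
  }
})

test_that("invader correlation reproduces the rank-formula oracle", {
  t <- msp_table(tibble::tibble(
    msp_id = paste0("m", 1:5),
    src = c(1, 2, 3, 4, 5),
    tgt = c(2, 1, 4, 3, 5),
    rev = c(5, 4, 3, 2, 1)
  ))
  res <- invader_correlation(t, "src", "tgt", paste0("m", 1:5))
  # oracle: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)), d^2 = (1,1,1,1,0)
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24)) # 0.7 exactly
  expect_equal(res$n, 5)
  expect_true(res$p_value > 0 && res$p_value < 1)

  expect_equal(invader_correlation(t, "src", "src", paste0("m", 1:5))$rho, 1)
  expect_equal(invader_correlation(t, "src", "rev", paste0("m", 1:5))$rho, -1)

  expect_error(invader_correlation(t, "src", "tgt", c("m1", "m2")),
               class = "oralgut_input_error")
  expect_error(invader_correlation(t, "src", "nope", paste0("m", 1:5)),
               class = "oralgut_input_error")
})
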