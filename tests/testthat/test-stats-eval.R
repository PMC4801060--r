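# Differential selection, overlap filtering, reproducibility statistics,
# dominance, and enrichment tests.

# a dpsi_fit-shaped tibble built directly from mass vectors
fake_dpsi <- function(ids, masses, V = 40) {
  dv <- lsvtools:::.dpsi_values(V)
  out <- tibble::tibble(
    lsv_id = ids,
    junction_id = paste0(ids, ":j1"),
    junction_idx = 1L,
    dpsi = vapply(masses, function(m) sum(m * dv), numeric(1)),
    p_change = vapply(masses, prob_changing, numeric(1)),
    mass = masses
  )
  attr(out, "V") <- V
  class(out) <- c("dpsi_fit", class(out))
  out
}

point_mass <- function(d, V = 40) {
  m <- numeric(2 * V - 1)
  m[which.min(abs(lsvtools:::.dpsi_values(V) - d))] <- 1
  m
}

test_that("selection follows the confident-change rule", {
  V <- 40
  uniform <- rep(1 / (2 * V - 1), 2 * V - 1)
  fit <- fake_dpsi(c("l1", "l2"), list(point_mass(0.5), uniform))
  calls <- select_differential(fit)
  expect_true(calls$selected[calls$lsv_id == "l1"])
  expect_false(calls$selected[calls$lsv_id == "l2"])
  # discretized uniform: P(|dPSI| > 0.2) = 62/79, near the continuous 0.8
  expect_equal(calls$p_change[calls$lsv_id == "l2"], 62 / 79)
  expect_equal(attr(calls, "N"), 1L)
  # empty input
  empty <- select_differential(fit[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "N"), 0L)
})

test_that("relaxing the dPSI threshold never shrinks the selected set", {
  withr::local_seed(51)
  masses <- lapply(1:30, function(i) {
    m <- runif(79); m / sum(m)
  })
  fit <- fake_dpsi(sprintf("l%02d", 1:30), masses)
  sel <- function(th) {
    c <- select_differential(fit, dpsi_thresh = th, confidence = 0.5)
    c$lsv_id[c$selected]
  }
  expect_true(all(sel(0.2) %in% sel(0.15)))
  expect_true(all(sel(0.15) %in% sel(0.1)))
})

test_that("ranking is by |E[dPSI]| with lexicographic tie-break", {
  fit <- fake_dpsi(c("b", "a", "c"),
                   list(point_mass(0.5), point_mass(-0.5), point_mass(0.3)))
  calls <- select_differential(fit)
  expect_equal(calls$lsv_id, c("a", "b", "c"))
})

# ---- overlap filter ---------------------------------------------------

ranked_with_footprints <- function(ids, dpsis, footprints, chrom = "chr1") {
  out <- tibble::tibble(
    lsv_id = ids, e_dpsi = abs(dpsis), p_change = 1, selected = TRUE,
    chrom = chrom, complex = FALSE,
    footprint = footprints
  ) %>% dplyr::arrange(dplyr::desc(e_dpsi), lsv_id)
  attr(out, "N") <- nrow(out)
  class(out) <- c("ranked_calls", class(out))
  out
}

test_that("of a cassette exon's two LSVs only the higher ranked survives", {
  fp1 <- tibble::tibble(start = c(100, 500, 900), end = c(200, 600, 1000))
  fp2 <- tibble::tibble(start = c(500, 900), end = c(600, 1000))
  ranked <- ranked_with_footprints(c("ss", "st"), c(0.5, 0.4),
                                   list(fp1, fp2))
  out <- overlap_filter(ranked)
  expect_equal(out$lsv_id, "ss")
})

test_that("LSVs in different genes both survive the overlap filter", {
  fp1 <- tibble::tibble(start = 100, end = 200)
  fp2 <- tibble::tibble(start = 5000, end = 5100)
  ranked <- ranked_with_footprints(c("g1", "g2"), c(0.5, 0.4),
                                   list(fp1, fp2))
  expect_equal(nrow(overlap_filter(ranked)), 2)
})

test_that("of three mutually overlapping LSVs exactly rank 1 survives", {
  fps <- list(tibble::tibble(start = 100, end = 300),
              tibble::tibble(start = 200, end = 400),
              tibble::tibble(start = 250, end = 350))
  ranked <- ranked_with_footprints(c("x", "y", "z"), c(0.6, 0.5, 0.4), fps)
  out <- overlap_filter(ranked)
  expect_equal(out$lsv_id, "x")
  # retained footprints are pairwise disjoint by construction: re-check
  # with a case where two of three overlap
  fps2 <- list(tibble::tibble(start = 100, end = 300),
               tibble::tibble(start = 200, end = 400),
               tibble::tibble(start = 1000, end = 1100))
  out2 <- overlap_filter(ranked_with_footprints(c("x", "y", "z"),
                                                c(0.6, 0.5, 0.4), fps2))
  expect_setequal(out2$lsv_id, c("x", "z"))
})

# ---- reproducibility ratio -------------------------------------------

rank_list <- function(ids, n_selected = length(ids)) {
  out <- tibble::tibble(lsv_id = ids)
  attr(out, "N") <- n_selected
  class(out) <- c("ranked_calls", class(out))
  out
}

test_that("identical ranked lists give RR(n) = 1 everywhere", {
  a <- rank_list(letters[1:6])
  rr <- reproducibility_ratio(a, a)
  expect_equal(rr$rr, rep(1, 6))
})

test_that("the quoted worked example gives RR(4) = 0.5", {
  a <- rank_list(c("a", "b", "c", "d"))
  b <- rank_list(c("a", "c", "e", "f"))
  rr <- reproducibility_ratio(a, b)
  expect_equal(rr$rr[4], 0.5)
  expect_equal(rr$rr, c(1, 1 / 2, 2 / 3, 1 / 2))
})

test_that("RR matches brute-force intersection on random lists and is
           invariant to permuting the comparison top-N", {
  withr::local_seed(61)
  for (rep_i in 1:10) {
    ids <- sprintf("l%03d", 1:60)
    a <- rank_list(sample(ids), n_selected = 25)
    b <- rank_list(sample(ids))
    rr <- reproducibility_ratio(a, b)
    N <- 25
    brute <- vapply(seq_len(N), function(n) {
      length(intersect(a$lsv_id[1:n], b$lsv_id[1:N])) / n
    }, numeric(1))
    expect_equal(rr$rr, brute)
    # permute B's top-N internally: curve unchanged
    b_perm <- rank_list(c(sample(b$lsv_id[1:N]), b$lsv_id[-(1:N)]))
    expect_equal(reproducibility_ratio(a, b_perm)$rr, rr$rr)
  }
})

test_that("an empty selected set warns and returns an empty curve", {
  a <- rank_list(character(0), n_selected = 0)
  expect_warning(rr <- reproducibility_ratio(a, a), "empty")
  expect_equal(nrow(rr), 0)
})

# ---- PSI reproducibility, dominance, max inclusion -------------------

fake_psi <- function(ids, junctions, psis) {
  out <- tibble::tibble(
    lsv_id = ids, junction_id = junctions,
    junction_idx = as.integer(ave(seq_along(ids), ids, FUN = seq_along)),
    psi = psis, mass = replicate(length(ids), rep(1 / 40, 40),
                                 simplify = FALSE),
    low_confidence = FALSE
  )
  attr(out, "V") <- 40
  class(out) <- c("psi_fit", class(out))
  out
}

test_that("PSI reproducibility is the absolute difference of means", {
  a <- fake_psi(c("l1", "l1", "l2"), c("j1", "j2", "j3"), c(0.6, 0.4, 0.3))
  b <- fake_psi(c("l1", "l1", "l3"), c("j1", "j2", "j9"), c(0.7, 0.3, 0.9))
  rep_tbl <- psi_reproducibility(a, b)
  expect_equal(nrow(rep_tbl), 2)        # l2/l3 junctions discarded
  expect_equal(rep_tbl$r, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(attr(rep_tbl, "frac_within"), 0)
  identical_runs <- psi_reproducibility(a, a)
  expect_true(all(identical_runs$r == 0))
  expect_equal(attr(identical_runs, "frac_within"), 1)
})

test_that("dominance needs a strict E[psi] > 0.6", {
  fit <- fake_psi(
    c("l1", "l1", "l2", "l2", "l2", "l3", "l3"),
    paste0("j", 1:7),
    c(0.7, 0.3, 0.5, 0.3, 0.2, 0.6, 0.4)
  )
  dom <- dominance(fit)
  expect_equal(dom$dominant_idx[dom$lsv_id == "l1"], 1L)
  expect_true(is.na(dom$dominant_idx[dom$lsv_id == "l2"]))
  expect_true(is.na(dom$dominant_idx[dom$lsv_id == "l3"]))  # exactly 0.6
})

test_that("max inclusion ranks junctions by their best condition", {
  c1 <- fake_psi(c("b1", "b1", "c1", "c1", "c1"), paste0("j", 1:5),
                 c(0.9, 0.1, 0.6, 0.3, 0.1))
  c2 <- fake_psi(c("b1", "b1", "c1", "c1", "c1"), paste0("j", 1:5),
                 c(0.85, 0.15, 0.5, 0.25, 0.08))
  stats <- max_inclusion_stats(list(a = c1, b = c2))
  b1 <- stats[stats$lsv_id == "b1", ]
  expect_equal(b1$value[b1$least_used], 0.15)
  cx <- stats[stats$lsv_id == "c1", ]
  expect_true(all(cx$complex))
  expect_equal(cx$value[cx$rank == 2], 0.3)
  expect_equal(cx$value[cx$rank == 3], 0.1)
  # a fit seen in one condition only uses that condition's values
  solo <- max_inclusion_stats(c1[c1$lsv_id == "b1", ])
  expect_equal(solo$value, c(0.9, 0.1))
})

# ---- enrichment -------------------------------------------------------

test_that("complex enrichment matches the exact binomial tail", {
  res <- complex_enrichment(rep(c(TRUE, FALSE), c(10, 10)),
                            rep(c(TRUE, FALSE), c(30, 70)),
                            n_datasets = 3)
  expect_equal(res$fold, (10 / 20) / 0.3, tolerance = 1e-12)
  oracle <- sum(vapply(10:20, function(k) {
    choose(20, k) * 0.3^k * 0.7^(20 - k)
  }, numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, min(1, oracle * 3))
})

test_that("enrichment edge cases behave", {
  eq <- complex_enrichment(rep(c(TRUE, FALSE), c(3, 7)),
                           rep(c(TRUE, FALSE), c(30, 70)))
  expect_equal(eq$fold, 1)
  na <- complex_enrichment(logical(0), rep(TRUE, 5))
  expect_true(is.na(na$fold))
  expect_error(
    complex_enrichment(c(TRUE, FALSE), rep(FALSE, 10)), "invalid null")
})

# ---- permutation-corrected Fisher tests ------------------------------

make_feature_table <- function(n_lsvs, sizes, seed, effect = NULL) {
  withr::local_seed(seed)
  rows <- list()
  for (i in seq_len(n_lsvs)) {
    sz <- sample(sizes, 1)
    lab <- runif(1) < 0.4
    for (j in seq_len(sz)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lsv_id = sprintf("l%03d", i),
        junction_id = sprintf("l%03d:j%d", i, j),
        label = lab,
        f1 = runif(1) < 0.3,
        f2 = runif(1) < 0.5
      )
    }
  }
  tbl <- dplyr::bind_rows(rows)
  if (!is.null(effect)) tbl[[effect]] <- tbl$label  # perfect alignment
  tbl
}

test_that("label permutation preserves the per-size label multiset", {
  tbl <- make_feature_table(30, c(2, 3), seed = 71)
  res <- permutation_fet(tbl, n_perm = 50, seed = 1)
  expect_setequal(res$feature, c("f1", "f2"))
  # group sizes identical in every permutation is implied by corrected
  # p-values being computable; check the observed side explicitly:
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
})

test_that("independent labels give no small corrected p-values", {
  tbl <- make_feature_table(40, c(2, 3), seed = 72)
  res <- permutation_fet(tbl, n_perm = 100, seed = 2)
  expect_true(all(res$p_corrected > 0.05))
})

test_that("a feature perfectly aligned with the label is detected", {
  tbl <- make_feature_table(40, c(2, 3), seed = 73, effect = "f1")
  res <- permutation_fet(tbl, n_perm = 100, seed = 3)
  expect_lte(res$p_corrected[res$feature == "f1"], 2 / 100 + 0.05)
  expect_lt(res$p_raw[res$feature == "f1"], 1e-10)
})

test_that("features present in fewer than two junctions are excluded", {
  tbl <- make_feature_table(20, 2, seed = 74)
  tbl$rare <- FALSE; tbl$rare[1] <- TRUE
  expect_message(res <- permutation_fet(tbl, n_perm = 20, seed = 4),
                 "rare")
  expect_false("rare" %in% res$feature)
})
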