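# Differential-call selection, reproducibility statistics, dominance and
# enrichment tests.

#' Select and rank differential LSVs
#'
#' An LSV is called differential when `P(|dPSI| > dpsi_thresh) >
#' confidence` for at least one of its junctions (defaults 0.2 and 0.95,
#' the conservative rule; relaxed thresholds are just different
#' arguments). All quantifiable LSVs are ranked by decreasing maximal
#' `|E[dPSI]|`, ties broken lexicographically by `lsv_id`.
#'
#' @param dpsi A `dpsi_fit` tibble.
#' @param lsvs Optional `lsv_catalog` supplying exon footprints (needed by
#'   [overlap_filter()]) and the `complex` flag.
#' @param dpsi_thresh `|dPSI|` threshold (default 0.2).
#' @param confidence Posterior probability cutoff (default 0.95).
#' @return A `ranked_calls` tibble ordered by rank with columns `lsv_id`,
#'   `e_dpsi`, `p_change`, `selected`; attribute `N` is the selected-set
#'   size.
#' @export
select_differential <- function(dpsi, lsvs = NULL, dpsi_thresh = 0.2,
                                confidence = 0.95) {
  if (nrow(dpsi) == 0) {
    out <- tibble(lsv_id = character(), e_dpsi = double(),
                  p_change = double(), selected = logical())
    attr(out, "N") <- 0L
    class(out) <- unique(c("ranked_calls", class(out)))
    return(out)
  }
  per_lsv <- as_tibble(dpsi) %>%
    mutate(p_thr = vapply(.data$mass, prob_changing, numeric(1),
                          c = dpsi_thresh)) %>%
    group_by(.data$lsv_id) %>%
    summarise(e_dpsi = max(abs(.data$dpsi)),
              p_change = max(.data$p_thr), .groups = "drop") %>%
    mutate(selected = .data$p_change > confidence) %>%
    arrange(desc(.data$e_dpsi), .data$lsv_id)
  if (!is.null(lsvs)) {
    per_lsv <- per_lsv %>%
      left_join(lsvs %>% select("lsv_id", "chrom", "complex", "footprint"),
                by = "lsv_id")
  }
  attr(per_lsv, "N") <- sum(per_lsv$selected)
  class(per_lsv) <- unique(c("ranked_calls", class(per_lsv)))
  per_lsv
}

#' Filter ranked LSVs for exon overlap
#'
#' Greedy scan in rank order: an LSV is dropped iff any of its footprint
#' exons overlaps an exon of a higher-ranked retained LSV on the same
#' chromosome. This removes the double counting of, e.g., the two LSVs of
#' a differentially included cassette exon.
#'
#' @param ranked A `ranked_calls` tibble carrying `chrom` and `footprint`
#'   (from `select_differential(..., lsvs = catalog)`).
#' @return The filtered `ranked_calls`; retained footprints are pairwise
#'   disjoint.
#' @export
overlap_filter <- function(ranked) {
  if (nrow(ranked) == 0) return(ranked)
  if (!"footprint" %in% names(ranked)) {
    abort("ranked calls lack footprints; pass the catalog to select_differential()")
  }
  kept <- list()
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    fp <- ranked$footprint[[i]]
    chrom <- ranked$chrom[i]
    clash <- FALSE
    for (k in kept) {
      if (k$chrom != chrom) next
      ov <- any(outer(fp$start, k$fp$end, "<") &
                  outer(fp$end, k$fp$start, ">"))
      if (ov) { clash <- TRUE; break }
    }
    if (!clash) {
      keep[i] <- TRUE
      kept[[length(kept) + 1L]] <- list(chrom = chrom, fp = fp)
    }
  }
  out <- ranked[keep, ]
  attr(out, "N") <- sum(out$selected)
  class(out) <- unique(c("ranked_calls", class(out)))
  out
}

#' Reproducibility-ratio curve between two ranked runs
#'
#' `RR(n) = n*/n`, where `n*` counts how many of run A's first `n` ranked
#' LSVs appear among run B's best `N`; `N` is run A's selected-set size.
#' The statistic depends on run B only through its top-`N` *set*, so it is
#' invariant to permutations of B's top-ranked order.
#'
#' @param calls_a,calls_b `ranked_calls` tibbles (or any tibbles with an
#'   `lsv_id` column in rank order; `N` then defaults to
#'   `nrow(calls_a)`).
#' @param N Selected-set size; defaults to `attr(calls_a, "N")`.
#' @return An `rr_curve` tibble with columns `n`, `rr` for `n = 1..N`.
#' @export
reproducibility_ratio <- function(calls_a, calls_b, N = NULL) {
  if (is.null(N)) N <- attr(calls_a, "N") %||% nrow(calls_a)
  if (N == 0) {
    warn("empty selected set; RR curve is empty")
    out <- tibble(n = integer(), rr = double())
  } else {
    top_b <- head(calls_b$lsv_id, N)
    hits <- cumsum(head(calls_a$lsv_id, N) %in% top_b)
    out <- tibble(n = seq_len(N), rr = hits / seq_len(N))
  }
  attr(out, "N") <- N
  class(out) <- unique(c("rr_curve", class(out)))
  out
}

#' @export
glance.rr_curve <- function(x, ...) {
  tibble(N = attr(x, "N"),
         rr_at_N = if (nrow(x) > 0) x$rr[nrow(x)] else NA_real_)
}

#' Per-junction PSI reproducibility between two runs
#'
#' `R = |E[psi_A] - E[psi_B]|` for junctions quantified in both runs;
#' junctions present in only one run are discarded. The conventional
#' summary is the fraction reproducible within 5 percentage points.
#'
#' @param psi_a,psi_b `psi_fit` tibbles.
#' @param within Reproducibility margin for the summary (default 0.05).
#' @return Tibble with `lsv_id`, `junction_id`, `psi_a`, `psi_b`, `r`;
#'   attribute `frac_within` gives the summary fraction.
#' @export
psi_reproducibility <- function(psi_a, psi_b, within = 0.05) {
  out <- inner_join(
    as_tibble(psi_a) %>% select("lsv_id", "junction_id", psi_a = "psi"),
    as_tibble(psi_b) %>% select("lsv_id", "junction_id", psi_b = "psi"),
    by = c("lsv_id", "junction_id")
  ) %>%
    mutate(r = abs(.data$psi_a - .data$psi_b))
  attr(out, "frac_within") <- if (nrow(out) > 0) mean(out$r < within) else NA_real_
  out
}

#' Dominant junction per LSV
#'
#' The dominant junction of an LSV in a condition is the one with
#' `E[psi] > 0.6` (strict; at most one junction can satisfy it). Reports
#' `NA` when no junction dominates.
#'
#' @param psi A `psi_fit` tibble.
#' @param threshold Dominance threshold (default 0.6, strict inequality).
#' @return Tibble with one row per LSV: `lsv_id`, `dominant_idx` (ordinal
#'   of the dominant junction in the LSV's canonical order, or `NA`),
#'   `dominant_junction` (its id, or `NA`).
#' @export
dominance <- function(psi, threshold = 0.6) {
  as_tibble(psi) %>%
    group_by(.data$lsv_id) %>%
    summarise(
      dominant_idx = {
        k <- which(.data$psi > threshold)
        if (length(k) == 1) .data$junction_idx[k] else NA_integer_
      },
      dominant_junction = {
        k <- which(.data$psi > threshold)
        if (length(k) == 1) .data$junction_id[k] else NA_character_
      },
      .groups = "drop"
    )
}

#' Ranked maximal inclusion of LSV junctions across conditions
#'
#' For each LSV, junctions are ordered by their maximum statistic across
#' conditions (E\\[psi\\], or |E\\[dPSI\\]| if a `dpsi_fit` is supplied), and
#' the per-rank values are returned for CDF summaries: e.g. how included
#' the 2nd, 3rd or least-used junction of complex LSVs ever gets.
#'
#' @param fits A named list of `psi_fit` (or `dpsi_fit`) tibbles, one per
#'   condition, or a single fit.
#' @return Tibble with `lsv_id`, `rank` (1 = most included), `value`
#'   (the max-across-conditions statistic), `n_junctions`, `complex`,
#'   `least_used` flag.
#' @export
max_inclusion_stats <- function(fits) {
  if (is_tibble(fits)) fits <- list(fits)
  stat_col <- if ("psi" %in% names(fits[[1]])) "psi" else "dpsi"
  long <- bind_rows(lapply(fits, as_tibble), .id = "condition") %>%
    mutate(value = abs(.data[[stat_col]]))
  long %>%
    group_by(.data$lsv_id, .data$junction_idx) %>%
    summarise(value = max(.data$value), .groups = "drop") %>%
    group_by(.data$lsv_id) %>%
    arrange(desc(.data$value), .by_group = TRUE) %>%
    mutate(rank = row_number(), n_junctions = n(),
           complex = n() > 2, least_used = row_number() == n()) %>%
    ungroup() %>%
    select("lsv_id", "rank", "value", "n_junctions", "complex",
           "least_used")
}

#' Enrichment of complex LSVs among differential calls
#'
#' Tests whether complex LSVs (more than two junctions) are
#' over-represented among changing LSVs relative to their proportion in
#' all detected LSVs, by an exact binomial tail, Bonferroni-corrected for
#' the number of datasets in the meta-analysis.
#'
#' @param changing Logical vector (or `lsv_catalog`): complexity of the
#'   changing LSVs.
#' @param detected Logical vector (or `lsv_catalog`): complexity of all
#'   detected LSVs.
#' @param n_datasets Bonferroni factor (default 1).
#' @return One-row tibble: counts, `fold` enrichment, `p` (binomial upper
#'   tail), `p_bonferroni`.
#' @export
complex_enrichment <- function(changing, detected, n_datasets = 1) {
  cx <- function(x) if (is.logical(x)) x else x$complex
  ch <- cx(changing); de <- cx(detected)
  if (length(ch) == 0) {
    return(tibble(n_changing = 0L, n_complex_changing = 0L,
                  background = mean(de), fold = NA_real_, p = NA_real_,
                  p_bonferroni = NA_real_))
  }
  p0 <- mean(de)
  k <- sum(ch); n <- length(ch)
  if (p0 == 0 && k > 0) abort("background complex proportion is 0; invalid null")
  fold <- (k / n) / p0
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  tibble(n_changing = n, n_complex_changing = k, background = p0,
         fold = fold, p = p, p_bonferroni = min(1, p * n_datasets))
}

#' Permutation-corrected Fisher tests on a junction feature table
#'
#' Raw p-values per feature come from the 2x2 Fisher exact test of
#' feature presence against the junction group label. The correction
#' shuffles labels while controlling for LSV origin: whole LSVs swap
#' label vectors only with LSVs having the same number of junctions, so
#' the number of labelled junctions and the within-LSV label correlation
#' structure are preserved. The corrected p-value of a feature is the
#' fraction of permutations whose *minimum* raw p across features is at
#' or below the feature's observed raw p (family-wise convention;
#' `family_wise = FALSE` gives the per-feature empirical p instead).
#'
#' @param table Tibble with one row per junction: `lsv_id`, a logical
#'   `label` column, and logical feature columns.
#' @param feature_cols Names of the feature columns (default: all logical
#'   columns except `label`).
#' @param n_perm Number of permutations (default 10000).
#' @param family_wise Use the min-p convention (default TRUE).
#' @param seed RNG seed.
#' @return Tibble per feature: `feature`, `n_with`, `p_raw`,
#'   `p_corrected`. Features present in fewer than 2 junctions are
#'   excluded with a message.
#' @export
permutation_fet <- function(table, feature_cols = NULL, n_perm = 10000,
                            family_wise = TRUE, seed = 1) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(table)[vapply(table, is.logical, logical(1))], "label")
  }
  n_with <- vapply(feature_cols, function(f) sum(table[[f]]), numeric(1))
  drop <- feature_cols[n_with < 2]
  if (length(drop) > 0) {
    inform(paste0("excluding feature(s) present in <2 junctions: ",
                  paste(drop, collapse = ", ")))
    feature_cols <- setdiff(feature_cols, drop)
  }
  if (length(feature_cols) == 0) abort("no testable features")

  tab2 <- function(label, feat) {
    matrix(c(sum(!label & !feat), sum(!label & feat),
             sum(label & !feat), sum(label & feat)), nrow = 2, byrow = TRUE)
  }
  fet_p <- function(label) {
    vapply(feature_cols, function(f) {
      fisher.test(tab2(label, table[[f]]))$p.value
    }, numeric(1))
  }

  obs <- fet_p(table$label)

  # group LSVs by junction count; permute label vectors across LSVs
  # within each size class
  lsv_sizes <- table %>% count(.data$lsv_id, name = "size")
  lsv_labels <- split(table$label, table$lsv_id)
  lsv_rows <- split(seq_len(nrow(table)), table$lsv_id)
  size_classes <- split(names(lsv_labels),
                        lsv_sizes$size[match(names(lsv_labels),
                                             lsv_sizes$lsv_id)])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, "permfet"))
  perm_p <- matrix(NA_real_, nrow = n_perm, ncol = length(feature_cols))
  label_perm <- table$label
  for (b in seq_len(n_perm)) {
    for (cls in size_classes) {
      perm <- sample(length(cls))
      for (i in seq_along(cls)) {
        src <- lsv_labels[[cls[perm[i]]]]
        label_perm[lsv_rows[[cls[i]]]] <- sample(src)
      }
    }
    perm_p[b, ] <- fet_p(label_perm)
  }
  min_p <- apply(perm_p, 1, min)
  p_corr <- vapply(seq_along(feature_cols), function(k) {
    if (family_wise) mean(min_p <= obs[k]) else mean(perm_p[, k] <= obs[k])
  }, numeric(1))
  tibble(feature = feature_cols,
         n_with = n_with[feature_cols],
         p_raw = unname(obs),
         p_corrected = p_corr)
}
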