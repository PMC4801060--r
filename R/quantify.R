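# End-to-end quantification: counts -> dispersion -> stacks -> bootstrap
# -> discretized posteriors, per LSV.

.prep_counts <- function(counts, r = NULL, stack_threshold = 1e-7,
                         gc = FALSE, seed = 1) {
  if (gc) counts <- gc_correct(counts, enable = TRUE)
  if (is.null(r)) {
    r <- tryCatch(fit_dispersion(counts, seed = seed),
                  error = function(e) {
                    inform("dispersion fit skipped (too little data); stacks not flagged")
                    NULL
                  })
  }
  if (!is.null(r) && is.finite(r)) {
    counts <- flag_stacks(counts, r = r, threshold = stack_threshold)
  }
  list(counts = counts, r = r)
}

# J x M sample matrix for one LSV from a bootstrap_samples tibble,
# summed across the experiments present (conjugate chain rule)
.mu_for_lsv <- function(boot, lsv_row, M) {
  jx <- lsv_row$junctions[[1]]
  experiments <- unique(boot$experiment)
  mu <- matrix(0, nrow = nrow(jx), ncol = M)
  for (k in seq_len(nrow(jx))) {
    hit <- boot$chrom == lsv_row$chrom &
      boot$donor_end == jx$donor_end[k] &
      boot$acceptor_start == jx$acceptor_start[k] &
      boot$is_intron == jx$is_intron[k]
    if (any(hit)) {
      for (row in which(hit)) mu[k, ] <- mu[k, ] + boot$mu[[row]]
    }
  }
  mu
}

#' Quantify PSI posteriors for a catalog of LSVs
#'
#' Runs the full read-rate model on one condition (one experiment or a
#' group of replicates): optional GC correction, per-experiment ZTNB
#' dispersion fit, stack flagging, quantifiable filtering, positional
#' bootstrap, and the discretized Beta posterior averaged over bootstrap
#' samples. Replicates are combined by the conjugate chain rule (their
#' sampled read rates add).
#'
#' @param lsvs An `lsv_catalog`.
#' @param counts A `junction_counts` tibble; every experiment present is
#'   treated as a replicate of the condition.
#' @param M Bootstrap samples per junction (default 100).
#' @param prior A [prior_config()].
#' @param r Dispersion; fitted from the data when `NULL`.
#' @param stack_threshold Stack flagging p-value cutoff (default 1e-7).
#' @param gc Apply GC correction first?
#' @param min_reads,min_positions Quantifiable filter (defaults 10, 3),
#'   applied after stack removal.
#' @param require_all Quantifiable in every replicate (default) or any.
#' @param seed Run-level seed.
#' @return A `psi_fit` tibble: one row per (LSV, junction) with `psi`
#'   (posterior mean) and `mass` (list-column of `V` bin masses).
#' @export
quantify_psi <- function(lsvs, counts, M = 100, prior = prior_config(),
                         r = NULL, stack_threshold = 1e-7, gc = FALSE,
                         min_reads = 10, min_positions = 3,
                         require_all = TRUE, seed = 1) {
  prep <- .prep_counts(counts, r = r, stack_threshold = stack_threshold,
                       gc = gc, seed = seed)
  counts <- prep$counts
  lsvs <- filter_quantifiable(lsvs, counts, min_reads = min_reads,
                              min_positions = min_positions,
                              require_all = require_all)
  boot <- bootstrap_rates(counts, M = M, seed = seed)
  rows <- vector("list", nrow(lsvs))
  for (i in seq_len(nrow(lsvs))) {
    mu <- .mu_for_lsv(boot, lsvs[i, ], M)
    post <- psi_posterior(mu, prior)
    jx <- lsvs$junctions[[i]]
    rows[[i]] <- post %>%
      mutate(lsv_id = lsvs$lsv_id[i],
             junction_id = jx$junction_id[.data$junction_idx])
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(junction_idx = integer(), psi = double(), mass = list(),
                  low_confidence = logical(), lsv_id = character(),
                  junction_id = character())
  }
  out <- out %>% select("lsv_id", "junction_id", "junction_idx", "psi",
                        "mass", "low_confidence")
  attr(out, "V") <- prior$V
  attr(out, "M") <- M
  attr(out, "r") <- prep$r
  attr(out, "experiments") <- unique(counts$experiment)
  class(out) <- unique(c("psi_fit", class(out)))
  out
}

#' Quantify dPSI posteriors between two conditions
#'
#' As [quantify_psi()] per condition, then the joint posterior with the
#' regularizing dPSI mixture prior. LSVs quantifiable in only one
#' condition are excluded with a message.
#'
#' @param lsvs An `lsv_catalog`.
#' @param counts_t,counts_tp `junction_counts` for the two conditions;
#'   experiments within each are replicates.
#' @param M,prior,r,stack_threshold,gc,min_reads,min_positions,require_all,seed
#'   As in [quantify_psi()]; `r` may be a length-2 list for the two
#'   conditions.
#' @param changing_threshold `|dPSI|` threshold reported in the
#'   `p_change` column (default 0.2).
#' @return A `dpsi_fit` tibble: one row per (LSV, junction) with `psi_t`,
#'   `psi_tp`, `dpsi`, `p_change` = `P(|dPSI| > changing_threshold)` and
#'   the full `mass` vector over `2V - 1` bins.
#' @export
quantify_dpsi <- function(lsvs, counts_t, counts_tp, M = 100,
                          prior = prior_config(), r = NULL,
                          stack_threshold = 1e-7, gc = FALSE,
                          min_reads = 10, min_positions = 3,
                          require_all = TRUE, changing_threshold = 0.2,
                          seed = 1) {
  if (!is.list(r)) r <- list(r, r)
  prep_t <- .prep_counts(counts_t, r = r[[1]], stack_threshold = stack_threshold,
                         gc = gc, seed = seed)
  prep_tp <- .prep_counts(counts_tp, r = r[[2]], stack_threshold = stack_threshold,
                          gc = gc, seed = .derive_seed(seed, "cond2"))
  q_t <- filter_quantifiable(lsvs, prep_t$counts, min_reads, min_positions,
                             require_all = require_all)
  q_tp <- filter_quantifiable(lsvs, prep_tp$counts, min_reads, min_positions,
                              require_all = require_all)
  shared <- intersect(q_t$lsv_id, q_tp$lsv_id)
  dropped <- setdiff(union(q_t$lsv_id, q_tp$lsv_id), shared)
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " LSV(s) quantifiable in only one condition; excluded"))
  }
  lsvs <- lsvs %>% filter(.data$lsv_id %in% shared)
  boot_t <- bootstrap_rates(prep_t$counts, M = M, seed = seed)
  boot_tp <- bootstrap_rates(prep_tp$counts, M = M,
                             seed = .derive_seed(seed, "cond2"))
  rows <- vector("list", nrow(lsvs))
  for (i in seq_len(nrow(lsvs))) {
    mu_t <- .mu_for_lsv(boot_t, lsvs[i, ], M)
    mu_tp <- .mu_for_lsv(boot_tp, lsvs[i, ], M)
    post <- .dpsi_engine(mu_t, mu_tp, prior)
    jx <- lsvs$junctions[[i]]
    rows[[i]] <- post %>%
      mutate(lsv_id = lsvs$lsv_id[i],
             junction_id = jx$junction_id[.data$junction_idx])
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(junction_idx = integer(), psi_t = double(),
                  psi_tp = double(), dpsi = double(), mass = list(),
                  lsv_id = character(), junction_id = character())
  }
  out <- out %>%
    mutate(p_change = vapply(.data$mass, prob_changing, numeric(1),
                             c = changing_threshold)) %>%
    select("lsv_id", "junction_id", "junction_idx", "psi_t", "psi_tp",
           "dpsi", "p_change", "mass")
  attr(out, "V") <- prior$V
  attr(out, "M") <- M
  attr(out, "changing_threshold") <- changing_threshold
  class(out) <- unique(c("dpsi_fit", class(out)))
  out
}

#' Write a posterior table as TSV
#'
#' The discretized mass vector is serialized as a comma-separated field,
#' keeping the table plain text while preserving the full posterior.
#'
#' @param fit A `psi_fit` or `dpsi_fit` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_table <- function(fit, path) {
  flat <- fit %>%
    mutate(mass = vapply(.data$mass,
                         function(m) paste(signif(m, 8), collapse = ","),
                         character(1)))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @export
tidy.psi_fit <- function(x, ...) {
  as_tibble(x) %>% select(-"mass")
}

#' @export
glance.psi_fit <- function(x, ...) {
  tibble(n_lsvs = length(unique(x$lsv_id)),
         n_junctions = nrow(x),
         V = attr(x, "V"), M = attr(x, "M"),
         mean_psi = mean(x$psi))
}

#' @export
tidy.dpsi_fit <- function(x, ...) {
  as_tibble(x) %>% select(-"mass")
}

#' @export
glance.dpsi_fit <- function(x, ...) {
  thr <- attr(x, "changing_threshold") %||% 0.2
  per_lsv <- as_tibble(x) %>%
    group_by(.data$lsv_id) %>%
    summarise(p = max(.data$p_change), .groups = "drop")
  tibble(n_lsvs = nrow(per_lsv), n_junctions = nrow(x),
         V = attr(x, "V"), M = attr(x, "M"),
         changing_threshold = thr,
         n_confident = sum(per_lsv$p > 0.95))
}
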