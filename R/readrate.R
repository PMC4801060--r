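# Read-rate machinery: GC correction, global ZTNB dispersion, stack
# removal, and the per-junction positional bootstrap.

#' Optional GC-content bias correction
#'
#' Rescales per-junction counts by a smooth factor of the junction's GC
#' fraction, fitted by loess of junction totals against GC and normalized
#' to mean 1 across junctions, so that totals are preserved on average.
#' With `enable = FALSE` (the default when GC fractions are absent) the
#' input is returned unchanged. This is a deliberately simple correction;
#' it removes a smooth monotone GC trend, nothing more.
#'
#' @param counts A `junction_counts` tibble; `gc` must be in `[0,1]` when
#'   the correction is enabled.
#' @param enable Apply the correction? Defaults to `TRUE` iff any `gc`
#'   values are present.
#' @param span Loess span (default 0.75).
#' @return The counts with rescaled `count` values.
#' @export
gc_correct <- function(counts, enable = any(!is.na(counts$gc)), span = 0.75) {
  if (!enable) return(counts)
  if (any(is.na(counts$gc))) abort("gc fraction missing for some junctions")
  if (any(counts$gc < 0 | counts$gc > 1)) abort("gc fraction outside [0,1]")
  totals <- counts %>%
    group_by(.data$experiment, .data$chrom, .data$strand,
             .data$donor_end, .data$acceptor_start, .data$is_intron) %>%
    summarise(total = sum(.data$count), gc = first(.data$gc),
              .groups = "drop")
  if (length(unique(totals$gc)) < 3) return(counts)  # no trend to fit
  fit <- loess(total ~ gc, data = totals, span = span, degree = 1)
  f <- predict(fit, newdata = totals)
  f <- pmax(f, 1e-8)
  f <- f / mean(f)
  fac <- totals %>% mutate(gc_factor = f) %>%
    select("experiment", "chrom", "strand", "donor_end", "acceptor_start",
           "is_intron", "gc_factor")
  out <- counts %>%
    left_join(fac, by = c("experiment", "chrom", "strand", "donor_end",
                          "acceptor_start", "is_intron")) %>%
    mutate(count = .data$count / .data$gc_factor) %>%
    select(-"gc_factor")
  class(out) <- class(counts)
  out
}

# zero-truncated NB log-pmf for x >= 1
.dztnb_log <- function(x, mu, size) {
  dnbinom(x, mu = mu, size = size, log = TRUE) -
    log1p(-dnbinom(0, mu = mu, size = size))
}

#' Fit the per-experiment ZTNB dispersion
#'
#' Models non-zero per-position read counts as zero-truncated negative
#' binomial with a junction-specific mean (plugged in as the junction's
#' observed non-zero-position mean) and a single experiment-wide dispersion
#' `r`, fitted by maximum likelihood over a random subsample of up to
#' `max_junctions` quantifiable junctions. Larger `r` means closer to
#' Poisson; the fit is clamped to `[r_floor, r_cap]`.
#'
#' @param counts A `junction_counts` tibble for one experiment (if several
#'   experiments are present they are fitted jointly).
#' @param max_junctions Subsample size cap (default 10000).
#' @param min_reads,min_positions Quantifiable-junction rule used to pick
#'   junctions for the fit (defaults 10 and 3).
#' @param r_floor,r_cap Clamp bounds for the dispersion (defaults 1e-2, 1e6).
#' @param seed Seed for the junction subsample.
#' @return The fitted dispersion, a positive scalar with attribute
#'   `n_junctions`.
#' @export
fit_dispersion <- function(counts, max_junctions = 10000,
                           min_reads = 10, min_positions = 3,
                           r_floor = 1e-2, r_cap = 1e6, seed = 1) {
  ev <- junction_evidence(counts, pool = FALSE, drop_stacks = FALSE) %>%
    filter(.data$reads >= min_reads, .data$positions >= min_positions)
  if (nrow(ev) == 0) abort("no quantifiable junctions to fit dispersion on")
  nz <- counts %>%
    filter(.data$count > 0) %>%
    inner_join(ev %>% select("experiment", "chrom", "strand",
                             "donor_end", "acceptor_start", "is_intron"),
               by = c("experiment", "chrom", "strand", "donor_end",
                      "acceptor_start", "is_intron")) %>%
    group_by(.data$experiment, .data$chrom, .data$strand,
             .data$donor_end, .data$acceptor_start, .data$is_intron) %>%
    mutate(mu_j = mean(.data$count)) %>%
    ungroup()
  jkeys <- nz %>% distinct(.data$experiment, .data$chrom, .data$strand,
                           .data$donor_end, .data$acceptor_start, .data$is_intron)
  if (nrow(jkeys) > max_junctions) {
    withr_seed <- .derive_seed(seed, "dispersion")
    old <- .Random.seed_save()
    set.seed(withr_seed)
    pick <- sort(sample.int(nrow(jkeys), max_junctions))
    .Random.seed_restore(old)
    nz <- nz %>% inner_join(jkeys[pick, ], by = names(jkeys))
  }
  x <- round(nz$count); mu <- nz$mu_j
  ok <- x >= 1
  x <- x[ok]; mu <- mu[ok]
  if (length(unique(x)) == 1) {
    warn("degenerate counts (all equal); returning dispersion floor")
    return(structure(r_floor, n_junctions = nrow(jkeys)))
  }
  nll <- function(logr) -sum(.dztnb_log(x, mu, exp(logr)))
  opt <- optimize(nll, interval = log(c(r_floor, r_cap)))
  r <- exp(opt$minimum)
  if (r >= r_cap * 0.99) r <- r_cap
  structure(max(r, r_floor), n_junctions = min(nrow(jkeys), max_junctions))
}

# save/restore global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Flag read stacks
#'
#' A stack is a position whose count is implausibly high given the
#' negative-binomial model: for each non-zero position the upper-tail
#' probability of its count is computed under NB with mean equal to the
#' average of the junction's *other* non-zero positions and dispersion
#' `r`; positions with `p <= threshold` (default 1e-7, deliberately
#' conservative) are flagged and excluded from all downstream computation.
#' A junction with a single non-zero position cannot be tested and is
#' retained.
#'
#' @param counts A `junction_counts` tibble.
#' @param r Dispersion from [fit_dispersion()].
#' @param threshold Upper-tail probability cutoff (default 1e-7).
#' @return The counts with the `stack` column set.
#' @export
flag_stacks <- function(counts, r, threshold = 1e-7) {
  counts %>%
    group_by(.data$experiment, .data$chrom, .data$strand,
             .data$donor_end, .data$acceptor_start, .data$is_intron) %>%
    mutate(stack = {
      x <- .data$count
      nz <- x > 0
      k <- sum(nz)
      if (k < 2) {
        rep(FALSE, length(x))
      } else {
        s <- sum(x[nz])
        mu_others <- (s - x) / (k - 1)
        p <- pnbinom(x - 1, size = r, mu = pmax(mu_others, 1e-12),
                     lower.tail = FALSE)
        nz & p <= threshold
      }
    }) %>%
    ungroup() %>%
    as_junction_counts()
}

#' Bootstrap per-junction read-rate estimates
#'
#' For each junction the relevant positions are the non-zero, non-stack
#' read-start positions (`W` of them). Each bootstrap sample draws `W`
#' positions with replacement and estimates the read rate as
#' `mu = W * mean(sampled counts)`; `M` repetitions give an empirical
#' distribution over `mu`. A junction with no relevant positions yields
#' all-zero samples. Samples are derived from a per-junction RNG stream
#' hashed from the junction id and `seed`, so results do not depend on
#' row order.
#'
#' @param counts A `junction_counts` tibble (stack-flagged rows are
#'   dropped).
#' @param M Number of bootstrap samples (default 100).
#' @param seed Run-level seed.
#' @return A `bootstrap_samples` tibble: one row per (experiment,
#'   junction) with `W`, `total`, and list-column `mu` of length-`M`
#'   samples.
#' @export
bootstrap_rates <- function(counts, M = 100, seed = 1) {
  stopifnot(M >= 1)
  nz <- counts %>% filter(!.data$stack, .data$count > 0)
  keys <- nz %>%
    group_by(.data$experiment, .data$chrom, .data$strand,
             .data$donor_end, .data$acceptor_start, .data$is_intron)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- keys %>%
    summarise(W = dplyr::n(), total = sum(.data$count),
              mu = {
        cts <- .data$count
        w <- length(cts)
        jid <- paste(first(.data$experiment), first(.data$chrom),
                     first(.data$donor_end), first(.data$acceptor_start),
                     first(.data$is_intron))
        set.seed(.derive_seed(seed, jid))
        if (w == 1) {
          list(rep(cts * 1, M))
        } else {
          idx <- matrix(sample.int(w, w * M, replace = TRUE), nrow = w)
          list(w * colMeans(matrix(cts[idx], nrow = w)))
        }
      }, .groups = "drop")
  class(out) <- unique(c("bootstrap_samples", class(out)))
  out
}
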