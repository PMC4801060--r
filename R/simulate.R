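# Synthetic gene models and junction-level read evidence with known truth.
#
# Reads are simulated at the junction-count level (no sequences, no
# alignment): per junction the total read count is negative-binomial
# around coverage * inclusion, spread multinomially across read-start
# positions, with optional single-position stacks and GC bias.

.sim_structures <- c("cassette", "alt5", "alt3", "multiway", "ir")

#' Simulate gene models with alternative splicing structures
#'
#' Generates genes containing cassette exons, alternative 5'/3' splice
#' sites, multi-way splits (complex LSVs with 3-6 junctions) or a
#' retainable intron, with per-junction true inclusion fractions in two
#' conditions. A configurable fraction of genes is differential with a
#' stated |dPSI| between the conditions; the rest share the same
#' inclusion in both.
#'
#' @param n_genes Number of genes.
#' @param structure Named probabilities over
#'   `c("cassette","alt5","alt3","multiway","ir")`; default all cassette.
#' @param complex_junctions Junction-count range for multiway genes
#'   (default 3:6).
#' @param psi True inclusion for condition A per gene; `NULL` draws
#'   uniformly from `[0.05, 0.95]`. Recycled to `n_genes`.
#' @param prop_differential Fraction of genes whose LSVs change between
#'   conditions (default 0.2).
#' @param delta True |dPSI| of differential genes (default 0.3; the shift
#'   direction is whichever keeps psi inside `[0.02, 0.98]`).
#' @param chrom Chromosome name.
#' @param seed RNG seed; the output is a deterministic function of it.
#' @return A list with `genes` (a `gene_models` tibble) and `truth`
#'   (a `sim_truth` tibble: one row per junction and condition-pair with
#'   `phi_a`, `phi_b` inclusion fractions, `is_intron`, `structure`,
#'   `differential`).
#' @export
simulate_genes <- function(n_genes, structure = c(cassette = 1),
                           complex_junctions = 3:6, psi = NULL,
                           prop_differential = 0.2, delta = 0.3,
                           chrom = "chrS", seed = 1) {
  stopifnot(n_genes >= 1)
  if (!all(names(structure) %in% .sim_structures)) {
    abort(paste0("unknown structure(s): ",
                 paste(setdiff(names(structure), .sim_structures),
                       collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, "genes"))

  probs <- structure / sum(structure)
  kinds <- sample(names(probs), n_genes, replace = TRUE, prob = probs)
  if (is.null(psi)) psi <- runif(n_genes, 0.05, 0.95)
  psi <- rep_len(psi, n_genes)
  diff_flag <- runif(n_genes) < prop_differential

  exon <- 150; intron <- 800
  gene_rows <- list(); truth_rows <- list()
  pos <- 1000
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%05d", i)
    kind <- kinds[i]
    pa <- psi[i]
    pb <- if (diff_flag[i]) {
      if (pa + delta <= 0.98) pa + delta else pa - delta
    } else pa
    e <- function(k) c(pos + (k - 1) * (exon + intron),
                       pos + (k - 1) * (exon + intron) + exon)
    add_tx <- function(tid, exons) {
      for (ex in exons) {
        gene_rows[[length(gene_rows) + 1L]] <<- tibble(
          gene_id = gid, chrom = chrom, strand = "+",
          transcript_id = paste0(gid, ".", tid),
          start = ex[1], end = ex[2])
      }
    }
    add_truth <- function(donor, acceptor, phi_a, phi_b, is_intron = FALSE) {
      truth_rows[[length(truth_rows) + 1L]] <<- tibble(
        gene_id = gid, chrom = chrom, strand = "+",
        donor_end = donor, acceptor_start = acceptor,
        phi_a = phi_a, phi_b = phi_b, is_intron = is_intron,
        structure = kind, differential = diff_flag[i])
    }

    if (kind == "cassette") {
      e1 <- e(1); e2 <- e(2); e3 <- e(3)
      add_tx("t1", list(e1, e2, e3)); add_tx("t2", list(e1, e3))
      add_truth(e1[2], e2[1], pa, pb)
      add_truth(e2[2], e3[1], pa, pb)
      add_truth(e1[2], e3[1], 1 - pa, 1 - pb)
      pos <- e3[2] + 5000
    } else if (kind %in% c("alt5", "alt3")) {
      e1 <- e(1); e2 <- e(2)
      if (kind == "alt5") {
        alt_end <- e1[2] - 60
        add_tx("t1", list(e1, e2))
        add_tx("t2", list(c(e1[1], alt_end), e2))
        add_truth(e1[2], e2[1], pa, pb)
        add_truth(alt_end, e2[1], 1 - pa, 1 - pb)
      } else {
        alt_start <- e2[1] + 60
        add_tx("t1", list(e1, e2))
        add_tx("t2", list(e1, c(alt_start, e2[2])))
        add_truth(e1[2], e2[1], pa, pb)
        add_truth(e1[2], alt_start, 1 - pa, 1 - pb)
      }
      pos <- e2[2] + 5000
    } else if (kind == "multiway") {
      k <- sample(complex_junctions, 1)
      # reference exon splices to k partner exons; partner i is included
      # with weight theta_i; partners re-join a common last exon
      mids <- k - 1
      exs <- lapply(seq_len(k + 1), e)
      theta_a <- c(pa, rep((1 - pa) / (k - 1), k - 1))
      theta_b <- c(pb, rep((1 - pb) / (k - 1), k - 1))
      last <- exs[[k + 1]]
      for (j in seq_len(mids)) {
        add_tx(paste0("t", j), list(exs[[1]], exs[[j + 1]], last))
        add_truth(exs[[1]][2], exs[[j + 1]][1], theta_a[j], theta_b[j])
        add_truth(exs[[j + 1]][2], last[1], theta_a[j], theta_b[j])
      }
      add_tx(paste0("t", k), list(exs[[1]], last))
      add_truth(exs[[1]][2], last[1], theta_a[k], theta_b[k])
      pos <- last[2] + 5000
    } else if (kind == "ir") {
      e1 <- e(1); e2 <- e(2)
      add_tx("t1", list(e1, e2))
      add_truth(e1[2], e2[1], 1 - pa, 1 - pb)            # spliced junction
      add_truth(e1[2], e2[1], pa, pb, is_intron = TRUE)  # retained intron
      pos <- e2[2] + 5000
    }
  }

  genes <- bind_rows(gene_rows) %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start)
  class(genes) <- c("gene_models", class(genes))
  truth <- bind_rows(truth_rows)
  class(truth) <- unique(c("sim_truth", class(truth)))
  list(genes = genes, truth = truth)
}

#' Simulate per-position junction counts from a truth table
#'
#' Per junction the total read count is marginally
#' `NB(coverage * phi, r)`; by default the negative-binomial
#' overdispersion enters as a shared per-gene Gamma(r, r) expression
#' factor with Poisson counts given the factor, so splicing ratios within
#' a gene stay multinomially clean (reads choose isoforms); mode
#' `"independent"` draws each junction's NB total independently instead.
#' Totals are spread multinomially over `W` read-start positions
#' (near-uniform, with optional exponential positional bias), optional
#' read stacks are injected as single-position spikes, and an optional
#' monotone GC bias rescales junction totals.
#'
#' @param truth A `sim_truth` tibble from [simulate_genes()].
#' @param condition `"a"` or `"b"`: which inclusion column drives the
#'   simulation.
#' @param coverage Expected reads per fully included junction (> 0).
#' @param r NB dispersion of junction totals (default 30).
#' @param W Number of read-start positions per junction window
#'   (default 40).
#' @param n_replicates Independent replicates to emit (default 1).
#' @param positional_bias Exponential tilt of the positional distribution
#'   (0 = uniform).
#' @param stack_rate Per-junction probability of an injected stack.
#' @param stack_size Reads added at the stacked position (default 500).
#' @param gc_bias `NULL` for none, or a slope: junction totals are scaled
#'   by `exp(gc_bias * (gc - 0.5))` with per-junction GC drawn uniformly
#'   in `[0.3, 0.7]` and recorded in the `gc` column.
#' @param experiment_prefix Experiment names are
#'   `<prefix>_r<replicate>`.
#' @param mode `"shared"` (default) or `"independent"` (see above).
#' @param seed RNG seed.
#' @return A `junction_counts` tibble.
#' @export
simulate_counts <- function(truth, condition = "a", coverage = 50, r = 30,
                            W = 40, n_replicates = 1, positional_bias = 0,
                            stack_rate = 0, stack_size = 500,
                            gc_bias = NULL,
                            experiment_prefix = condition,
                            mode = c("shared", "independent"), seed = 1) {
  if (coverage <= 0) abort("coverage must be > 0")
  mode <- match.arg(mode)
  phi <- if (tolower(condition) == "a") truth$phi_a else truth$phi_b
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  pos_probs <- exp(positional_bias * (seq_len(W) - 1) / W)
  pos_probs <- pos_probs / sum(pos_probs)

  gc_of <- NULL
  if (!is.null(gc_bias)) {
    set.seed(.derive_seed(seed, "gc"))
    gc_of <- runif(nrow(truth), 0.3, 0.7)
  }

  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    exp_id <- paste0(experiment_prefix, "_r", rep_i)
    set.seed(.derive_seed(seed, paste0(exp_id, ":", condition)))
    gene_factor <- setNames(
      rgamma(length(unique(truth$gene_id)), shape = r, rate = r),
      unique(truth$gene_id))
    for (i in seq_len(nrow(truth))) {
      lambda <- coverage * phi[i]
      if (!is.null(gc_bias)) lambda <- lambda * exp(gc_bias * (gc_of[i] - 0.5))
      total <- if (mode == "shared") {
        rpois(1, gene_factor[truth$gene_id[i]] * lambda)
      } else {
        rnbinom(1, mu = lambda, size = r)
      }
      cts <- if (total > 0) rmultinom(1, total, pos_probs)[, 1] else numeric(W)
      if (stack_rate > 0 && runif(1) < stack_rate) {
        p <- sample.int(W, 1)
        cts[p] <- cts[p] + stack_size
      }
      nz <- which(cts > 0)
      if (length(nz) == 0) next
      rows[[length(rows) + 1L]] <- tibble(
        experiment = exp_id,
        chrom = truth$chrom[i], strand = truth$strand[i],
        donor_end = truth$donor_end[i],
        acceptor_start = truth$acceptor_start[i],
        is_intron = truth$is_intron[i],
        offset = nz - 1L, count = as.double(cts[nz]),
        gc = if (is.null(gc_bias)) NA_real_ else gc_of[i]
      )
    }
  }
  if (length(rows) == 0) {
    return(as_junction_counts(tibble(
      experiment = character(), chrom = character(), strand = character(),
      donor_end = double(), acceptor_start = double(), offset = integer(),
      count = double())))
  }
  as_junction_counts(bind_rows(rows))
}

#' True per-junction PSI for a catalog of LSVs
#'
#' Normalizes the truth table's junction inclusion fractions within each
#' LSV's junction set, giving the ground-truth PSI vector the quantifier
#' should recover.
#'
#' @param lsvs An `lsv_catalog`.
#' @param truth A `sim_truth` tibble.
#' @return Tibble with `lsv_id`, `junction_id`, `junction_idx`,
#'   `true_psi_a`, `true_psi_b`, `true_dpsi`, `differential`.
#' @export
true_lsv_psi <- function(lsvs, truth) {
  tr <- truth %>%
    mutate(junction_id = .junction_id(.data$chrom, .data$donor_end,
                                      .data$acceptor_start, .data$is_intron))
  rows <- purrr::map(seq_len(nrow(lsvs)), function(i) {
    jx <- lsvs$junctions[[i]]
    t_i <- tr %>% filter(.data$junction_id %in% jx$junction_id,
                         .data$gene_id == lsvs$gene_id[i])
    if (nrow(t_i) == 0) return(NULL)
    t_i %>%
      mutate(junction_idx = match(.data$junction_id, jx$junction_id),
             true_psi_a = .data$phi_a / sum(.data$phi_a),
             true_psi_b = .data$phi_b / sum(.data$phi_b),
             lsv_id = lsvs$lsv_id[i]) %>%
      select("lsv_id", "junction_id", "junction_idx",
             "true_psi_a", "true_psi_b", "differential")
  })
  # dPSI convention: first condition minus second (psi_a - psi_b),
  # matching the quantifier's dpsi = psi_t - psi_t'
  bind_rows(rows) %>%
    mutate(true_dpsi = .data$true_psi_a - .data$true_psi_b)
}

#' Compare estimates against simulation truth
#'
#' Joins a `psi_fit` or `dpsi_fit` with the ground truth and reports
#' per-junction errors plus aggregate recovery metrics; when ranked calls
#' and the truth's differential flags are both available, a selection
#' confusion matrix is included.
#'
#' @param fit A `psi_fit` or `dpsi_fit`.
#' @param lsvs The `lsv_catalog` the fit was computed on.
#' @param truth The `sim_truth` tibble.
#' @param calls Optional `ranked_calls` from [select_differential()].
#' @param condition For `psi_fit`s: which condition's truth to compare
#'   against (`"a"` or `"b"`).
#' @return A list with `per_junction` (tibble of errors) and `summary`
#'   (one-row tibble: `n`, `mae`, `bias`, `rmse`, and confusion counts
#'   when `calls` is given).
#' @export
truth_compare <- function(fit, lsvs, truth, calls = NULL, condition = "a") {
  tt <- true_lsv_psi(lsvs, truth)
  is_dpsi <- inherits(fit, "dpsi_fit") || "dpsi" %in% names(fit)
  est <- as_tibble(fit)
  joined <- inner_join(est, tt,
                       by = c("lsv_id", "junction_id", "junction_idx"))
  if (nrow(joined) == 0) abort("no overlap between estimates and truth ids")
  if (is_dpsi) {
    joined <- joined %>% mutate(error = .data$dpsi - .data$true_dpsi)
  } else {
    tcol <- if (tolower(condition) == "a") "true_psi_a" else "true_psi_b"
    joined <- joined %>% mutate(error = .data$psi - .data[[tcol]])
  }
  summary <- tibble(
    n = nrow(joined),
    mae = mean(abs(joined$error)),
    bias = mean(joined$error),
    rmse = sqrt(mean(joined$error^2))
  )
  if (!is.null(calls)) {
    truth_lsv <- tt %>% group_by(.data$lsv_id) %>%
      summarise(differential = any(.data$differential), .groups = "drop")
    sel <- calls %>% select("lsv_id", "selected") %>%
      inner_join(truth_lsv, by = "lsv_id")
    summary <- summary %>% mutate(
      tp = sum(sel$selected & sel$differential),
      fp = sum(sel$selected & !sel$differential),
      fn = sum(!sel$selected & sel$differential),
      tn = sum(!sel$selected & !sel$differential)
    )
  }
  list(per_junction = joined %>% select(-"mass"), summary = summary)
}

#' Write a truth manifest as JSON
#'
#' @param truth A `sim_truth` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(as_tibble(truth), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
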