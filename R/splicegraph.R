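#' Reliability filter for de novo junction evidence
#'
#' A junction absent from the annotation is admitted to the splice graph
#' only if it is supported by at least `min_reads` reads spread over at
#' least `min_positions` distinct read-start positions (defaults 2 and 2),
#' in one experiment (default) or pooled across experiments.
#'
#' @param min_reads Minimum total reads (default 2).
#' @param min_positions Minimum distinct non-zero positions (default 2).
#' @return A `reliability_filter` list.
#' @export
reliability_filter <- function(min_reads = 2, min_positions = 2) {
  stopifnot(min_reads >= 1, min_positions >= 1)
  structure(list(min_reads = min_reads, min_positions = min_positions),
            class = "reliability_filter")
}

.merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Build a per-gene splice graph
#'
#' Combines the annotated transcript structure of one gene with reliable
#' de novo junction evidence. All annotated junctions are kept (marked
#' `annotated`, even with zero reads). A de novo junction passes if it
#' meets the [reliability_filter()] in at least one experiment
#' (`per_experiment = TRUE`) or pooled across experiments. De novo splice
#' sites falling outside annotated exons extend the proximal exon
#' (an intronic donor extends the upstream exon out to it, an intronic
#' acceptor extends the downstream exon back to it); an acceptor followed
#' by a donor within the same intron delimits a putative de novo exon.
#' De novo exonic regions longer than `max_denovo_exon` (default 500 bp,
#' roughly the 95th percentile of known exon lengths) are not closed:
#' they become open-ended regions whose unknown far boundary is flagged,
#' and edges touching them are excluded from LSV enumeration.
#'
#' @param gene A `gene_models` tibble restricted to a single gene.
#' @param counts Optional `junction_counts` evidence.
#' @param filter A [reliability_filter()].
#' @param max_denovo_exon Maximum length of a closed de novo exonic region.
#' @param flank Evidence beyond the gene span by more than this is ignored.
#' @param per_experiment Assess the reliability filter per experiment
#'   (default) rather than on pooled evidence.
#' @return A `splice_graph` object: a list with `gene_id`, `chrom`,
#'   `strand`, and tibbles `exons` (`start`, `end`, `origin`, `open_ended`,
#'   `unit`), `junctions` (`donor_end`, `acceptor_start`, `origin`,
#'   `is_intron`, nested `evidence`), `introns`.
#' @export
build_splice_graph <- function(gene, counts = NULL,
                               filter = reliability_filter(),
                               max_denovo_exon = 500, flank = 5000,
                               per_experiment = TRUE) {
  stopifnot(inherits(filter, "reliability_filter"))
  gid <- unique(gene$gene_id)
  if (length(gid) != 1) abort("build_splice_graph() expects a single gene")
  chrom <- gene$chrom[1]; strand <- gene$strand[1]
  span <- c(min(gene$start), max(gene$end))

  ann_ex <- .merge_intervals(gene$start, gene$end) %>%
    mutate(origin = "annotated", open_ended = FALSE)
  ann_jx <- annotated_junctions(gene) %>%
    select("donor_end", "acceptor_start")

  # ---- de novo junction evidence -------------------------------------
  ev <- NULL
  denovo_jx <- tibble(donor_end = double(), acceptor_start = double())
  if (!is.null(counts) && nrow(counts) > 0) {
    local <- counts %>%
      filter(.data$chrom == !!chrom, .data$strand == !!strand,
             .data$donor_end >= span[1] - flank,
             .data$acceptor_start <= span[2] + flank)
    ev <- junction_evidence(local, pool = FALSE, drop_stacks = TRUE) %>%
      filter(!.data$is_intron)
    pass <- junction_evidence(local, pool = !per_experiment,
                              drop_stacks = TRUE) %>%
      filter(!.data$is_intron,
             .data$reads >= filter$min_reads,
             .data$positions >= filter$min_positions) %>%
      distinct(.data$donor_end, .data$acceptor_start)
    denovo_jx <- anti_join(pass, ann_jx,
                           by = c("donor_end", "acceptor_start"))
  }

  # ---- place novel splice sites --------------------------------------
  inside_donor <- function(p) any(p > ann_ex$start & p <= ann_ex$end)
  inside_acceptor <- function(p) any(p >= ann_ex$start & p < ann_ex$end)
  novel_donors <- sort(unique(denovo_jx$donor_end[
    !vapply(denovo_jx$donor_end, inside_donor, logical(1))]))
  novel_acceptors <- sort(unique(denovo_jx$acceptor_start[
    !vapply(denovo_jx$acceptor_start, inside_acceptor, logical(1))]))

  extra <- tibble(start = double(), end = double(),
                  origin = character(), open_ended = logical())
  add_region <- function(s, e, origin, open = FALSE) {
    extra <<- bind_rows(extra, tibble(start = s, end = e,
                                      origin = origin, open_ended = open))
  }

  # gaps between consecutive merged annotated exons (+ outer flanks)
  bounds <- c(-Inf, ann_ex$end, Inf)
  gap_lo <- c(-Inf, ann_ex$end)
  gap_hi <- c(ann_ex$start, Inf)
  for (g in seq_along(gap_lo)) {
    lo <- gap_lo[g]; hi <- gap_hi[g]
    acc <- novel_acceptors[novel_acceptors >= lo & novel_acceptors < hi]
    don <- novel_donors[novel_donors > lo & novel_donors <= hi]
    used_d <- logical(length(don))
    for (a in acc) {
      k <- which(!used_d & don > a)
      if (length(k) > 0) {
        d <- don[k[1]]; used_d[k[1]] <- TRUE
        if (d - a <= max_denovo_exon) {
          add_region(a, d, "denovo")
        } else {
          add_region(a, NA_real_, "denovo", open = TRUE)
          add_region(NA_real_, d, "denovo", open = TRUE)
        }
      } else if (is.finite(hi) && hi - a <= max_denovo_exon) {
        add_region(a, hi, "denovo_extension")   # extend downstream exon back
      } else {
        add_region(a, NA_real_, "denovo", open = TRUE)
      }
    }
    for (d in don[!used_d]) {
      if (is.finite(lo) && d - lo <= max_denovo_exon) {
        add_region(lo, d, "denovo_extension")   # extend upstream exon out
      } else {
        add_region(NA_real_, d, "denovo", open = TRUE)
      }
    }
  }

  exons <- bind_rows(ann_ex, extra) %>%
    arrange(is.na(.data$start), .data$start, .data$end)

  # exon units: contiguous/overlapping closed regions form one unit
  closed <- !exons$open_ended
  unit <- integer(nrow(exons))
  uid <- 0L; cur_end <- -Inf
  for (i in seq_len(nrow(exons))) {
    if (!closed[i]) { uid <- uid + 1L; unit[i] <- uid; next }
    if (exons$start[i] > cur_end) uid <- uid + 1L
    unit[i] <- uid
    cur_end <- max(cur_end, exons$end[i])
  }
  exons$unit <- unit

  jx <- bind_rows(
    ann_jx %>% mutate(origin = "annotated"),
    denovo_jx %>% mutate(origin = "denovo")
  ) %>%
    distinct(.data$donor_end, .data$acceptor_start, .keep_all = TRUE) %>%
    mutate(is_intron = FALSE) %>%
    arrange(.data$donor_end, .data$acceptor_start)

  # attach per-experiment evidence summaries
  if (!is.null(ev) && nrow(ev) > 0) {
    evn <- ev %>%
      select("donor_end", "acceptor_start", "experiment", "reads", "positions") %>%
      tidyr::nest(evidence = c("experiment", "reads", "positions"))
    jx <- left_join(jx, evn, by = c("donor_end", "acceptor_start"))
  } else {
    jx$evidence <- vector("list", nrow(jx))
  }

  # candidate retained introns: gaps between consecutive closed units
  units <- exons %>%
    filter(!.data$open_ended) %>%
    group_by(.data$unit) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    arrange(.data$start)
  introns <- tibble(start = double(), end = double(), retained = logical())
  if (nrow(units) > 1) {
    introns <- tibble(start = units$end[-nrow(units)],
                      end = units$start[-1], retained = FALSE) %>%
      filter(.data$end > .data$start)
  }

  structure(list(gene_id = gid, chrom = chrom, strand = strand,
                 exons = exons, junctions = jx, introns = introns),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("<splice_graph> gene ", x$gene_id, " (", x$chrom, x$strand, ")\n",
      "  exons: ", nrow(x$exons),
      " (", sum(x$exons$origin != "annotated"), " de novo)",
      "  junctions: ", nrow(x$junctions),
      " (", sum(x$junctions$origin == "denovo"), " de novo)",
      "  retained introns: ", sum(x$introns$retained), "\n", sep = "")
  invisible(x)
}

#' Tidy a splice graph into one edge-per-row tibble
#'
#' @param x A `splice_graph`.
#' @param ... Unused.
#' @return Tibble of junction and intron edges with origins.
#' @export
tidy.splice_graph <- function(x, ...) {
  x$junctions %>%
    mutate(gene_id = x$gene_id, chrom = x$chrom, strand = x$strand) %>%
    select("gene_id", "chrom", "strand", "donor_end", "acceptor_start",
           "origin", "is_intron")
}

#' Detect retained introns by windowed coverage
#'
#' An intron between two exon units gains a retention edge iff every
#' consecutive fixed-width window tiled across it (last window truncated;
#' an intron shorter than one window is a single window) has average
#' per-base coverage at or above `min_intronic_cov` in at least one
#' experiment. The builder default threshold is 1.5; a relaxed evaluation
#' mode (e.g. 0.5) is just a different `min_intronic_cov`.
#'
#' @param graph A `splice_graph`.
#' @param coverage Per-base depth: tibble with `experiment`, `chrom`,
#'   `pos` (0-based), `depth`; absent positions count as depth 0.
#' @param min_intronic_cov Average-coverage threshold (default 1.5).
#' @param window Window width in bp (default 50).
#' @return The graph with `introns$retained` updated and one retention
#'   edge (`is_intron = TRUE`) appended per retained intron.
#' @export
detect_retained_introns <- function(graph, coverage, min_intronic_cov = 1.5,
                                    window = 50) {
  stopifnot(min_intronic_cov >= 0, window >= 1)
  if (nrow(graph$introns) == 0) return(graph)
  cov <- coverage %>% filter(.data$chrom == graph$chrom)
  experiments <- unique(cov$experiment)
  retained <- logical(nrow(graph$introns))
  for (i in seq_len(nrow(graph$introns))) {
    s <- graph$introns$start[i]; e <- graph$introns$end[i]
    ws <- seq(s, e - 1, by = window)
    for (ex in experiments) {
      d <- cov %>% filter(.data$experiment == ex,
                          .data$pos >= s, .data$pos < e)
      depth <- numeric(e - s)
      if (nrow(d) > 0) depth[d$pos - s + 1] <- d$depth
      means <- vapply(ws, function(w0) {
        idx <- (w0 - s + 1):(min(w0 + window, e) - s)
        mean(depth[idx])
      }, numeric(1))
      if (all(means >= min_intronic_cov)) { retained[i] <- TRUE; break }
    }
  }
  graph$introns$retained <- retained
  if (any(retained)) {
    ir <- graph$introns[retained, ]
    new_edges <- tibble(
      donor_end = ir$start, acceptor_start = ir$end,
      origin = "denovo", is_intron = TRUE,
      evidence = vector("list", nrow(ir))
    )
    new_edges <- anti_join(
      new_edges,
      graph$junctions %>% filter(.data$is_intron),
      by = c("donor_end", "acceptor_start")
    )
    graph$junctions <- bind_rows(graph$junctions, new_edges) %>%
      arrange(.data$donor_end, .data$acceptor_start)
  }
  graph
}

#' Serialize splice graphs to JSON
#'
#' @param graphs A `splice_graph` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_graph_json <- function(graphs, path) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  payload <- lapply(graphs, function(g) {
    list(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      exons = g$exons,
      junctions = g$junctions %>%
        mutate(evidence = purrr::map(.data$evidence,
                                     ~ if (is.null(.x)) list() else .x)),
      introns = g$introns
    )
  })
  names(payload) <- vapply(graphs, function(g) g$gene_id, character(1))
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
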