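#' Read a per-position junction count table
#'
#' The TSV schema is the package's plain-text alternative to BAM input:
#' one row per (experiment, junction, read-start offset) with columns
#' `experiment`, `chrom`, `strand`, `donor_end`, `acceptor_start`, `offset`,
#' `count`, and optionally `gc` (junction GC fraction in `[0,1]`).
#' Coordinates are 0-based half-open: `donor_end` is the end of the upstream
#' exonic segment, `acceptor_start` the start of the downstream one, and
#' `offset` indexes the read start position within the junction window.
#'
#' @param path Path to the TSV file.
#' @return A `junction_counts` tibble (adds a `stack` logical column,
#'   initially `FALSE`, used by [flag_stacks()]).
#' @export
read_counts_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    experiment = "c", chrom = "c", strand = "c",
    donor_end = "d", acceptor_start = "d", offset = "i", count = "d",
    .default = "d"
  ), progress = FALSE)
  req <- c("experiment", "chrom", "strand", "donor_end", "acceptor_start",
           "offset", "count")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("counts table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(tbl$count < 0)) {
    abort(paste0("negative count at line ",
                 which(tbl$count < 0)[1] + 1L, " of ", path))
  }
  if (!"is_intron" %in% names(tbl)) tbl$is_intron <- FALSE
  tbl$is_intron <- as.logical(tbl$is_intron)
  dup <- duplicated(tbl[, c("experiment", "chrom", "strand", "donor_end",
                            "acceptor_start", "is_intron", "offset")])
  if (any(dup)) {
    abort(paste0("duplicate (junction, offset) row at line ",
                 which(dup)[1] + 1L, " of ", path))
  }
  as_junction_counts(tbl)
}

#' Coerce a data frame to the junction-counts container
#'
#' @param x Data frame with the columns documented in [read_counts_table()].
#' @return A `junction_counts` tibble.
#' @export
as_junction_counts <- function(x) {
  x <- as_tibble(x)
  if (nrow(x) == 0) {
    proto <- tibble(experiment = character(), chrom = character(),
                    strand = character(), donor_end = double(),
                    acceptor_start = double(), offset = integer(),
                    count = double())
    for (nm in setdiff(names(proto), names(x))) x[[nm]] <- proto[[nm]]
  }
  if (!"stack" %in% names(x)) x$stack <- FALSE
  if (!"gc" %in% names(x)) x$gc <- NA_real_
  if (!"is_intron" %in% names(x)) x$is_intron <- FALSE
  x <- x %>% arrange(.data$experiment, .data$chrom, .data$donor_end,
                     .data$acceptor_start, .data$is_intron, .data$offset)
  class(x) <- unique(c("junction_counts", class(x)))
  x
}

#' Write a junction count table
#'
#' @param counts A `junction_counts` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  out <- counts %>%
    select("experiment", "chrom", "strand", "donor_end", "acceptor_start",
           "is_intron", "offset", "count", "gc")
  if (all(is.na(out$gc))) out$gc <- NULL
  if (!any(out$is_intron)) out$is_intron <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise evidence per junction
#'
#' Total reads and number of distinct non-zero read-start positions per
#' junction, per experiment (or pooled). Stack-flagged positions are
#' excluded when `drop_stacks = TRUE`.
#'
#' @param counts A `junction_counts` tibble.
#' @param pool Pool across experiments before summarising?
#' @param drop_stacks Exclude positions flagged by [flag_stacks()]?
#' @return Tibble with `experiment` (unless pooled), junction key columns,
#'   `reads`, `positions`.
#' @export
junction_evidence <- function(counts, pool = FALSE, drop_stacks = TRUE) {
  x <- counts
  if (drop_stacks && "stack" %in% names(x)) x <- filter(x, !.data$stack)
  if (!"is_intron" %in% names(x)) x$is_intron <- FALSE
  keys <- c(if (!pool) "experiment", "chrom", "strand",
            "donor_end", "acceptor_start", "is_intron")
  x %>%
    filter(.data$count > 0) %>%
    group_by(across(all_of(keys))) %>%
    summarise(reads = sum(.data$count), positions = dplyr::n_distinct(.data$offset),
              .groups = "drop")
}

#' Extract per-position junction counts from a BAM file
#'
#' Scans split-read (CIGAR `N`) alignments overlapping each gene's span and
#' tallies, per junction, the number of uniquely mapped reads starting at
#' each offset of the junction window. The read-start offset is measured on
#' the donor side: a read whose last aligned base before the gap sits
#' `k` bases from the junction gets offset `k - min_overhang`. Reads whose
#' anchor on either side of the junction is shorter than `min_overhang`
#' are discarded, as are reads below the unique-mapping MAPQ threshold.
#' Junctions falling inside the spans of two genes on opposite strands are
#' counted for neither and reported with a warning.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param genes A `gene_models` tibble; junctions are attributed to the
#'   gene(s) whose span (plus `flank`) contains them.
#' @param min_overhang Minimum aligned bases on both sides of the junction
#'   (default 8).
#' @param mapq_unique MAPQ at or above which an alignment counts as uniquely
#'   mapped (default 255, the "unique" convention of splice-aware aligners;
#'   set lower for aligners that cap MAPQ differently).
#' @param experiment Experiment label for the output; defaults to the BAM
#'   base name.
#' @param flank Extra genomic span around each gene searched for junctions.
#' @return A `junction_counts` tibble.
#' @export
extract_junction_counts <- function(bam, genes, min_overhang = 8,
                                    mapq_unique = 255,
                                    experiment = NULL, flank = 0) {
  for (pkg in c("Rsamtools", "GenomicAlignments", "GenomicRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("package '", pkg, "' is required for BAM input"))
    }
  }
  if (min_overhang < 1) abort("min_overhang must be >= 1")
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort(paste0("BAM index not found for ", bam,
                 "; index it first (e.g. samtools index)"))
  }
  if (is.null(experiment)) {
    experiment <- sub("\\.bam$", "", basename(bam))
  }

  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = "mapq",
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE)
    )
  )
  mq <- S4Vectors::mcols(aln)$mapq
  aln <- aln[!is.na(mq) & mq >= mapq_unique]
  if (length(aln) == 0) {
    return(as_junction_counts(tibble(
      experiment = character(), chrom = character(), strand = character(),
      donor_end = double(), acceptor_start = double(),
      offset = integer(), count = double()
    )))
  }

  rows <- list()
  cig <- GenomicAlignments::cigar(aln)
  starts <- GenomicRanges::start(aln)  # 1-based
  chroms <- as.character(GenomicAlignments::seqnames(aln))
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)

  for (i in seq_along(aln)) {
    op <- ops[[i]]; ln <- lens[[i]]
    if (!any(op == "N")) next
    ref_consume <- op %in% c("M", "D", "N", "=", "X")
    pos <- starts[i] - 1L  # 0-based
    seg_len <- 0L          # aligned bases since last gap / read start
    segs <- integer(0); gaps <- list()
    for (k in seq_along(op)) {
      if (op[k] == "N") {
        gaps[[length(gaps) + 1L]] <- c(pos, pos + ln[k], seg_len)
        segs <- c(segs, seg_len)
        seg_len <- 0L
      } else if (op[k] %in% c("M", "=", "X")) {
        seg_len <- seg_len + ln[k]
      }
      if (ref_consume[k]) pos <- pos + ln[k]
    }
    segs <- c(segs, seg_len)
    for (k in seq_along(gaps)) {
      left <- segs[k]; right <- segs[k + 1L]
      if (left < min_overhang || right < min_overhang) next
      g <- gaps[[k]]
      rows[[length(rows) + 1L]] <- c(i, g[1], g[2], g[3])
    }
  }

  if (length(rows) == 0) {
    return(as_junction_counts(tibble(
      experiment = character(), chrom = character(), strand = character(),
      donor_end = double(), acceptor_start = double(),
      offset = integer(), count = double()
    )))
  }
  m <- do.call(rbind, rows)
  jx <- tibble(
    rid = seq_len(nrow(m)),
    chrom = chroms[m[, 1]],
    donor_end = m[, 2],
    acceptor_start = m[, 3],
    offset = as.integer(m[, 4] - min_overhang)
  )

  spans <- genes %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(gstart = min(.data$start) - flank, gend = max(.data$end) + flank,
              .groups = "drop")

  assigned <- jx %>%
    inner_join(spans, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$donor_end >= .data$gstart, .data$acceptor_start <= .data$gend)

  amb <- assigned %>%
    distinct(.data$chrom, .data$donor_end, .data$acceptor_start, .data$strand) %>%
    count(.data$chrom, .data$donor_end, .data$acceptor_start) %>%
    filter(.data$n > 1)
  if (nrow(amb) > 0) {
    warn(paste0(nrow(amb), " junction(s) span genes on opposite strands; ",
                "counted for neither"))
    assigned <- anti_join(
      assigned, amb,
      by = c("chrom", "donor_end", "acceptor_start")
    )
  }

  out <- assigned %>%
    distinct(.data$rid, .data$chrom, .data$strand, .data$donor_end,
             .data$acceptor_start, .data$offset) %>%
    count(.data$chrom, .data$strand, .data$donor_end, .data$acceptor_start,
          .data$offset, name = "count") %>%
    mutate(experiment = experiment, count = as.double(.data$count)) %>%
    select("experiment", "chrom", "strand", "donor_end", "acceptor_start",
           "offset", "count")
  as_junction_counts(out)
}
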