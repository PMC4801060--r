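#' Parse gene models from a GFF3 annotation
#'
#' Reads a GFF3 file with the usual gene / mRNA (or transcript) / exon
#' hierarchy and returns one row per exon. GFF3 coordinates are 1-based
#' inclusive; internally everything is 0-based half-open, so an exon printed
#' as `start=101, end=200` becomes `[100, 200)`. Exons are sorted in genomic
#' ascending order within each transcript regardless of strand.
#'
#' Malformed records are handled leniently where the damage is local: an exon
#' whose `Parent` is not a known transcript, or whose start exceeds its end,
#' is dropped with a warning and parsing continues. A gene whose transcripts
#' disagree on strand is a hard error, because strand decides how splice
#' sites are labelled downstream.
#'
#' @param path Path to a GFF3 file (plain text).
#' @return A tibble of class `gene_models` with columns `gene_id`, `chrom`,
#'   `strand`, `transcript_id`, `start`, `end` (0-based half-open exon
#'   intervals), one row per exon.
#' @seealso [write_gff3()] for the inverse, [build_splice_graph()].
#' @export
parse_gff3 <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_names = c("seqid", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes"),
    col_types = readr::cols(
      seqid = "c", source = "c", type = "c", start = "d", end = "d",
      score = "c", strand = "c", phase = "c", attributes = "c"
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(structure(
      tibble(gene_id = character(), chrom = character(), strand = character(),
             transcript_id = character(), start = double(), end = double()),
      class = c("gene_models", "tbl_df", "tbl", "data.frame")
    ))
  }

  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))
    m[, 2]
  }

  type <- tolower(raw$type)
  genes <- raw[type == "gene", ]
  txs <- raw[type %in% c("mrna", "transcript"), ]
  exons <- raw[type == "exon", ]

  gene_ids <- attr_field(genes$attributes, "ID")
  tx_ids <- attr_field(txs$attributes, "ID")
  tx_parent <- attr_field(txs$attributes, "Parent")

  tx_tbl <- tibble(
    transcript_id = tx_ids, gene_id = tx_parent,
    tx_strand = txs$strand, tx_chrom = txs$seqid
  ) %>% filter(!is.na(.data$transcript_id))

  orphan_tx <- !(tx_tbl$gene_id %in% gene_ids)
  if (any(orphan_tx)) {
    warn(paste0("dropping ", sum(orphan_tx),
                " transcript(s) whose Parent is not a gene record"))
    tx_tbl <- tx_tbl[!orphan_tx, ]
  }

  ex_parent <- attr_field(exons$attributes, "Parent")
  ex <- tibble(
    transcript_id = ex_parent,
    start = exons$start - 1,   # to 0-based half-open
    end = exons$end,
    chrom = exons$seqid,
    strand = exons$strand
  )

  bad_coord <- ex$end <= ex$start
  if (any(bad_coord)) {
    warn(paste0("rejecting ", sum(bad_coord),
                " exon record(s) with start > end"))
    ex <- ex[!bad_coord, ]
  }
  orphan <- !(ex$transcript_id %in% tx_tbl$transcript_id)
  if (any(orphan)) {
    warn(paste0("rejecting ", sum(orphan),
                " exon record(s) without a parent transcript"))
    ex <- ex[!orphan, ]
  }

  out <- ex %>%
    inner_join(tx_tbl, by = "transcript_id") %>%
    mutate(strand = .data$tx_strand, chrom = .data$tx_chrom) %>%
    select("gene_id", "chrom", "strand", "transcript_id", "start", "end") %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start)

  strands <- out %>% distinct(.data$gene_id, .data$strand) %>% count(.data$gene_id)
  bad <- strands$gene_id[strands$n > 1]
  if (length(bad) > 0) {
    abort(paste0("gene(s) with transcripts on conflicting strands: ",
                 paste(bad, collapse = ", ")))
  }

  structure(out, class = c("gene_models", class(out)))
}

#' Write gene models back to GFF3
#'
#' Inverse of [parse_gff3()]: converts the internal 0-based half-open exon
#' intervals back to 1-based inclusive GFF3 records so that a parse/write
#' round trip reproduces the original coordinates exactly.
#'
#' @param genes A `gene_models` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in split(genes, genes$gene_id)) {
    gid <- g$gene_id[1]
    lines <- c(lines, paste(
      g$chrom[1], "lsvtools", "gene", min(g$start) + 1, max(g$end),
      ".", g$strand[1], ".", paste0("ID=", gid), sep = "\t"
    ))
    for (tx in split(g, g$transcript_id)) {
      tid <- tx$transcript_id[1]
      lines <- c(lines, paste(
        tx$chrom[1], "lsvtools", "mRNA", min(tx$start) + 1, max(tx$end),
        ".", tx$strand[1], ".", paste0("ID=", tid, ";Parent=", gid), sep = "\t"
      ))
      lines <- c(lines, paste(
        tx$chrom, "lsvtools", "exon", tx$start + 1, tx$end,
        ".", tx$strand, ".", paste0("Parent=", tid), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Implied splice junctions of annotated transcripts
#'
#' For every pair of consecutive exons within a transcript, emits the
#' junction `(donor_end, acceptor_start)` in genomic orientation.
#'
#' @param genes A `gene_models` tibble.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `donor_end`,
#'   `acceptor_start`, de-duplicated across transcripts.
#' @export
annotated_junctions <- function(genes) {
  genes %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(donor_end = .data$end, acceptor_start = lead(.data$start)) %>%
    filter(!is.na(.data$acceptor_start)) %>%
    ungroup() %>%
    distinct(.data$gene_id, .data$chrom, .data$strand,
             .data$donor_end, .data$acceptor_start)
}
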