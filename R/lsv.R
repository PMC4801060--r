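# Local splicing variations: a split in the splice graph where >= 2 edges
# leave (single-source) or enter (single-target) one reference exon.

.empty_catalog <- function() {
  res <- tibble(gene_id = character(), chrom = character(),
                strand = character(), lsv_id = character(),
                direction = character(), ref_start = double(),
                ref_end = double(), type_string = character(),
                n_junctions = integer(), n_exons = integer(),
                complex = logical(), intronic = logical(),
                has_denovo = logical(), junctions = list(),
                footprint = list())
  class(res) <- unique(c("lsv_catalog", class(res)))
  res
}

.closed_units <- function(graph) {
  graph$exons %>%
    filter(!.data$open_ended) %>%
    group_by(.data$unit) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              denovo = any(.data$origin != "annotated"), .groups = "drop") %>%
    arrange(.data$start)
}

# map junction endpoints to exon units; NA when the endpoint only touches
# an open-ended region (excluded from LSV enumeration)
.edge_table <- function(graph) {
  units <- .closed_units(graph)
  jx <- graph$junctions
  find_unit <- function(p, donor) {
    if (donor) {
      k <- which(p > units$start & p <= units$end)
    } else {
      k <- which(p >= units$start & p < units$end)
    }
    if (length(k) == 0) NA_integer_ else units$unit[k[1]]
  }
  jx$donor_unit <- vapply(jx$donor_end, find_unit, integer(1), donor = TRUE)
  jx$acceptor_unit <- vapply(jx$acceptor_start, find_unit, integer(1),
                             donor = FALSE)
  if (graph$strand == "+") {
    jx$source_unit <- jx$donor_unit; jx$target_unit <- jx$acceptor_unit
  } else {
    jx$source_unit <- jx$acceptor_unit; jx$target_unit <- jx$donor_unit
  }
  list(edges = jx, units = units)
}

.type_string <- function(edges, direction, strand, units) {
  # reference/partner splice-site ordinals in transcript orientation
  tx_order <- function(x) if (strand == "+") order(x) else order(-x)
  ref_is_donor <- (strand == "+") == (direction == "source")
  ref_coord <- if (ref_is_donor) edges$donor_end else edges$acceptor_start
  par_coord <- if (ref_is_donor) edges$acceptor_start else edges$donor_end
  par_unit <- if (direction == "source") edges$target_unit else edges$source_unit

  sgn <- if (strand == "+") 1 else -1
  ref_sites <- sort(unique(sgn * ref_coord[!edges$is_intron]))
  pu_pos <- units$start[match(par_unit, units$unit)]
  par_order <- sort(unique(sgn * pu_pos[!edges$is_intron]))

  tokens <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$is_intron[i]) { tokens[i] <- "i"; next }
    rs <- match(sgn * ref_coord[i], ref_sites)
    pe <- match(sgn * pu_pos[i], par_order)
    within <- !edges$is_intron & par_unit == par_unit[i]
    psites <- sort(unique(sgn * par_coord[within]))
    ps <- match(sgn * par_coord[i], psites)
    tokens[i] <- paste0(rs, "e", pe, ".", ps)
  }
  paste0(ifelse(direction == "source", "s", "t"), "|",
         paste(tokens, collapse = "|"))
}

#' Enumerate LSVs of a splice graph
#'
#' Every exon with two or more outgoing edges (in transcript orientation)
#' defines a single-source LSV; every exon with two or more incoming edges
#' a single-target LSV. Retention edges participate as junctions; edges
#' touching open-ended regions are excluded. Junctions within an LSV are
#' ordered by reference splice-site coordinate, then partner coordinate,
#' in transcript orientation, which makes the type string strand-invariant.
#'
#' @param graph A `splice_graph`.
#' @return An `lsv_catalog` tibble, one row per LSV, with nested
#'   `junctions` and exon `footprint` list-columns, the canonical
#'   `type_string`, and `complex` / `intronic` / `has_denovo` flags.
#' @export
enumerate_lsvs <- function(graph) {
  et <- .edge_table(graph)
  edges <- et$edges %>% filter(!is.na(.data$source_unit),
                               !is.na(.data$target_unit))
  out <- list()
  for (direction in c("source", "target")) {
    key <- if (direction == "source") edges$source_unit else edges$target_unit
    for (u in unique(key)) {
      sub <- edges[key == u, ]
      if (nrow(sub) < 2) next
      sgn <- if (graph$strand == "+") 1 else -1
      ref_is_donor <- (graph$strand == "+") == (direction == "source")
      ref_coord <- if (ref_is_donor) sub$donor_end else sub$acceptor_start
      par_coord <- if (ref_is_donor) sub$acceptor_start else sub$donor_end
      sub <- sub[order(sgn * ref_coord, sgn * par_coord), ]
      unit_row <- et$units[et$units$unit == u, ]
      partners <- unique(c(sub$source_unit, sub$target_unit))
      fp <- et$units %>% filter(.data$unit %in% partners) %>%
        select("start", "end")
      jx <- sub %>%
        mutate(junction_id = .junction_id(graph$chrom, .data$donor_end,
                                          .data$acceptor_start,
                                          .data$is_intron)) %>%
        select("junction_id", "donor_end", "acceptor_start", "origin",
               "is_intron")
      out[[length(out) + 1L]] <- tibble(
        gene_id = graph$gene_id, chrom = graph$chrom, strand = graph$strand,
        lsv_id = paste0(graph$gene_id, ":",
                        ifelse(direction == "source", "s", "t"), ":",
                        unit_row$start, "-", unit_row$end),
        direction = direction,
        ref_start = unit_row$start, ref_end = unit_row$end,
        type_string = .type_string(sub, direction, graph$strand, et$units),
        n_junctions = nrow(sub),
        n_exons = length(partners),
        complex = nrow(sub) > 2,
        intronic = any(sub$is_intron),
        has_denovo = any(sub$origin == "denovo") || unit_row$denovo,
        junctions = list(jx),
        footprint = list(fp)
      )
    }
  }
  res <- if (length(out) == 0) {
    .empty_catalog()
  } else {
    bind_rows(out) %>% arrange(.data$ref_start, .data$direction)
  }
  class(res) <- unique(c("lsv_catalog", class(res)))
  res
}

#' Canonical type string of one LSV
#'
#' Encodes the direction tag (`s`/`t`) and, per junction, the splice-site
#' ordinal in the reference exon and the partner exon index and splice-site
#' ordinal, all numbered in transcript orientation; a retention edge is
#' encoded `i`. Two LSVs with identical local graphs yield identical
#' strings on either strand.
#'
#' @param lsv One row of an `lsv_catalog`.
#' @param graph The `splice_graph` it came from.
#' @return The type string.
#' @export
classify_lsv <- function(lsv, graph) {
  et <- .edge_table(graph)
  jx <- lsv$junctions[[1]]
  edges <- et$edges %>%
    inner_join(jx %>% select("donor_end", "acceptor_start", "is_intron"),
               by = c("donor_end", "acceptor_start", "is_intron"))
  .type_string(edges, lsv$direction, graph$strand, et$units)
}

#' Remove redundant LSVs
#'
#' An LSV whose edge set is a strict subset of another retained LSV's edge
#' set is dropped; of two LSVs with identical edge sets, one is retained
#' (the single-source one, a deterministic tie-break). The SS/ST pair of a
#' cassette exon has different edge sets and is therefore kept intact.
#'
#' @param lsvs An `lsv_catalog` (one gene or many; comparison is per gene).
#' @return The filtered catalog.
#' @export
remove_redundant <- function(lsvs) {
  if (nrow(lsvs) == 0) return(lsvs)
  sig <- purrr::map(lsvs$junctions, ~ sort(.x$junction_id))
  keep <- logical(nrow(lsvs))
  ord <- order(-lsvs$n_junctions, lsvs$direction != "source", lsvs$lsv_id)
  for (gene in unique(lsvs$gene_id)) {
    idx <- ord[lsvs$gene_id[ord] == gene]
    kept <- list()
    for (i in idx) {
      subset_of_kept <- any(vapply(kept, function(s) all(sig[[i]] %in% s),
                                   logical(1)))
      if (!subset_of_kept) {
        keep[i] <- TRUE
        kept[[length(kept) + 1L]] <- sig[[i]]
      }
    }
  }
  lsvs[keep, ] %>% arrange(.data$gene_id, .data$ref_start, .data$direction)
}

.lsv_evidence <- function(lsvs, counts, pool = FALSE) {
  ev <- junction_evidence(counts, pool = pool, drop_stacks = TRUE)
  purrr::map(seq_len(nrow(lsvs)), function(i) {
    jx <- lsvs$junctions[[i]]
    ev %>% filter(.data$chrom == lsvs$chrom[i],
                  .data$strand == lsvs$strand[i]) %>%
      inner_join(jx %>% select("junction_id", "donor_end", "acceptor_start",
                               "is_intron"),
                 by = c("donor_end", "acceptor_start", "is_intron"))
  })
}

#' Keep LSVs that exist in the data
#'
#' The default rule: all the LSV's junctions are reliable (annotated, a
#' retention edge that passed the coverage filter, or de novo evidence
#' meeting `filter`), and at least one junction has at least
#' `filter$min_reads` reads from `filter$min_positions` positions.
#'
#' @param lsvs An `lsv_catalog`.
#' @param counts A `junction_counts` tibble.
#' @param filter A [reliability_filter()] (default 2 reads / 2 positions).
#' @param pool Pool evidence across experiments (default: any single
#'   experiment may satisfy the rule).
#' @return The filtered catalog.
#' @export
filter_existing <- function(lsvs, counts, filter = reliability_filter(),
                            pool = FALSE) {
  if (nrow(lsvs) == 0) return(lsvs)
  evs <- .lsv_evidence(lsvs, counts, pool = pool)
  keep <- vapply(seq_len(nrow(lsvs)), function(i) {
    jx <- lsvs$junctions[[i]]
    ev <- evs[[i]]
    ok_each <- vapply(seq_len(nrow(jx)), function(k) {
      if (jx$origin[k] == "annotated" || jx$is_intron[k]) return(TRUE)
      e <- ev %>% filter(.data$junction_id == jx$junction_id[k])
      any(e$reads >= filter$min_reads & e$positions >= filter$min_positions)
    }, logical(1))
    some_supported <- any(ev$reads >= filter$min_reads &
                            ev$positions >= filter$min_positions)
    all(ok_each) && some_supported
  }, logical(1))
  lsvs[keep, ]
}

#' Keep LSVs with enough coverage to quantify
#'
#' The default quantifiable rule is at least 10 reads from at least 3
#' positions on at least one junction, counted after stack removal, in
#' every experiment being quantified (`require_all = TRUE`) or in any one.
#'
#' @param lsvs An `lsv_catalog`.
#' @param counts A `junction_counts` tibble (stack-flagged positions are
#'   ignored).
#' @param min_reads,min_positions Thresholds (defaults 10 and 3).
#' @param require_all Require the rule in every experiment present in
#'   `counts` (default) rather than in at least one.
#' @return The filtered catalog.
#' @export
filter_quantifiable <- function(lsvs, counts, min_reads = 10,
                                min_positions = 3, require_all = TRUE) {
  if (nrow(lsvs) == 0) return(lsvs)
  experiments <- unique(counts$experiment)
  evs <- .lsv_evidence(lsvs, counts, pool = FALSE)
  keep <- vapply(seq_along(evs), function(i) {
    ev <- evs[[i]] %>% filter(.data$reads >= min_reads,
                              .data$positions >= min_positions)
    if (require_all) {
      all(experiments %in% ev$experiment)
    } else {
      nrow(ev) > 0
    }
  }, logical(1))
  lsvs[keep, ]
}

#' Detect LSVs across a set of splice graphs
#'
#' Convenience pipeline: [enumerate_lsvs()] per gene, [remove_redundant()],
#' then [filter_existing()] when evidence is supplied.
#'
#' @param graphs A `splice_graph` or list of them.
#' @param counts Optional `junction_counts`.
#' @param filter A [reliability_filter()].
#' @return An `lsv_catalog` tibble.
#' @export
detect_lsvs <- function(graphs, counts = NULL,
                        filter = reliability_filter()) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) return(.empty_catalog())
  cat_all <- purrr::map(graphs, enumerate_lsvs) %>%
    bind_rows() %>%
    remove_redundant()
  if (!is.null(counts)) {
    cat_all <- filter_existing(cat_all, counts, filter = filter)
  }
  class(cat_all) <- unique(c("lsv_catalog", class(cat_all)))
  cat_all
}

#' Write an LSV catalog as TSV
#'
#' One row per junction with its LSV id, type string, flags and 1-based
#' inclusive genomic coordinates (report convention; internal coordinates
#' are 0-based half-open).
#'
#' @param lsvs An `lsv_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lsv_catalog <- function(lsvs, path) {
  if (nrow(lsvs) == 0) {
    hdr <- c("gene_id", "chrom", "strand", "lsv_id", "direction",
             "type_string", "n_junctions", "complex", "intronic",
             "has_denovo", "junction_id", "origin", "is_intron",
             "junction_start", "junction_end")
    writeLines(paste(hdr, collapse = "\t"), path)
    return(invisible(path))
  }
  flat <- lsvs %>%
    select("gene_id", "chrom", "strand", "lsv_id", "direction",
           "type_string", "n_junctions", "complex", "intronic",
           "has_denovo", "junctions") %>%
    tidyr::unnest("junctions") %>%
    mutate(junction_start = .data$donor_end,          # 1-based last exonic base
           junction_end = .data$acceptor_start + 1) %>%  # 1-based first exonic base
    select(-"donor_end", -"acceptor_start")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Export LSV regions as GFF3
#'
#' Each LSV becomes a `gene` record spanning its exon footprint with the
#' footprint exons as children, the form downstream event-centric tools
#' consume.
#'
#' @param lsvs An `lsv_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lsv_gff3 <- function(lsvs, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(lsvs))) {
    fp <- lsvs$footprint[[i]]
    id <- lsvs$lsv_id[i]
    lines <- c(lines,
      paste(lsvs$chrom[i], "lsvtools", "gene", min(fp$start) + 1, max(fp$end),
            ".", lsvs$strand[i], ".", paste0("ID=", id), sep = "\t"),
      paste(lsvs$chrom[i], "lsvtools", "mRNA", min(fp$start) + 1, max(fp$end),
            ".", lsvs$strand[i], ".",
            paste0("ID=", id, ".t;Parent=", id), sep = "\t"),
      paste(lsvs$chrom[i], "lsvtools", "exon", fp$start + 1,
            fp$end, ".", lsvs$strand[i], ".",
            paste0("Parent=", id, ".t"), sep = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
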