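# Static HTML reporting: splice-graph drawings and posterior violins
# rendered as inline SVG straight from the discretized masses.

.svg_header <- function(w, h) {
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
          w, h)
}

.origin_color <- function(origin) {
  ifelse(origin == "annotated", "#b03030", "#2f9e44")  # annotated red, de novo green
}

.svg_splice_graph <- function(graph, width = 800) {
  ex <- graph$exons %>% filter(!is.na(.data$start), !is.na(.data$end))
  if (nrow(ex) == 0) return("")
  lo <- min(ex$start); hi <- max(ex$end)
  sx <- function(p) 20 + (p - lo) / max(hi - lo, 1) * (width - 40)
  h <- 120; base <- 80
  parts <- c(.svg_header(width, h))
  for (i in seq_len(nrow(graph$exons))) {
    e <- graph$exons[i, ]
    if (is.na(e$start) || is.na(e$end)) next
    col <- if (e$origin == "annotated") "#888" else "#2f9e44"
    dash <- if (e$open_ended) ' stroke-dasharray="4,3"' else ""
    parts <- c(parts, sprintf(
      '<rect x="%.1f" y="%d" width="%.1f" height="24" fill="%s" stroke="#333"%s/>',
      sx(e$start), base, max(sx(e$end) - sx(e$start), 2), col, dash))
  }
  for (i in seq_len(nrow(graph$junctions))) {
    j <- graph$junctions[i, ]
    x1 <- sx(j$donor_end); x2 <- sx(j$acceptor_start)
    col <- .origin_color(j$origin)
    if (j$is_intron) {
      parts <- c(parts, sprintf(
        '<rect x="%.1f" y="%d" width="%.1f" height="8" fill="%s" opacity="0.5"/>',
        x1, base + 8, x2 - x1, col))
    } else {
      parts <- c(parts, sprintf(
        '<path d="M %.1f %d Q %.1f %d %.1f %d" stroke="%s" fill="none" stroke-width="1.5"/>',
        x1, base, (x1 + x2) / 2, base - 55, x2, base, col))
    }
  }
  paste(c(parts, "</svg>"), collapse = "\n")
}

.svg_violin <- function(mass, width = 46, height = 120, color = "#4263eb") {
  V <- length(mass)
  y <- height - (seq_len(V) - 0.5) / V * height
  half <- mass / max(mass, 1e-12) * (width / 2 - 2)
  xl <- width / 2 - half; xr <- width / 2 + half
  pts <- paste(c(sprintf("%.1f,%.1f", xl, y), sprintf("%.1f,%.1f", rev(xr), rev(y))),
               collapse = " ")
  paste0(.svg_header(width, height),
         sprintf('<polygon points="%s" fill="%s" opacity="0.8"/>', pts, color),
         "</svg>")
}

#' Write a static HTML report of splice graphs and LSV posteriors
#'
#' One self-contained page: per gene, the splice graph (annotated edges
#' red, de novo green, the usual convention), the LSV table grouped by
#' type (binary/complex, source/target, exonic/intronic), and per-LSV
#' violin glyphs of the discretized PSI or dPSI posteriors (drawn from
#' the mass vectors directly, no kernel smoothing). A posterior
#' referencing an LSV that is not in the catalog is an error.
#'
#' @param graphs A `splice_graph` or list of them.
#' @param lsvs An `lsv_catalog` (may be empty for graphs-only mode).
#' @param psi Optional `psi_fit`.
#' @param dpsi Optional `dpsi_fit`.
#' @param path Output HTML path.
#' @return `path`, invisibly.
#' @export
write_report <- function(graphs, lsvs = NULL, psi = NULL, dpsi = NULL,
                         path = "lsv_report.html") {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  names(graphs) <- vapply(graphs, function(g) g$gene_id, character(1))
  for (fit in list(psi, dpsi)) {
    if (!is.null(fit) && !is.null(lsvs)) {
      unknown <- setdiff(unique(fit$lsv_id), lsvs$lsv_id)
      if (length(unknown) > 0) {
        abort(paste0("posterior references unknown lsv_id(s): ",
                     paste(head(unknown, 5), collapse = ", ")))
      }
    }
  }
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>LSV report</title>",
    "<style>body{font-family:sans-serif;margin:24px}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:3px 8px;font-size:13px}",
    "h2{border-bottom:2px solid #888}.violin{display:inline-block;margin:2px;text-align:center;font-size:11px}",
    "</style></head><body>",
    "<h1>Local splicing variations</h1>"
  )
  groups <- function(tbl) {
    paste0(ifelse(tbl$complex, "complex", "binary"), " / ",
           ifelse(tbl$direction == "source", "source", "target"), " / ",
           ifelse(tbl$intronic, "intronic", "exonic"))
  }
  for (g in graphs) {
    html <- c(html, sprintf("<h2>%s (%s%s)</h2>", g$gene_id, g$chrom, g$strand),
              .svg_splice_graph(g))
    if (is.null(lsvs)) next
    sub <- lsvs %>% filter(.data$gene_id == g$gene_id)
    if (nrow(sub) == 0) next
    sub$group <- groups(sub)
    for (grp in unique(sub$group)) {
      html <- c(html, sprintf("<h3>%s</h3>", grp), "<table>",
                "<tr><th>LSV</th><th>type</th><th>junctions</th><th>posterior</th></tr>")
      for (i in which(sub$group == grp)) {
        row <- sub[i, ]
        cells <- ""
        fit <- if (!is.null(dpsi)) dpsi else psi
        if (!is.null(fit)) {
          f <- fit %>% filter(.data$lsv_id == row$lsv_id)
          stat <- if (!is.null(dpsi)) f$dpsi else f$psi
          cells <- paste(vapply(seq_len(nrow(f)), function(k) {
            paste0("<span class='violin'>", .svg_violin(f$mass[[k]]),
                   "<br/>", sprintf("%.3f", stat[k]), "</span>")
          }, character(1)), collapse = "")
        }
        html <- c(html, sprintf(
          "<tr><td>%s</td><td><code>%s</code></td><td>%d</td><td>%s</td></tr>",
          row$lsv_id, row$type_string, row$n_junctions, cells))
      }
      html <- c(html, "</table>")
    }
  }
  html <- c(html, "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' PSI from RT-PCR band intensities
#'
#' For gel-based validation, the percent selected index of a junction is
#' the summed intensity of the isoform bands containing that junction
#' over the total intensity of all bands.
#'
#' @param intensities Named numeric vector of band intensities (one per
#'   isoform).
#' @param incidence Logical matrix or data frame, isoforms x junctions:
#'   `TRUE` where the isoform contains the junction. Row order must match
#'   `intensities`.
#' @return Named numeric vector of per-junction PSI.
#' @export
rtpcr_psi <- function(intensities, incidence) {
  inc <- as.matrix(incidence)
  stopifnot(nrow(inc) == length(intensities))
  total <- sum(intensities)
  if (total <= 0) abort("all band intensities are zero; PSI undefined")
  psi <- as.vector(crossprod(inc, intensities)) / total
  setNames(psi, colnames(inc))
}
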