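# Fixture builders shared across tests. Everything is constructed in
# code; no data files.

# a cassette-exon gene: three exons, inclusion and skipping transcripts
cassette_gene <- function(gene_id = "gA", chrom = "chr1", strand = "+",
                          offset = 0) {
  ex <- function(s, e) c(s + offset, e + offset)
  e1 <- ex(100, 200); e2 <- ex(500, 600); e3 <- ex(900, 1000)
  rows <- list(
    list(tx = "t1", ex = list(e1, e2, e3)),
    list(tx = "t2", ex = list(e1, e3))
  )
  g <- dplyr::bind_rows(lapply(rows, function(r) {
    dplyr::bind_rows(lapply(r$ex, function(e) tibble::tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      transcript_id = paste0(gene_id, ".", r$tx), start = e[1], end = e[2])))
  }))
  class(g) <- c("gene_models", class(g))
  g
}

# five-exon gene exercising redundancy removal: the ST-LSV into exon 2 is
# a strict subset of the complex SS-LSV from exon 1, and the SS-LSV from
# exon 4 equals the ST-LSV into exon 5 edge-for-edge
redundancy_gene <- function(gene_id = "gR", chrom = "chr1") {
  tx <- function(tid, exons) {
    dplyr::bind_rows(lapply(exons, function(e) tibble::tibble(
      gene_id = gene_id, chrom = chrom, strand = "+",
      transcript_id = paste0(gene_id, ".", tid), start = e[1], end = e[2])))
  }
  e1 <- c(100, 200); e1s <- c(100, 160); e2 <- c(500, 600)
  e3 <- c(900, 1000); e4 <- c(1300, 1400)
  e5 <- c(1700, 1800); e5b <- c(1740, 1800)
  g <- dplyr::bind_rows(
    tx("t1", list(e1, e2, e3, e4, e5)),
    tx("t2", list(e1s, e2, e4, e5b)),
    tx("t3", list(e1, e3, e4, e5))
  )
  class(g) <- c("gene_models", class(g))
  g
}

# uniform positional counts for one junction
junction_counts_row <- function(experiment, chrom, strand, donor, acceptor,
                                counts, is_intron = FALSE) {
  nz <- which(counts > 0)
  tibble::tibble(
    experiment = experiment, chrom = chrom, strand = strand,
    donor_end = donor, acceptor_start = acceptor, is_intron = is_intron,
    offset = nz - 1L, count = as.double(counts[nz])
  )
}

# counts giving `reads` total over `positions` distinct offsets
even_counts <- function(experiment, chrom, strand, donor, acceptor,
                        reads, positions) {
  base <- rep(floor(reads / positions), positions)
  base[seq_len(reads - sum(base))] <- base[seq_len(reads - sum(base))] + 1
  junction_counts_row(experiment, chrom, strand, donor, acceptor, base)
}

make_counts <- function(...) as_junction_counts(dplyr::bind_rows(...))

# fine-grid numeric-integration oracle for the dPSI posterior of one
# junction (M = 1, deterministic rates): integrates the joint posterior
# density over each coarse V-bin cell on a sub-refined grid and
# assembles the dPSI masses exactly like the quantifier does
fine_dpsi_oracle <- function(mu_t, mu_tp, prior, j = 1, V = prior$V,
                             sub = 100) {
  G <- V * sub
  J <- length(mu_t)
  a0 <- prior$eta / J; b0 <- prior$eta * (J - 1) / J
  at <- a0 + mu_t[j]; bt <- b0 + sum(mu_t) - mu_t[j]
  ap <- a0 + mu_tp[j]; bp <- b0 + sum(mu_tp) - mu_tp[j]
  edges <- seq(0, 1, length.out = G + 1)
  pt <- diff(pbeta(edges, at, bt)); pp <- diff(pbeta(edges, ap, bp))
  cc <- (seq_len(G) - 0.5) / G
  mixd <- function(d) {
    x <- (d + 1) / 2
    out <- 0
    for (k in seq_len(nrow(prior$mixture))) {
      out <- out + prior$mixture$weight[k] *
        dbeta(x, prior$mixture$alpha[k], prior$mixture$beta[k])
    }
    out / 2
  }
  Icoarse <- rep(seq_len(V), each = sub)
  acc <- numeric(2 * V - 1)
  for (Jc in seq_len(V)) {
    cols <- ((Jc - 1) * sub + 1):(Jc * sub)
    blk <- outer(pt, pp[cols]) * mixd(outer(cc, cc[cols], "-"))
    cellmass <- rowSums(rowsum(blk, Icoarse))
    k <- seq_len(V) - Jc + V
    acc[k] <- acc[k] + cellmass
  }
  acc / sum(acc)
}

# fine-grid oracle for a marginal PSI posterior aggregated to V bins
fine_psi_oracle <- function(a, b, V = 40, sub = 100) {
  G <- V * sub
  f <- diff(pbeta(seq(0, 1, length.out = G + 1), a, b))
  rowsum(matrix(f, ncol = 1), rep(seq_len(V), each = sub))[, 1]
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
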