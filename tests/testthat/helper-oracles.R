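## Brute-force per-base oracles and exhaustive enumerations, independent of
## the package's interval machinery. All deliberately naive: explicit loops
## over bases and tables.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

element_labels_default <- c("CDS_Exons", "Introns",
                            "TSS_up_1kb", "TSS_up_5kb", "TSS_up_10kb",
                            "TES_down_1kb", "TES_down_5kb", "TES_down_10kb")

## Per-base class membership, one logical matrix [contig length x classes] per
## contig, computed by looping over genes and marking positions directly.
oracle_base_labels <- function(gm, contigs, sizes = c(1000, 5000, 10000)) {
  labels <- hmcpeaks:::element_class_labels(sizes)
  ctgs <- as.character(GenomeInfoDb::seqnames(contigs))
  lens <- GenomeInfoDb::seqlengths(contigs)
  genes <- gm$genes
  out <- list()
  for (ctg in ctgs) {
    L <- lens[[ctg]]
    m <- matrix(FALSE, nrow = L, ncol = length(labels),
                dimnames = list(NULL, labels))
    on_ctg <- which(as.character(seqnames(genes)) == ctg)
    exon <- logical(L); body <- logical(L)
    for (i in on_ctg) {
      body[start(genes)[i]:end(genes)[i]] <- TRUE
      ex <- gm$exons[[i]]
      for (j in seq_along(ex)) exon[start(ex)[j]:end(ex)[j]] <- TRUE
    }
    cand <- matrix(FALSE, nrow = L, ncol = 2L * length(sizes))
    for (i in on_ctg) {
      str <- as.character(strand(genes)[i])
      gs <- start(genes)[i]; ge <- end(genes)[i]
      for (k in seq_along(sizes)) {
        s <- sizes[k]
        up <- if (str == "+") c(gs - s, gs - 1L) else c(ge + 1L, ge + s)
        dn <- if (str == "+") c(ge + 1L, ge + s) else c(gs - s, gs - 1L)
        for (w in list(list(col = k, rng = up),
                       list(col = length(sizes) + k, rng = dn))) {
          lo <- max(1L, w$rng[1L]); hi <- min(L, w$rng[2L])
          if (lo <= hi) cand[lo:hi, w$col] <- TRUE
        }
      }
    }
    m[, 1L] <- exon
    m[, 2L] <- body & !exon
    for (k in seq_len(2L * length(sizes))) m[, 2L + k] <- cand[, k] & !body
    out[[ctg]] <- m
  }
  out
}

## Class intervals -> per-base logical vector for one contig
ranges_to_logical <- function(gr, ctg, L) {
  v <- logical(L)
  sel <- which(as.character(seqnames(gr)) == ctg)
  for (i in sel) {
    lo <- max(1L, start(gr)[i]); hi <- min(L, end(gr)[i])
    if (lo <= hi) v[lo:hi] <- TRUE
  }
  v
}

## Per-peak class set under the genic-priority rule, read off the per-base
## label matrices.
oracle_assign_peak <- function(labels_by_ctg, ctg, s, e) {
  m <- labels_by_ctg[[ctg]]
  hit <- colnames(m)[apply(m[s:e, , drop = FALSE], 2, any)]
  if ("CDS_Exons" %in% hit) return("CDS_Exons")
  if ("Introns" %in% hit) return("Introns")
  hit
}

## Two-sided Fisher exact p by exhaustive enumeration over all tables with
## the observed margins (hypergeometric probabilities from choose()).
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c; N <- n1 + n2
  xs <- max(0L, K - n2):min(K, n1)
  probs <- choose(n1, xs) * choose(n2, K - xs) / choose(N, K)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Tiny text-fixture writers -----------------------------------------------

write_lines_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## One-gene-per-call GFF3 builder; coordinates are 1-based closed as in GFF3.
gff3_fixture <- function(...) {
  write_lines_fixture(c("##gff-version 3", ...), ".gff3")
}

gff3_gene <- function(id, ctg, start, end, strand = "+",
                      transcripts = list(t1 = cbind(start, end))) {
  lines <- paste(ctg, "test", "gene", start, end, ".", strand, ".",
                 paste0("ID=", id), sep = "\t")
  for (tx in names(transcripts)) {
    txid <- paste0(id, ".", tx)
    ex <- transcripts[[tx]]
    lines <- c(lines,
               paste(ctg, "test", "mRNA", min(ex[, 1]), max(ex[, 2]), ".",
                     strand, ".", paste0("ID=", txid, ";Parent=", id),
                     sep = "\t"),
               vapply(seq_len(nrow(ex)), function(j)
                 paste(ctg, "test", "CDS", ex[j, 1], ex[j, 2], ".", strand,
                       "0", paste0("ID=", txid, ".c", j, ";Parent=", txid),
                       sep = "\t"), character(1)))
  }
  lines
}

## gene_models subset helper (used to plant high-PPKM genes)
subset_gene_models <- function(gm, idx) {
  gene_models(gm$genes[idx], gm$exons[idx])
}

## GRanges shorthand
gr <- function(ctg, start, end, strand = "*") {
  GRanges(ctg, IRanges(start, end), strand = strand)
}
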