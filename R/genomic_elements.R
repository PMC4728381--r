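## Element classes, in fixed report order. Flank labels depend on the window
## sizes; the defaults reproduce the standard 1/5/10-kb nesting.
element_class_labels <- function(sizes = c(1000, 5000, 10000)) {
  kb <- ifelse(sizes %% 1000 == 0, paste0(sizes / 1000, "kb"), paste0(sizes, "bp"))
  c("CDS_Exons", "Introns", paste0("TSS_up_", kb), paste0("TES_down_", kb))
}

#' Derive introns of each gene
#'
#' Introns are the maximal intervals of a gene body not covered by that gene's
#' own CDS exons. A single-exon gene (or one whose exons tile the body) has no
#' introns.
#'
#' @param gm A [gene_models] object.
#' @return `GRangesList` named by gene id; elements may be empty.
#' @examples
#' # a 300-bp gene with exons at both ends has one internal intron
#' @export
derive_introns <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  out <- lapply(seq_along(gm$genes), function(i)
    GenomicRanges::setdiff(gm$genes[i], gm$exons[[i]], ignore.strand = TRUE))
  names(out) <- mcols(gm$genes)$gene_id
  GRangesList(out)
}

#' Strand-aware flank windows around TSS or TES
#'
#' For each gene, windows of the requested sizes anchored immediately upstream
#' of the transcription start site (`side = "upstream"`) or downstream of the
#' transcription end site (`side = "downstream"`), reflected on the minus
#' strand and clipped to contig bounds. Window of size s contains the window of
#' every smaller size.
#'
#' @param genes `GRanges` of gene bodies (strand `+`/`-`).
#' @param sizes Positive window sizes in bp, ascending.
#' @param side `"upstream"` (TSS) or `"downstream"` (TES).
#' @param contigs `Seqinfo` catalog used for clipping; all gene contigs must
#'   resolve in it.
#' @return Named list (one element per size) of `GRanges` parallel to `genes`.
#' @export
flank_windows <- function(genes, sizes, side = c("upstream", "downstream"),
                          contigs) {
  side <- match.arg(side)
  stopifnot(is(genes, "GRanges"), all(sizes > 0), !is.unsorted(sizes))
  unknown <- setdiff(unique(as.character(seqnames(genes))), seqnames(contigs))
  if (length(unknown))
    stop("contig(s) not in catalog: ", paste(unknown, collapse = ", "))
  g <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
               strand = strand(genes), seqinfo = contigs)
  out <- lapply(sizes, function(s)
    trim(suppressWarnings(flank(g, width = s, start = (side == "upstream")))))
  names(out) <- as.character(sizes)
  out
}

#' Partition the genome into element classes
#'
#' Builds the element map used for peak-density profiling: merged CDS exons of
#' all genes; introns (gene-body bases not exonic in ANY gene); and nested,
#' cumulative TSS-upstream / TES-downstream windows with gene bodies removed.
#' Base ownership priority is CDS exons > introns > flank windows, so a base in
#' one gene's exon is never counted in another gene's flank. The two sides'
#' windows may overlap each other across neighbouring genes; such bases count
#' in both sides' totals (recorded in `meta`).
#'
#' @param gm A [gene_models] object.
#' @param contigs `Seqinfo` catalog (contig lengths).
#' @param sizes Flank window sizes in bp, ascending (default 1, 5, 10 kb).
#' @return An `element_map`: list with `ranges` (named list of reduced
#'   `GRanges` per class), `total_bases` (named numeric), `unassigned_bases`,
#'   `contigs`, `sizes`, and `meta` describing the ownership conventions.
#' @export
build_element_map <- function(gm, contigs, sizes = c(1000, 5000, 10000)) {
  stopifnot(inherits(gm, "gene_models"), is(contigs, "Seqinfo"),
            all(sizes > 0), !is.unsorted(sizes))
  labels <- element_class_labels(sizes)
  genes <- gm$genes
  unknown <- setdiff(unique(as.character(seqnames(genes))), seqnames(contigs))
  if (length(unknown))
    stop("contig(s) not in catalog: ", paste(unknown, collapse = ", "))
  exon_u <- reduce(unlist(gm$exons, use.names = FALSE), ignore.strand = TRUE)
  body_u <- reduce(granges_unstranded(genes), ignore.strand = TRUE)
  intron_u <- GenomicRanges::setdiff(body_u, exon_u, ignore.strand = TRUE)
  up <- flank_windows(genes, sizes, "upstream", contigs)
  dn <- flank_windows(genes, sizes, "downstream", contigs)
  flank_cls <- c(
    lapply(up, function(w)
      GenomicRanges::setdiff(reduce(granges_unstranded(w), ignore.strand = TRUE),
                             body_u, ignore.strand = TRUE)),
    lapply(dn, function(w)
      GenomicRanges::setdiff(reduce(granges_unstranded(w), ignore.strand = TRUE),
                             body_u, ignore.strand = TRUE)))
  ranges <- c(list(exon_u, intron_u), unname(flank_cls))
  names(ranges) <- labels
  total <- vapply(ranges, function(r) sum(as.numeric(width(r))), numeric(1))
  genome_bp <- sum(as.numeric(seqlengths(contigs)))
  assigned <- reduce(do.call(c, unname(ranges)), ignore.strand = TRUE)
  structure(list(
    ranges = ranges,
    total_bases = total,
    unassigned_bases = genome_bp - sum(as.numeric(width(assigned))),
    contigs = contigs,
    sizes = sizes,
    meta = list(priority = "CDS_Exons > Introns > flanks",
                flank_overlap_policy = "cross-gene TSS/TES windows overlap freely; shared bases count in both sides",
                nesting = "cumulative (each window contains the smaller ones)")),
    class = "element_map")
}

## strip strand + mcols so reduce/setdiff operate on naked intervals
granges_unstranded <- function(gr) {
  GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
}

#' @export
print.element_map <- function(x, ...) {
  cat("element_map over", length(seqnames(x$contigs)), "contig(s),",
      sum(as.numeric(seqlengths(x$contigs))), "bp\n")
  df <- data.frame(class = names(x$total_bases),
                   total_bases = unname(x$total_bases))
  print(df, row.names = FALSE)
  cat("unassigned (intergenic beyond largest window):", x$unassigned_bases, "bp\n")
  invisible(x)
}

#' Write per-class element intervals and totals
#'
#' Writes one BED file per element class plus a `total_bases.tsv` summary into
#' `dir`.
#'
#' @param emap An `element_map`.
#' @param dir Output directory (created if needed).
#' @return The summary TSV path, invisibly.
#' @export
write_element_map <- function(emap, dir) {
  stopifnot(inherits(emap, "element_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cls in names(emap$ranges))
    write_bed_peaks(emap$ranges[[cls]], file.path(dir, paste0(cls, ".bed")))
  out <- file.path(dir, "total_bases.tsv")
  utils::write.table(
    data.frame(class = names(emap$total_bases),
               total_bases = unname(emap$total_bases)),
    out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
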