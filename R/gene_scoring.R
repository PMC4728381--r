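#' High-coverage mask from per-base coverage
#'
#' Merges all coverage intervals whose depth is strictly greater than the
#' threshold into a disjoint, sorted mask. Peaks falling in such regions are
#' typically sequencing artefacts (collapsed repeats, contamination) and are
#' excluded before gene scoring.
#'
#' @param coverage `GRanges` with a `depth` metadata column (non-overlapping,
#'   as produced by [read_coverage_bedgraph()]).
#' @param threshold Depth above which bases are masked (default 50).
#' @return A `coverage_mask`: reduced `GRanges` with a `threshold` attribute.
#' @export
build_coverage_mask <- function(coverage, threshold = 50) {
  stopifnot(is(coverage, "GRanges"), !is.null(mcols(coverage)$depth))
  mask <- reduce(granges_unstranded(coverage[mcols(coverage)$depth > threshold]),
                 ignore.strand = TRUE)
  attr(mask, "threshold") <- threshold
  mask
}

#' Remove peaks overlapping a coverage mask
#'
#' Drops every peak overlapping a masked interval by at least 1 bp; input
#' order of the survivors is preserved.
#'
#' @param peaks `GRanges` of peaks.
#' @param mask `GRanges` mask from [build_coverage_mask()], or `NULL` to pass
#'   peaks through unchanged (with a warning, since unmasked peak sets may
#'   contain coverage artefacts).
#' @return Filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, mask) {
  stopifnot(is(peaks, "GRanges"))
  if (is.null(mask)) {
    warning("no coverage mask supplied; peaks passed through unfiltered")
    return(peaks)
  }
  peaks[!overlapsAny(granges_unstranded(peaks), mask)]
}

## peaks overlapping each gene body / each gene's exon set, counting a peak at
## most once per gene
.peak_counts <- function(gm, peaks, count_mode = c("body", "exon")) {
  count_mode <- match.arg(count_mode)
  q <- granges_unstranded(peaks)
  n <- integer(length(gm$genes))
  if (count_mode == "body") {
    n <- countOverlaps(granges_unstranded(gm$genes), q)
  } else {
    ex <- unlist(gm$exons, use.names = FALSE)
    gene_of <- rep(seq_along(gm$exons), lengths(gm$exons))
    hits <- findOverlaps(granges_unstranded(ex), q, ignore.strand = TRUE)
    pairs <- unique(cbind(gene_of[queryHits(hits)], subjectHits(hits)))
    tab <- table(factor(pairs[, 1L], levels = seq_along(gm$genes)))
    n <- as.integer(tab)
  }
  names(n) <- mcols(gm$genes)$gene_id
  n
}

#' PPKM: peaks per kilobase of coding sequence per million peaks
#'
#' The gene-level hydroxymethylation score: the number of peaks overlapping
#' the gene (>= 1 bp), normalised to the gene's protein-coding length and to
#' the total number of peaks,
#' `ppkm = n_gene / (coding_length/1000) / (total_peaks/1e6)`.
#' The analogue of RNA-seq RPKM for peak data: it makes exon
#' hydroxymethylation comparable between genes of different lengths.
#'
#' @param gm A [gene_models] object.
#' @param peaks `GRanges` of (coverage-filtered) peaks.
#' @param total_peaks Library size used for normalisation; defaults to
#'   `length(peaks)`. Must be positive.
#' @param count_mode Count peaks overlapping the gene `"body"` (default,
#'   introns included) or only its CDS `"exon"`s.
#' @return Named numeric vector of PPKM values.
#' @export
ppkm <- function(gm, peaks, total_peaks = length(peaks),
                 count_mode = c("body", "exon")) {
  stopifnot(inherits(gm, "gene_models"))
  if (total_peaks <= 0) stop("total_peaks must be positive")
  cl <- coding_length(gm)
  if (any(cl <= 0)) stop("coding length must be positive for all genes")
  n <- .peak_counts(gm, peaks, count_mode)
  n / (cl / 1000) / (total_peaks / 1e6)
}

#' Classify genes into void / high / neither PPKM groups
#'
#' The two functional-analysis groups: `void` genes have CDS exons completely
#' void of peaks (no peak overlaps any exon); `high` genes have a peak density
#' across the gene body of at least `threshold` PPKM (inclusive). A gene
#' qualifying for both — possible when intronic peaks drive the PPKM while the
#' exons stay clean — is labelled `high`, keeping the groups disjoint.
#' Everything else is `neither`.
#'
#' @inheritParams ppkm
#' @param threshold PPKM cut-off for the high group (default 10, inclusive).
#' @return Data frame with columns `gene_id`, `peak_count` (per
#'   `count_mode`), `coding_length`, `ppkm`, `group`
#'   (factor void/high/neither).
#' @export
classify_genes <- function(gm, peaks, threshold = 10,
                           total_peaks = length(peaks),
                           count_mode = c("body", "exon")) {
  count_mode <- match.arg(count_mode)
  pk <- ppkm(gm, peaks, total_peaks, count_mode)
  exon_n <- .peak_counts(gm, peaks, "exon")
  is_high <- pk >= threshold
  is_void <- exon_n == 0L & !is_high
  group <- factor(ifelse(is_high, "high", ifelse(is_void, "void", "neither")),
                  levels = c("void", "high", "neither"))
  data.frame(gene_id = names(pk),
             peak_count = unname(.peak_counts(gm, peaks, count_mode)),
             coding_length = unname(coding_length(gm)),
             ppkm = unname(pk),
             group = group,
             row.names = NULL)
}
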