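#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used in
#' the published density tables; R's `round()` rounds ties to even.
#'
#' @param x Numeric vector (non-negative in this package's uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assign peaks to element classes
#'
#' Implements the ownership rules of the density table: a peak overlapping any
#' CDS-exon base (>= 1 bp) belongs to `CDS_Exons` only; otherwise, overlapping
#' any intron base puts it in `Introns` only; otherwise it belongs to every
#' flank class it overlaps. Under cumulative nesting, membership in a 1-kb
#' window entails membership in the 5-kb and 10-kb windows of the same side;
#' `nested = "disjoint"` instead counts a flank peak only in the smallest
#' window of each side that contains it.
#'
#' @param peaks `GRanges` of peaks.
#' @param emap An `element_map` from [build_element_map()].
#' @param criterion Overlap criterion: `"any"` (>= 1 bp of the peak interval,
#'   default) or `"midpoint"` (the peak's midpoint base only).
#' @param nested `"cumulative"` (default) or `"disjoint"` flank counting.
#' @return Logical matrix `length(peaks)` x classes; a peak with an all-`FALSE`
#'   row is unassigned (intergenic beyond the largest window).
#' @export
assign_peaks <- function(peaks, emap, criterion = c("any", "midpoint"),
                         nested = c("cumulative", "disjoint")) {
  criterion <- match.arg(criterion)
  nested <- match.arg(nested)
  stopifnot(is(peaks, "GRanges"), inherits(emap, "element_map"))
  unknown <- setdiff(unique(as.character(seqnames(peaks))),
                     seqnames(emap$contigs))
  if (length(unknown))
    stop("peak contig(s) not in element map: ", paste(unknown, collapse = ", "))
  q <- granges_unstranded(peaks)
  if (criterion == "midpoint") {
    mid <- floor((start(q) + end(q)) / 2)
    q <- GRanges(seqnames(q), IRanges(mid, mid))
  }
  labels <- names(emap$ranges)
  m <- matrix(FALSE, nrow = length(q), ncol = length(labels),
              dimnames = list(NULL, labels))
  for (cls in labels) m[, cls] <- overlapsAny(q, emap$ranges[[cls]])
  genic <- m[, "CDS_Exons"] | m[, "Introns"]
  m[, "Introns"] <- m[, "Introns"] & !m[, "CDS_Exons"]
  flank_labels <- labels[-(1:2)]
  m[genic, flank_labels] <- FALSE
  if (nested == "disjoint") {
    for (side in c("TSS_up_", "TES_down_")) {
      cls <- grep(side, labels, fixed = TRUE, value = TRUE)
      if (length(cls) > 1L)
        for (k in rev(seq_along(cls))[-length(cls)])
          m[, cls[k]] <- m[, cls[k]] & !m[, cls[k - 1L]]
    }
  }
  m
}

#' Single-peak element assignment
#'
#' Convenience wrapper around [assign_peaks()] returning the set of class
#' labels for one peak.
#'
#' @inheritParams assign_peaks
#' @param peak A length-one `GRanges`.
#' @return Character vector of element class labels (possibly empty).
#' @export
assign_peak <- function(peak, emap, criterion = "any", nested = "cumulative") {
  stopifnot(length(peak) == 1L)
  m <- assign_peaks(peak, emap, criterion, nested)
  colnames(m)[m[1L, ]]
}

#' Peak-density table over element classes
#'
#' For each element class: the class's base total, the number of peaks assigned
#' to it, and the density in tags per kilobase (`tag_count / total_bases *
#' 1000`), reported rounded half-up to two decimals. Unassigned peaks are
#' counted separately.
#'
#' @inheritParams assign_peaks
#' @return A `density_table` data frame with columns `element`, `total_bases`,
#'   `tag_count`, `tags_per_kb`, and attributes `n_peaks_input`,
#'   `n_peaks_unassigned`, `tags_per_kb_raw` (unrounded densities).
#' @export
density_table <- function(peaks, emap, criterion = c("any", "midpoint"),
                          nested = c("cumulative", "disjoint")) {
  stopifnot(inherits(emap, "element_map"))
  if (all(emap$total_bases == 0)) stop("element map is empty")
  m <- assign_peaks(peaks, emap, criterion, nested)
  counts <- colSums(m)
  density_from_counts(counts, emap$total_bases,
                      n_input = length(peaks),
                      n_unassigned = sum(rowSums(m) == 0L))
}

#' Density table from pre-tabulated counts
#'
#' Computes tags-per-kilobase rows directly from (total bases, tag count)
#' pairs — e.g. a published element table — without interval data.
#'
#' @param tag_count Named (by element class) non-negative integer vector.
#' @param total_bases Base totals, parallel to `tag_count`.
#' @param n_input,n_unassigned Optional peak bookkeeping for the attributes.
#' @return A `density_table` data frame (see [density_table()]).
#' @export
density_from_counts <- function(tag_count, total_bases,
                                n_input = sum(tag_count), n_unassigned = NA) {
  stopifnot(length(tag_count) == length(total_bases),
            all(tag_count >= 0), all(total_bases > 0))
  raw <- tag_count / total_bases * 1000
  out <- data.frame(element = if (!is.null(names(tag_count))) names(tag_count)
                    else paste0("class", seq_along(tag_count)),
                    total_bases = unname(total_bases),
                    tag_count = unname(tag_count),
                    tags_per_kb = round_half_up(unname(raw), 2))
  attr(out, "tags_per_kb_raw") <- unname(raw)
  attr(out, "n_peaks_input") <- n_input
  attr(out, "n_peaks_unassigned") <- n_unassigned
  class(out) <- c("density_table", "data.frame")
  out
}

#' @export
print.density_table <- function(x, ...) {
  cat("Peak density over genomic elements (",
      attr(x, "n_peaks_input"), " peaks, ",
      attr(x, "n_peaks_unassigned"), " unassigned)\n", sep = "")
  print.data.frame(x, row.names = FALSE,
                   digits = NULL)
  invisible(x)
}

#' Exon-to-intron density ratio
#'
#' Ratio of the unrounded CDS-exon density to the unrounded intron density —
#' the statistic behind the "exons are about twice as hydroxymethylated as
#' introns" observation.
#'
#' @param x A `density_table` containing `CDS_Exons` and `Introns` rows.
#' @return A single number (0 when the exon count is 0).
#' @export
exon_intron_ratio <- function(x) {
  stopifnot(inherits(x, "density_table"))
  raw <- attr(x, "tags_per_kb_raw")
  ie <- match("CDS_Exons", x$element)
  ii <- match("Introns", x$element)
  if (is.na(ie) || is.na(ii)) stop("table lacks CDS_Exons/Introns rows")
  if (x$total_bases[ie] <= 0 || x$total_bases[ii] <= 0)
    stop("element base totals must be positive")
  if (raw[ii] == 0) stop("intron density is zero; ratio undefined")
  raw[ie] / raw[ii]
}

#' Published D. pulex element peak counts
#'
#' The per-element base totals and 5-hmC peak (tag) counts published for the
#' *Daphnia pulex* enrichment study, shipped so the density arithmetic can be
#' recomputed offline.
#'
#' @return Data frame with columns `element`, `total_bases`, `tag_count`,
#'   `tags_per_kb_published`.
#' @export
dpulex_element_counts <- function() {
  path <- system.file("extdata", "dpulex_element_counts.tsv",
                      package = "hmcpeaks", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric", "numeric", "numeric"))
}
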