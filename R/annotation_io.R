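#' @importFrom GenomicRanges GRanges GRangesList reduce setdiff flank trim
#'   resize countOverlaps findOverlaps start end width strand seqnames
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlengths seqlevels
#'   seqnames<-
#' @importFrom methods is as
NULL

#' Gene models: bodies plus ordered protein-coding exons
#'
#' Container for a set of gene models: one body interval per gene
#' (transcription start to transcription end) and its ordered, non-overlapping
#' protein-coding (CDS) exons. All coordinates are held as `GRanges`
#' (1-based, closed); file-format conventions are converted at read/write time.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` metadata column
#'   (unique, non-empty) and strand `+` or `-`.
#' @param exons `GRangesList` named by `gene_id`, parallel to `genes`; each
#'   element holds that gene's CDS exons, sorted by start, non-overlapping and
#'   contained in the gene body.
#' @return An object of class `gene_models` with elements `genes` and `exons`.
#' @examples
#' gr <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(101, 400),
#'                              strand = "+", gene_id = "g1")
#' ex <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("ctg1", IRanges::IRanges(c(101, 301), c(200, 400)),
#'                               strand = "+"))
#' gm <- gene_models(gr, ex)
#' coding_length(gm)
#' @export
gene_models <- function(genes, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"))
  ids <- mcols(genes)$gene_id
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("'genes' must carry a non-empty 'gene_id' metadata column")
  if (anyDuplicated(ids)) stop("duplicated gene_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(exons) != length(genes) || !identical(names(exons), as.character(ids)))
    stop("'exons' must be named by gene_id and parallel to 'genes'")
  for (i in seq_along(genes)) {
    g <- genes[i]; ex <- exons[[i]]; id <- ids[i]
    if (length(ex) == 0L)
      stop("gene ", id, ": no CDS exons (coding length must be > 0)")
    if (!all(as.character(seqnames(ex)) == as.character(seqnames(g))))
      stop("gene ", id, ": exon on a different contig than the gene body")
    if (any(start(ex) < start(g)) || any(end(ex) > end(g)))
      stop("gene ", id, ": CDS exon outside the gene span")
    if (is.unsorted(start(ex)))
      stop("gene ", id, ": exons not sorted by start")
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      stop("gene ", id, ": overlapping exons")
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes on",
      length(unique(as.character(seqnames(x$genes)))), "contig(s)\n")
  cat("  exons per gene:", paste(range(lengths(x$exons)), collapse = "-"),
      " total coding bp:", sum(sum(width(x$exons))), "\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Total protein-coding length per gene
#'
#' @param gm A [gene_models] object.
#' @return Named integer vector of summed CDS exon lengths (bp).
#' @export
coding_length <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  cl <- sum(width(gm$exons))
  names(cl) <- mcols(gm$genes)$gene_id
  cl
}

#' Read a contig catalog
#'
#' Reads a two-column TSV (contig id, length in bp) into a
#' [GenomeInfoDb::Seqinfo], the catalog used to clip flank windows to contig
#' bounds.
#'
#' @param path Path to a headerless two-column TSV.
#' @return A `Seqinfo` object.
#' @export
read_contigs <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "length"),
                         colClasses = c("character", "numeric"))
  if (any(!is.finite(d$length)) || any(d$length <= 0) ||
      any(d$length != round(d$length)))
    stop("contig lengths must be positive integers")
  if (anyDuplicated(d$contig)) stop("duplicated contig id in catalog")
  Seqinfo(seqnames = d$contig, seqlengths = as.integer(d$length))
}

#' Write a contig catalog
#' @param contigs A `Seqinfo` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  utils::write.table(
    data.frame(seqnames(contigs), seqlengths(contigs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Pre-scan a GFF3 file so syntax errors carry line numbers (rtracklayer's
## importer reports none).
.scan_gff_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (!grepl("^[0-9]+$", f[4L]) || !grepl("^[0-9]+$", f[5L]))
      stop("malformed GFF3 at line ", i, ": non-integer coordinate")
  }
  invisible(TRUE)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features linked by `Parent` attributes. When a gene
#' has several transcripts, the transcript with the longest total CDS is kept
#' (ties broken by transcript id, so the choice is deterministic). GFF3's
#' 1-based closed coordinates are used as-is internally.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff_genes <- function(path) {
  .scan_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  cds   <- gr[type == "CDS"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  if (length(mrnas) == 0L || length(cds) == 0L)
    stop("GFF3 must contain mRNA and CDS features with Parent links")
  gene_id <- as.character(genes$ID)
  tx_id <- as.character(mrnas$ID)
  tx_parent <- vapply(mrnas$Parent, `[`, character(1), 1L)
  cds_parent <- vapply(cds$Parent, `[`, character(1), 1L)
  if (anyNA(tx_parent) || anyNA(cds_parent))
    stop("mRNA/CDS features missing Parent attributes")
  cds_by_tx <- split(cds, factor(cds_parent, levels = tx_id))
  tx_len <- vapply(cds_by_tx, function(x) sum(width(x)), numeric(1))
  ## longest-CDS transcript per gene; ties -> lexicographically first tx id
  ord <- order(tx_parent, -tx_len, tx_id)
  keep_tx <- tx_id[ord][!duplicated(tx_parent[ord])]
  names(keep_tx) <- tx_parent[ord][!duplicated(tx_parent[ord])]
  missing_tx <- setdiff(gene_id, names(keep_tx))
  if (length(missing_tx))
    stop("gene(s) without mRNA children: ", paste(missing_tx, collapse = ", "))
  exons <- lapply(gene_id, function(g) {
    ex <- cds_by_tx[[keep_tx[[g]]]]
    if (length(ex) == 0L) stop("gene ", g, ": selected transcript has no CDS")
    ex <- ex[order(start(ex))]
    mcols(ex) <- NULL
    ex
  })
  names(exons) <- gene_id
  g <- genes
  mcols(g) <- NULL
  mcols(g)$gene_id <- gene_id
  gene_models(g, GRangesList(exons))
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene) with `Parent`
#' links, in gene order. The output is byte-deterministic for a given input, so
#' simulated annotations round-trip identically.
#'
#' @param gm A [gene_models] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  con <- file(path, "wb")  # "wb": identical bytes on every platform
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  g <- gm$genes
  ids <- mcols(g)$gene_id
  for (i in seq_along(g)) {
    ctg <- as.character(seqnames(g)[i]); str <- as.character(strand(g)[i])
    id <- ids[i]; tx <- paste0(id, ".t1")
    writeLines(c(
      paste(ctg, "hmcpeaks", "gene", start(g)[i], end(g)[i], ".", str, ".",
            paste0("ID=", id), sep = "\t"),
      paste(ctg, "hmcpeaks", "mRNA", start(g)[i], end(g)[i], ".", str, ".",
            paste0("ID=", tx, ";Parent=", id), sep = "\t")), con, sep = "\n")
    ex <- gm$exons[[i]]
    for (j in seq_along(ex))
      writeLines(paste(ctg, "hmcpeaks", "CDS", start(ex)[j], end(ex)[j], ".",
                       str, "0", paste0("ID=", tx, ".cds", j, ";Parent=", tx),
                       sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read enrichment peaks from BED
#'
#' BED3+ records become unstranded `GRanges`; BED's 0-based half-open
#' coordinates are converted on read (start + 1). Columns 4 and 5 are kept as
#' `name` and `score` when present.
#'
#' @param path Path to a BED3/BED6 file.
#' @return `GRanges` of peaks (possibly empty), with optional `name`/`score`.
#' @export
read_bed_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) return(GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 3L)) stop("BED record with fewer than 3 fields at line ",
                           which(ncol < 3L)[1L])
  ctg <- vapply(f, `[`, character(1), 1L)
  s_chr <- vapply(f, `[`, character(1), 2L)
  e_chr <- vapply(f, `[`, character(1), 3L)
  if (any(!grepl("^[0-9]+$", c(s_chr, e_chr))))
    stop("non-integer coordinate in BED file ", path)
  s <- as.numeric(s_chr); e <- as.numeric(e_chr)
  if (any(s >= e))
    stop("invalid BED interval (start >= end) at line ", which(s >= e)[1L])
  gr <- GRanges(ctg, IRanges(s + 1, e))
  if (all(ncol >= 4L)) mcols(gr)$name <- vapply(f, `[`, character(1), 4L)
  if (all(ncol >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 5L)))
    if (anyNA(sc) || any(sc < 0)) stop("BED score must be a non-negative number")
    mcols(gr)$score <- sc
  }
  gr
}

#' Write peaks to BED
#'
#' Writes BED6 when `name`/`score` columns are present, BED3 otherwise,
#' converting back to 0-based half-open coordinates.
#'
#' @param peaks `GRanges` of peaks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  stopifnot(is(peaks, "GRanges"))
  d <- data.frame(chrom = as.character(seqnames(peaks)),
                  start = start(peaks) - 1L, end = end(peaks))
  if (!is.null(mcols(peaks)$name) || !is.null(mcols(peaks)$score)) {
    d$name <- if (is.null(mcols(peaks)$name)) "." else mcols(peaks)$name
    d$score <- if (is.null(mcols(peaks)$score)) 0 else mcols(peaks)$score
    d$strand <- "."
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(d))
    writeLines(do.call(paste, c(unname(d), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read per-base coverage from bedGraph
#'
#' Four-column bedGraph records (0-based half-open) with a numeric depth.
#' Records on a contig must not overlap; adjacent records of equal depth are
#' merged when `normalize = TRUE`.
#'
#' @param path Path to a bedGraph file.
#' @param normalize Merge adjacent equal-depth records (default `TRUE`).
#' @return `GRanges` with a numeric `depth` metadata column.
#' @export
read_coverage_bedgraph <- function(path, normalize = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) {
    gr0 <- GRanges()
    mcols(gr0)$depth <- numeric(0)
    return(gr0)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 4L)) stop("bedGraph record without 4 fields at line ",
                                  which(lengths(f) != 4L)[1L])
  ctg <- vapply(f, `[`, character(1), 1L)
  s <- as.numeric(vapply(f, `[`, character(1), 2L))
  e <- as.numeric(vapply(f, `[`, character(1), 3L))
  depth <- as.numeric(vapply(f, `[`, character(1), 4L))
  if (anyNA(s) || anyNA(e) || any(s >= e)) stop("invalid bedGraph interval")
  if (anyNA(depth) || any(depth < 0)) stop("negative or missing bedGraph depth")
  gr <- GRanges(ctg, IRanges(s + 1, e), depth = depth)
  gr <- gr[base::order(as.character(seqnames(gr)), start(gr))]
  ## overlap check within each contig: starts must not precede previous end
  bycg <- split(gr, as.character(seqnames(gr)))
  for (x in bycg) {
    if (length(x) > 1L && any(start(x)[-1L] <= end(x)[-length(x)]))
      stop("overlapping bedGraph records on contig ",
           as.character(seqnames(x)[1L]))
  }
  if (normalize && length(gr) > 1L) {
    same <- as.character(seqnames(gr))[-1L] == as.character(seqnames(gr))[-length(gr)] &
      start(gr)[-1L] == end(gr)[-length(gr)] + 1L &
      mcols(gr)$depth[-1L] == mcols(gr)$depth[-length(gr)]
    run <- cumsum(c(TRUE, !same))
    gr <- unlist(GRangesList(lapply(split(gr, run), function(x)
      GRanges(seqnames(x)[1L], IRanges(min(start(x)), max(end(x))),
              depth = mcols(x)$depth[1L]))), use.names = FALSE)
  }
  gr
}

#' Read gene-to-GO annotations
#'
#' Reads a headerless two-column TSV (gene id, GO term id). Duplicate pairs are
#' collapsed; genes with no line are absent from the result.
#'
#' @param path Path to the TSV.
#' @return Named list: gene id -> character vector of unique GO ids.
#' @export
read_go_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 2L))
    stop("annotation line without 2 fields at line ", which(lengths(f) != 2L)[1L])
  gene <- vapply(f, `[`, character(1), 1L)
  term <- vapply(f, `[`, character(1), 2L)
  bad <- !grepl("^GO:[0-9]{7}$", term)
  if (any(bad)) stop("invalid GO id '", term[which(bad)[1L]], "' at line ",
                     which(bad)[1L])
  lapply(split(term, gene), function(x) sort(unique(x)))
}

#' Write gene-to-GO annotations
#' @param annotations Named list gene id -> character vector of GO ids.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_go_annotations <- function(annotations, path) {
  gene <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(gene))
    writeLines(paste(gene, term, sep = "\t"), con, sep = "\n")
  invisible(path)
}
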