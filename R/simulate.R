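## Seed hygiene: every generator runs under its own substream derived from
## (seed, stream tag) so adding one generator never perturbs another, and the
## caller's RNG state is untouched.
with_substream <- function(seed, stream, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  ## fold the stream tag into the seed, staying inside 32-bit integer range
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  set.seed((as.integer(seed) %% 1000003L) * 2039L + h %% 104729L,
           kind = "Mersenne-Twister")
  force(code)
}

r_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else range[1L] + floor(stats::runif(n) * (range[2L] - range[1L] + 1))
}

#' Simulate a multi-contig annotated genome
#'
#' Places non-overlapping multi-exon genes along each contig, alternating
#' random intergenic gaps with gene bodies built from exon/intron runs. The
#' defaults mirror a compact invertebrate gene architecture: 4-11 exons per
#' gene of 80-400 bp with 60-400 bp introns. Deterministic given `seed`.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (bp).
#' @param n_genes Total genes to place (distributed round-robin over contigs).
#' @param exon_count_range,exon_length_range,intron_length_range
#'   Inclusive integer ranges for gene architecture.
#' @param intergenic_gap_range Inclusive range of gaps before each gene (bp).
#' @param seed Integer seed; same seed, same genome, byte-identical GFF3.
#' @return List with `genes` (a [gene_models]) and `contigs` (`Seqinfo`).
#' @export
simulate_genome <- function(n_contigs = 3, contig_length = 100000,
                            n_genes = 20,
                            exon_count_range = c(4, 11),
                            exon_length_range = c(80, 400),
                            intron_length_range = c(60, 400),
                            intergenic_gap_range = c(1000, 4000),
                            seed = 1) {
  stopifnot(n_contigs >= 1, contig_length > 0, n_genes >= 1,
            exon_count_range[1L] >= 1)
  with_substream(seed, "genome", {
    ctg_names <- sprintf("ctg%02d", seq_len(n_contigs))
    contigs <- Seqinfo(ctg_names, rep(as.integer(contig_length), n_contigs))
    per_ctg <- rep(seq_len(n_contigs), length.out = n_genes)
    gene_rows <- list(); exon_sets <- list(); k <- 0L
    for (ci in seq_len(n_contigs)) {
      pos <- 1L
      for (gi in which(per_ctg == ci)) {
        gap <- r_int(1L, intergenic_gap_range)
        n_ex <- r_int(1L, exon_count_range)
        ex_len <- r_int(n_ex, exon_length_range)
        in_len <- if (n_ex > 1L) r_int(n_ex - 1L, intron_length_range) else integer(0)
        body_len <- sum(ex_len) + sum(in_len)
        gstart <- pos + gap
        gend <- gstart + body_len - 1L
        if (gend > contig_length)
          stop("genes cannot fit on contig ", ctg_names[ci],
               ": reduce n_genes or gene/gap sizes, or lengthen contigs")
        ex_start <- gstart + cumsum(c(0L, ex_len[-n_ex] + in_len))
        ex_end <- ex_start + ex_len - 1L
        k <- k + 1L
        id <- sprintf("gene%04d", k)
        strand <- if (stats::runif(1L) < 0.5) "+" else "-"
        gene_rows[[k]] <- data.frame(ctg = ctg_names[ci], start = gstart,
                                     end = gend, strand = strand, id = id)
        exon_sets[[id]] <- GRanges(ctg_names[ci], IRanges(ex_start, ex_end),
                                   strand = strand)
        pos <- gend + 1L
      }
    }
    gdf <- do.call(rbind, gene_rows)
    genes <- GRanges(gdf$ctg, IRanges(gdf$start, gdf$end), strand = gdf$strand)
    mcols(genes)$gene_id <- gdf$id
    list(genes = gene_models(genes, GRangesList(exon_sets)), contigs = contigs)
  })
}

## Disjoint placement territories derived from an element map: the two genic
## classes, flank annuli (both sides pooled per size ring), and the intergenic
## remainder. Placement territories are disjoint so per-class per-kb
## intensities are unambiguous.
placement_territories <- function(emap) {
  r <- emap$ranges
  labels <- names(r)
  flank_labels <- labels[-(1:2)]
  sizes <- emap$sizes
  rings <- list()
  prev <- NULL
  for (i in seq_along(sizes)) {
    ring <- reduce(c(r[[2L + i]], r[[2L + length(sizes) + i]]),
                   ignore.strand = TRUE)
    if (!is.null(prev)) ring <- GenomicRanges::setdiff(ring, prev,
                                                       ignore.strand = TRUE)
    rings[[i]] <- ring
    prev <- reduce(c(r[[2L + i]], r[[2L + length(sizes) + i]]),
                   ignore.strand = TRUE)
  }
  all_assigned <- reduce(do.call(c, unname(r)), ignore.strand = TRUE)
  genome <- GRanges(seqnames(emap$contigs),
                    IRanges(1L, seqlengths(emap$contigs)))
  intergenic <- GenomicRanges::setdiff(genome, all_assigned,
                                       ignore.strand = TRUE)
  terr <- c(list(exon = r$CDS_Exons, intron = r$Introns), rings,
            list(intergenic = intergenic))
  names(terr) <- c("exon", "intron",
                   paste0("flank_", ifelse(sizes %% 1000 == 0,
                                           paste0(sizes / 1000, "kb"),
                                           paste0(sizes, "bp"))),
                   "intergenic")
  terr
}

#' Simulate enrichment peaks with per-element-class intensities
#'
#' Draws peaks class-wise over disjoint placement territories (CDS exons,
#' introns, flank rings by size, intergenic) with homogeneous per-kilobase
#' intensities, each peak placed entirely inside one territory interval so the
#' generating class is recovered exactly by peak assignment. With `n_peaks`
#' set, peak numbers per class are multinomial with weights
#' intensity x class bases; otherwise they are Poisson with mean
#' `intensity * bases / 1000`. The default intensities emulate the published
#' density profile: exonic rate about twice the intronic rate, decaying flank
#' and intergenic rates.
#'
#' @param genome A list with `genes` and `contigs` as from
#'   [simulate_genome()].
#' @param intensity Named per-kb intensities; names `exon`, `intron`,
#'   `flank_1kb`, `flank_5kb`, `flank_10kb`, `intergenic` (flank names follow
#'   `sizes`).
#' @param n_peaks Total peak count (multinomial allocation), or `NULL` for
#'   Poisson counts at the given intensities.
#' @param peak_length_range Inclusive peak length range (bp).
#' @param sizes Flank window sizes passed to [build_element_map()].
#' @param seed Integer seed.
#' @return `GRanges` of peaks with a `class` metadata column recording the
#'   generating territory.
#' @export
simulate_peaks <- function(genome,
                           intensity = c(exon = 0.61, intron = 0.27,
                                         flank_1kb = 0.08, flank_5kb = 0.07,
                                         flank_10kb = 0.05, intergenic = 0.02),
                           n_peaks = NULL,
                           peak_length_range = c(20, 60),
                           sizes = c(1000, 5000, 10000),
                           seed = 1) {
  stopifnot(all(intensity >= 0))
  emap <- build_element_map(genome$genes, genome$contigs, sizes)
  terr <- placement_territories(emap)
  miss <- setdiff(names(terr), names(intensity))
  if (length(miss))
    stop("intensity missing class(es): ", paste(miss, collapse = ", "))
  with_substream(seed, "peaks", {
    bases <- vapply(terr, function(r) sum(as.numeric(width(r))), numeric(1))
    w <- intensity[names(terr)] * bases / 1000
    if (is.null(n_peaks)) {
      n_cls <- stats::rpois(length(w), w)
    } else {
      if (sum(w) == 0) stop("all class intensities are zero but n_peaks > 0")
      n_cls <- as.integer(stats::rmultinom(1L, n_peaks, w / sum(w)))
    }
    names(n_cls) <- names(terr)
    out <- list()
    for (cls in names(terr)) {
      n <- n_cls[[cls]]
      if (n == 0L) next
      iv <- terr[[cls]]
      if (length(iv) == 0L) {
        if (intensity[[cls]] > 0)
          warning("class ", cls, " has no territory; its peaks are dropped")
        next
      }
      len <- r_int(n, peak_length_range)
      ## weight intervals by usable starts so placement is uniform over bases,
      ## shrinking a peak to its interval when the interval is shorter
      ividx <- sample.int(length(iv), n, replace = TRUE,
                          prob = as.numeric(width(iv)))
      len <- pmin(len, width(iv)[ividx])
      off <- floor(stats::runif(n) * (width(iv)[ividx] - len + 1))
      s <- start(iv)[ividx] + off
      pk <- GRanges(seqnames(iv)[ividx], IRanges(s, s + len - 1L))
      mcols(pk)$class <- cls
      out[[cls]] <- pk
    }
    if (length(out) == 0L) {
      pk0 <- GRanges()
      mcols(pk0)$class <- character(0)
      return(pk0)
    }
    pk <- unlist(GRangesList(out), use.names = FALSE)
    ord <- base::order(as.character(seqnames(pk)), start(pk), end(pk))
    pk <- pk[ord]
    mcols(pk)$name <- sprintf("peak%05d", seq_along(pk))
    pk
  })
}

#' Simulate gene-to-GO annotations with planted group effects
#'
#' Background terms are assigned to every gene independently of group at
#' `background_freq`; planted terms are assigned with separate Bernoulli
#' frequencies in the high and void groups, creating genuine frequency
#' differences for the comparison stage to detect.
#'
#' @param high,void Character vectors of gene ids (disjoint).
#' @param planted Named list `term -> c(freq_high, freq_void)`.
#' @param n_background Number of background terms.
#' @param background_freq Per-gene probability of each background term.
#' @param seed Integer seed.
#' @return Named list gene id -> character vector of GO ids (genes that drew
#'   no term are absent).
#' @export
simulate_go <- function(high, void, planted = list(),
                        n_background = 30, background_freq = 0.1, seed = 1) {
  stopifnot(!length(intersect(high, void)))
  freqs <- if (length(planted)) do.call(rbind, planted) else
    matrix(numeric(0), ncol = 2)
  stopifnot(all(freqs >= 0), all(freqs <= 1))
  with_substream(seed, "go", {
    genes <- c(high, void)
    in_high <- c(rep(TRUE, length(high)), rep(FALSE, length(void)))
    terms <- list()
    bg_ids <- sprintf("GO:%07d", 1000000L + seq_len(n_background))
    for (i in seq_len(n_background)) {
      hit <- stats::runif(length(genes)) < background_freq
      terms[[bg_ids[i]]] <- genes[hit]
    }
    pl_ids <- names(planted)
    for (i in seq_along(planted)) {
      p <- ifelse(in_high, planted[[i]][1L], planted[[i]][2L])
      hit <- stats::runif(length(genes)) < p
      terms[[pl_ids[i]]] <- genes[hit]
    }
    gene_col <- unlist(terms, use.names = FALSE)
    term_col <- rep(names(terms), lengths(terms))
    if (length(gene_col) == 0L) return(structure(list(), names = character(0)))
    lapply(split(term_col, gene_col), function(x) sort(unique(x)))
  })
}

#' Simulate a restriction-qPCR experiment with known truth
#'
#' Generates replicated digested/mock CT values under the assay model: mock CT
#' is Normal(ct0, sd); digested CT is the mock baseline delayed by
#' `-log(true_fraction) / log(1 + E)` cycles plus noise, so inverting with
#' `100/(1+E)^dCT` recovers `100 * true_fraction` in expectation. The
#' standard curve is generated noiseless from E.
#'
#' @param truth Data frame with columns `locus`, `assay`, `stage`,
#'   `true_fraction` (in (0, 1]).
#' @param efficiency Amplification efficiency fraction (shared across assays).
#' @param ct_noise_sd Gaussian CT noise, cycles.
#' @param n_replicates Biological replicates per cell (default 4).
#' @param ct0 Baseline mock CT.
#' @param seed Integer seed.
#' @return List with `ct` (long CT table) and `curves` (standard-curve points
#'   per assay, dilutions 1, 0.1, 0.01).
#' @export
simulate_qpcr <- function(truth, efficiency = 1.0, ct_noise_sd = 0.1,
                          n_replicates = 4, ct0 = 20, seed = 1) {
  stopifnot(all(truth$true_fraction > 0), all(truth$true_fraction <= 1),
            ct_noise_sd >= 0, efficiency > 0)
  with_substream(seed, "qpcr", {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      shift <- -log(truth$true_fraction[i]) / log(1 + efficiency)
      for (r in seq_len(n_replicates)) {
        ct_mock <- ct0 + stats::rnorm(1L, 0, ct_noise_sd)
        ct_dig <- ct0 + shift + stats::rnorm(1L, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = truth$locus[i], assay = truth$assay[i],
          stage = truth$stage[i], replicate = r,
          treatment = c("mock", "digested"), ct = c(ct_mock, ct_dig))
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    dil <- c(1, 0.1, 0.01)
    slope <- -1 / log10(1 + efficiency)
    curves <- do.call(rbind, lapply(unique(truth$assay), function(a)
      data.frame(assay = a, relative_input = dil,
                 ct = ct0 + slope * log10(dil))))
    list(ct = ct, curves = curves)
  })
}
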