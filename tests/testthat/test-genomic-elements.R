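make_gm <- function(body_start, body_end, exon_starts, exon_ends,
                    ctg = "ctg1", strand = "+", id = "g1") {
  g <- gr(ctg, body_start, body_end, strand)
  S4Vectors::mcols(g)$gene_id <- id
  ex <- GRangesList(setNames(list(gr(ctg, exon_starts, exon_ends, strand)), id))
  gene_models(g, ex)
}

test_that("introns are the exon complement within the gene body", {
  # 0-based exons (0,100),(200,300) in body (0,300) -> intron (100,200)
  gm <- make_gm(1, 300, c(1, 201), c(100, 300))
  intr <- derive_introns(gm)[[1]]
  expect_equal(start(intr), 101)
  expect_equal(end(intr), 200)

  # single exon spanning the body -> no introns
  gm1 <- make_gm(1, 300, 1, 300)
  expect_length(derive_introns(gm1)[[1]], 0)

  # 0-based exons (0,50),(60,70),(90,300) -> introns (50,60),(70,90)
  gm3 <- make_gm(1, 300, c(1, 61, 91), c(50, 70, 300))
  intr3 <- derive_introns(gm3)[[1]]
  expect_equal(start(intr3), c(51, 71))
  expect_equal(end(intr3), c(60, 90))
  # cross-checked per base: intron bases = body bases not in any exon
  base_in_exon <- logical(300)
  for (j in seq_along(gm3$exons[[1]]))
    base_in_exon[start(gm3$exons[[1]])[j]:end(gm3$exons[[1]])[j]] <- TRUE
  expect_equal(which(!base_in_exon), unlist(Map(seq, start(intr3), end(intr3))),
               ignore_attr = TRUE)
})

test_that("flank windows are strand-aware and clipped to contig bounds", {
  si <- GenomeInfoDb::Seqinfo("ctg1", 10000)
  # + strand body 0-based (5000,6000); upstream 1 kb -> 0-based (4000,5000)
  gp <- gr("ctg1", 5001, 6000, "+"); S4Vectors::mcols(gp)$gene_id <- "g1"
  up <- flank_windows(gp, 1000, "upstream", si)[["1000"]]
  expect_equal(c(start(up), end(up)), c(4001, 5000))

  # - strand: upstream reflects to 0-based (6000,7000)
  gm <- gr("ctg1", 5001, 6000, "-"); S4Vectors::mcols(gm)$gene_id <- "g1"
  upm <- flank_windows(gm, 1000, "upstream", si)[["1000"]]
  expect_equal(c(start(upm), end(upm)), c(6001, 7000))
  dnm <- flank_windows(gm, 1000, "downstream", si)[["1000"]]
  expect_equal(c(start(dnm), end(dnm)), c(4001, 5000))

  # gene near the contig start: upstream window clipped to 300 bp
  ge <- gr("ctg1", 301, 900, "+"); S4Vectors::mcols(ge)$gene_id <- "g1"
  upe <- flank_windows(ge, 1000, "upstream", si)[["1000"]]
  expect_equal(c(start(upe), end(upe)), c(1, 300))
  expect_equal(width(upe), 300)

  expect_error(flank_windows(gp, 1000, "upstream",
                             GenomeInfoDb::Seqinfo("other", 1000)),
               "not in catalog")
})

test_that("element map base totals are additive and deduplicate shared exon bases", {
  si <- GenomeInfoDb::Seqinfo("ctg1", 100000)
  # one gene: 600 exonic bp inside an 800-bp body -> 200 intronic bp
  gm <- make_gm(10001, 10800, c(10001, 10501), c(10300, 10800))
  em <- build_element_map(gm, si)
  expect_equal(unname(em$total_bases[c("CDS_Exons", "Introns")]), c(600, 200))

  # two genes with 0-based exons (100,200) and (150,250): union is 150 bp
  g2 <- gr("ctg1", c(101, 151), c(200, 250), "+")
  S4Vectors::mcols(g2)$gene_id <- c("a", "b")
  ex2 <- GRangesList(a = gr("ctg1", 101, 200, "+"), b = gr("ctg1", 151, 250, "+"))
  em2 <- build_element_map(gene_models(g2, ex2), si)
  expect_equal(unname(em2$total_bases["CDS_Exons"]), 150)
  # per-base union oracle
  v <- logical(300); v[101:200] <- TRUE; v[151:250] <- TRUE
  expect_equal(unname(em2$total_bases["CDS_Exons"]), sum(v))
})

test_that("an isolated mid-contig gene has unclipped nested flank totals", {
  si <- GenomeInfoDb::Seqinfo("ctg1", 100000)
  gm <- make_gm(40001, 41000, 40001, 41000)
  em <- build_element_map(gm, si)
  expect_equal(unname(em$total_bases[c("TSS_up_1kb", "TSS_up_5kb", "TSS_up_10kb")]),
               c(1000, 5000, 10000))
  expect_equal(unname(em$total_bases[c("TES_down_1kb", "TES_down_5kb",
                                       "TES_down_10kb")]),
               c(1000, 5000, 10000))
})

test_that("element maps match the brute-force per-base labeller on random genomes", {
  for (seed in c(3, 17, 42)) {
    g <- simulate_genome(n_contigs = 2, contig_length = 30000, n_genes = 6,
                         exon_count_range = c(2, 8),
                         exon_length_range = c(60, 250),
                         intron_length_range = c(40, 250),
                         intergenic_gap_range = c(200, 2500), seed = seed)
    em <- build_element_map(g$genes, g$contigs)
    oracle <- oracle_base_labels(g$genes, g$contigs)
    for (ctg in names(oracle)) {
      L <- GenomeInfoDb::seqlengths(g$contigs)[[ctg]]
      for (cls in names(em$ranges)) {
        expect_identical(ranges_to_logical(em$ranges[[cls]], ctg, L),
                         unname(oracle[[ctg]][, cls]),
                         label = paste("seed", seed, ctg, cls))
      }
    }
  }
})

test_that("nested window totals are monotone and stay within contigs", {
  for (seed in 1:5) {
    g <- simulate_genome(n_contigs = 1, contig_length = 60000, n_genes = 5,
                         seed = seed)
    em <- build_element_map(g$genes, g$contigs)
    tb <- em$total_bases
    expect_true(tb["TSS_up_1kb"] <= tb["TSS_up_5kb"])
    expect_true(tb["TSS_up_5kb"] <= tb["TSS_up_10kb"])
    expect_true(tb["TES_down_1kb"] <= tb["TES_down_5kb"])
    expect_true(tb["TES_down_5kb"] <= tb["TES_down_10kb"])
    for (cls in names(em$ranges)) {
      r <- em$ranges[[cls]]
      if (length(r)) {
        expect_true(all(start(r) >= 1))
        expect_true(all(end(r) <= GenomeInfoDb::seqlengths(g$contigs)[
          as.character(seqnames(r))]))
      }
    }
  }
})

test_that("element maps can be written out as BED plus a totals TSV", {
  g <- simulate_genome(n_contigs = 1, contig_length = 50000, n_genes = 4,
                       seed = 2)
  em <- build_element_map(g$genes, g$contigs)
  d <- tempfile()
  write_element_map(em, d)
  tb <- read.delim(file.path(d, "total_bases.tsv"))
  expect_equal(tb$total_bases, unname(em$total_bases))
  rt <- read_bed_peaks(file.path(d, "CDS_Exons.bed"))
  expect_equal(start(rt), start(em$ranges$CDS_Exons))
})
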