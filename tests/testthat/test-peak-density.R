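## one isolated gene: body 10001..11000, exons 10001..10300 and 10701..11000,
## intron 10301..10700, on a 100-kb contig with full flank clearance
iso_map <- function() {
  g <- gr("ctg1", 10001, 11000, "+")
  S4Vectors::mcols(g)$gene_id <- "g1"
  ex <- GRangesList(g1 = gr("ctg1", c(10001, 10701), c(10300, 11000), "+"))
  build_element_map(gene_models(g, ex), GenomeInfoDb::Seqinfo("ctg1", 100000))
}

test_that("peak assignment follows the genic-priority and nesting rules", {
  em <- iso_map()
  expect_equal(assign_peak(gr("ctg1", 10050, 10080), em), "CDS_Exons")
  # exon/intron junction peak: exon wins
  expect_equal(assign_peak(gr("ctg1", 10290, 10320), em), "CDS_Exons")
  expect_equal(assign_peak(gr("ctg1", 10400, 10430), em), "Introns")
  # 300 bp upstream of the TSS: member of all three nested upstream windows
  expect_equal(assign_peak(gr("ctg1", 9691, 9720), em),
               c("TSS_up_1kb", "TSS_up_5kb", "TSS_up_10kb"))
  # far intergenic: no class
  expect_equal(assign_peak(gr("ctg1", 60000, 60040), em), character(0))
  expect_error(assign_peaks(gr("chrX", 1, 10), em), "not in element map")
})

test_that("midpoint criterion reassigns junction peaks by their centre", {
  em <- iso_map()
  # overlaps the exon by 11 bp but its midpoint (10305) is intronic
  pk <- gr("ctg1", 10290, 10320)
  expect_equal(assign_peak(pk, em, criterion = "midpoint"), "Introns")
  expect_equal(assign_peak(pk, em, criterion = "any"), "CDS_Exons")
})

test_that("disjoint nesting counts each flank peak once per side", {
  em <- iso_map()
  pk <- gr("ctg1", 9691, 9720)  # inside the 1-kb upstream window
  expect_equal(assign_peak(pk, em, nested = "disjoint"), "TSS_up_1kb")
  pk5 <- gr("ctg1", 8000, 8030)  # between 1 and 5 kb upstream
  expect_equal(assign_peak(pk5, em, nested = "disjoint"), "TSS_up_5kb")
  expect_equal(assign_peak(pk5, em, nested = "cumulative"),
               c("TSS_up_5kb", "TSS_up_10kb"))
})

test_that("density rows reproduce published tags-per-kilobase arithmetic", {
  dt <- density_from_counts(c(CDS_Exons = 10651, Introns = 4652),
                            c(CDS_Exons = 17597397, Introns = 17376020))
  expect_equal(dt$tags_per_kb, c(0.61, 0.27))
})

test_that("zero peaks give all-zero density rows", {
  em <- iso_map()
  dt <- density_table(GRanges(), em)
  expect_equal(dt$tag_count, rep(0, 8))
  expect_equal(dt$tags_per_kb, rep(0, 8))
  expect_equal(attr(dt, "n_peaks_input"), 0L)
})

test_that("exon:intron ratio uses unrounded densities", {
  dt <- density_from_counts(c(CDS_Exons = 10651, Introns = 4652),
                            c(CDS_Exons = 17597397, Introns = 17376020))
  expect_equal(round(exon_intron_ratio(dt), 2), 2.26)

  eq <- density_from_counts(c(CDS_Exons = 10, Introns = 10),
                            c(CDS_Exons = 1000, Introns = 1000))
  expect_equal(exon_intron_ratio(eq), 1)

  z <- density_from_counts(c(CDS_Exons = 0, Introns = 10),
                           c(CDS_Exons = 1000, Introns = 1000))
  expect_equal(exon_intron_ratio(z), 0)

  zi <- density_from_counts(c(CDS_Exons = 10, Introns = 0),
                            c(CDS_Exons = 1000, Introns = 1000))
  expect_error(exon_intron_ratio(zi), "undefined")
})

test_that("reported densities round half-up at two decimals", {
  expect_equal(round_half_up(0.605, 2), 0.61)   # R's round() would give 0.6
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(c(0.2649, 0.265), 2), c(0.26, 0.27))
  # rounding is output-only: raw densities are preserved in the attribute
  dt <- density_from_counts(c(CDS_Exons = 1, Introns = 1),
                            c(CDS_Exons = 3000, Introns = 7000))
  expect_equal(attr(dt, "tags_per_kb_raw"), c(1/3, 1/7))
})

test_that("peak assignment matches the brute-force per-base oracle", {
  for (seed in c(5, 23)) {
    g <- simulate_genome(n_contigs = 2, contig_length = 30000, n_genes = 6,
                         exon_count_range = c(2, 8),
                         exon_length_range = c(60, 250),
                         intron_length_range = c(40, 250),
                         intergenic_gap_range = c(200, 2500), seed = seed)
    em <- build_element_map(g$genes, g$contigs)
    pk <- simulate_peaks(g, n_peaks = 80, seed = seed)
    labels <- oracle_base_labels(g$genes, g$contigs)
    m <- assign_peaks(pk, em)
    for (i in seq_along(pk)) {
      want <- oracle_assign_peak(labels, as.character(seqnames(pk)[i]),
                                 start(pk)[i], end(pk)[i])
      expect_identical(sort(colnames(m)[m[i, ]]), sort(want),
                       label = paste("seed", seed, "peak", i))
    }
  }
})

test_that("flank tag counts are monotone in window size and genic rows disjoint", {
  g <- simulate_genome(n_contigs = 3, contig_length = 50000, n_genes = 15,
                       seed = 9)
  em <- build_element_map(g$genes, g$contigs)
  pk <- simulate_peaks(g, n_peaks = 3000, seed = 9)
  m <- assign_peaks(pk, em)
  expect_false(any(m[, "CDS_Exons"] & m[, "Introns"]))
  dt <- density_table(pk, em)
  tc <- setNames(dt$tag_count, dt$element)
  expect_true(tc["TSS_up_1kb"] <= tc["TSS_up_5kb"])
  expect_true(tc["TSS_up_5kb"] <= tc["TSS_up_10kb"])
  expect_true(tc["TES_down_1kb"] <= tc["TES_down_5kb"])
  expect_true(tc["TES_down_5kb"] <= tc["TES_down_10kb"])
  # every peak is either in a class or counted unassigned
  expect_equal(sum(rowSums(m) > 0) + attr(dt, "n_peaks_unassigned"), length(pk))
  # disjoint flank counts per side sum to the cumulative largest window
  md <- assign_peaks(pk, em, nested = "disjoint")
  expect_equal(sum(md[, "TSS_up_1kb"] | md[, "TSS_up_5kb"] | md[, "TSS_up_10kb"]),
               unname(tc["TSS_up_10kb"]))
})
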