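test_that("SPINK1 anchors map as the reverse complement of the printed ranges", {
  gm <- spink1_gene_model()
  expect_equal(gm$cds_length, 240L)
  # 5'-most cDNA base takes the highest coordinate on the reverse strand
  expect_equal(c_to_genomic(gm, "c.1"), 147211140L)
  expect_equal(c_to_genomic(gm, "c.55"), 147211086L)
  expect_equal(genomic_to_c(gm, 147209162L), "c.87")
  expect_equal(genomic_to_c(gm, 147211140L), "c.1")
  # round trip over all 240 coding positions is the identity
  cpos <- sprintf("c.%d", 1:240)
  expect_equal(genomic_to_c(gm, c_to_genomic(gm, cpos)), cpos)
})

test_that("plus-strand mapping anchors c.1 at the first exon's genomic start", {
  gm <- toy_plus_model()
  expect_equal(c_to_genomic(gm, "c.1"), gm$exons$genomic_start[1])
  expect_equal(genomic_to_c(gm, 1107L), "c.7")
  # intronic position inside the single intron
  expect_equal(genomic_to_c(gm, 1007L), "c.6+1")
})

test_that("random models round-trip and preserve/reverse genomic order by strand", {
  set.seed(11)
  for (i in 1:8) {
    cds <- random_cds(sample(12:60, 1))
    gm <- random_model_for_cds(cds)
    cpos <- sprintf("c.%d", seq_len(gm$cds_length))
    g <- c_to_genomic(gm, cpos)
    expect_equal(genomic_to_c(gm, g), cpos)
    if (gm$strand == "+") expect_true(all(diff(g) > 0))
    else expect_true(all(diff(g) < 0))
  }
})

test_that("exon spans tile the CDS and bad models are rejected", {
  gm <- spink1_gene_model()
  covered <- unlist(Map(seq, gm$exons$cds_start, gm$exons$cds_end))
  expect_equal(sort(covered), 1:240)
  expect_equal(sum(gm$exons$cds_end - gm$exons$cds_start + 1L), gm$cds_length)
  # gap in cDNA tiling
  expect_error(gene_model("BAD", "chr1", "+",
                          data.frame(cds_start = c(1, 8), cds_end = c(6, 12),
                                     genomic_start = c(1, 100),
                                     genomic_end = c(6, 104)),
                          donors = 6, acceptors = 8),
               "contiguous")
  # overlapping genomic spans
  expect_error(gene_model("BAD", "chr1", "+",
                          data.frame(cds_start = c(1, 7), cds_end = c(6, 12),
                                     genomic_start = c(1, 4),
                                     genomic_end = c(6, 9)),
                          donors = 6, acceptors = 7),
               "disjoint")
  # donor not at an exon end
  expect_error(gene_model("BAD", "chr1", "+",
                          data.frame(cds_start = c(1, 7), cds_end = c(6, 12),
                                     genomic_start = c(1, 100),
                                     genomic_end = c(6, 105)),
                          donors = 5, acceptors = 7),
               "donor")
})

test_that("pre-mRNA shifts follow the 5'-positive convention and cross boundaries", {
  gm <- spink1_gene_model()
  expect_equal(shift_on_premrna(gm, "c.55", 49L), "c.6")
  expect_equal(shift_on_premrna(gm, "c.56", -31L), "c.87")
  expect_equal(shift_on_premrna(gm, "c.120", 0L), "c.120")
  # crossing into intron 1 from either side
  expect_equal(shift_on_premrna(gm, "c.55", -1L), "c.55+1")
  expect_equal(shift_on_premrna(gm, "c.56", 1L), "c.56-1")
  expect_equal(shift_on_premrna(gm, "c.55", -140L), "c.55+140")
  # escaping the model errors, naming the offender
  expect_error(shift_on_premrna(gm, "c.1", 1L), "escapes")
  expect_error(c_to_genomic(gm, "c.241"), "c\\.241")
  expect_error(c_to_genomic(gm, "c.0"), "outside")
})

test_that("position strings parse, format and round-trip", {
  for (s in c("c.55", "c.55+140", "c.88-3", "c.1")) {
    p <- parse_c_position(s)
    expect_equal(format_c_position(p$base, p$offset), s)
  }
  expect_equal(parse_c_position(55)$base, 55L)
  expect_error(parse_c_position("c.55+0"), "offset")
  expect_error(parse_c_position("g.100"), "parse")
})

test_that("documented splice sites answer by kind and exonic position", {
  gm <- spink1_gene_model()
  expect_true(annotated_site_at(gm, "c.55", "donor"))
  expect_false(annotated_site_at(gm, "c.8", "donor"))
  expect_true(annotated_site_at(gm, "c.88", "acceptor"))
  expect_false(annotated_site_at(gm, "c.88", "donor"))
  expect_false(annotated_site_at(gm, "c.55+1", "donor"))  # intronic never matches
})

test_that("gene-model files and BED exon lines round-trip", {
  gm <- spink1_gene_model()
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_gene_model(gm, tmp)
  gm2 <- read_gene_model(tmp)
  expect_equal(gm2$exons, gm$exons)
  expect_equal(gm2$donors, gm$donors)
  expect_equal(gm2$strand, gm$strand)

  bed <- withr::local_tempfile(fileext = ".bed")
  ex <- gm$exons
  writeLines(sprintf("%s\t%d\t%d\texon%d\t0\t%s", gm$chrom,
                     ex$genomic_start - 1L, ex$genomic_end, ex$index,
                     gm$strand), bed)
  gm3 <- read_exons_bed(bed, name = "SPINK1")
  expect_equal(gm3$exons, gm$exons)
  expect_equal(gm3$donors, gm$donors)
  expect_equal(gm3$acceptors, gm$acceptors)
})
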