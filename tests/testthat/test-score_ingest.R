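test_that("the packaged score table reproduces printed scores and offsets", {
  sc <- spink1_scores()
  expect_equal(nrow(sc), 67L)
  expect_equal(sum(sc$phase == "validation"), 5L)
  r <- sc[sc$hgvs_c == "c.86A>G", ]
  expect_equal(unlist(r[c("ag", "al", "dg", "dl")], use.names = FALSE),
               c(0.00, 0.84, 0.00, 0.67))
  expect_equal(r$al_pos, 30L)
  expect_equal(r$dl_pos, -1L)
  expect_true(is.na(r$ag_pos))
  r2 <- sc[sc$hgvs_c == "c.92A>G", ]
  expect_equal(r2$ag, 0.13)
  expect_equal(r2$ag_pos, -1L)
  # every score at or above the 0.10 reporting threshold carries an offset
  for (ch in c("ag", "al", "dg", "dl")) {
    has_off <- !is.na(sc[[paste0(ch, "_pos")]])
    expect_true(all(has_off[sc[[ch]] >= 0.10]))
  }
})

test_that("empty and malformed score tables are handled", {
  gm <- spink1_gene_model()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("hgvs_c\tag\tal\tdg\tdl", tmp)
  expect_warning(sc <- read_score_table(tmp, gm), "empty")
  expect_equal(nrow(sc), 0L)

  writeLines(c("hgvs_c\tag\tal\tdg\tdl", "c.5A>G\t0.1\t1.2\t0\t0"), tmp)
  expect_error(read_score_table(tmp, gm), "line 2")
  expect_warning(ok <- read_score_table(tmp, gm, strict = FALSE), "skipped")
  expect_equal(nrow(ok), 0L)

  writeLines(c("hgvs_c\tag\tal\tdg\tdl", "c.999A>G\t0\t0\t0\t0"), tmp)
  expect_error(read_score_table(tmp, gm), "c.999")
})

test_that("genomic-keyed rows orient to the sense strand of a minus-strand gene", {
  gm <- spink1_gene_model()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # c.86A>G on chr5: genomic T>C at the reverse-complemented position
  g <- c_to_genomic(gm, "c.86")
  writeLines(c("chrom\tpos\tref\talt\tag\tal\tdg\tdl\tal_pos\tdl_pos",
               sprintf("chr5\t%d\tT\tC\t0.00\t0.84\t0.00\t0.67\t30\t-1", g),
               "chr5\t147211200\tA\tG\t0\t0\t0\t0\t\t"), tmp)
  expect_warning(sc <- read_score_table(tmp, gm), "outside")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$hgvs_c, "c.86A>G")
  expect_equal(sc$al, 0.84)
})

test_that("offsets resolve to the predicted gained/lost sites on the pre-mRNA", {
  gm <- spink1_gene_model()
  sc <- resolve_sites(spink1_scores(gm), gm)
  expect_equal(sc$dl_site[sc$hgvs_c == "c.55G>A"], "c.55")
  expect_equal(sc$dg_site[sc$hgvs_c == "c.55G>A"], "c.6")
  expect_equal(sc$dl_site[sc$hgvs_c == "c.84A>G"], "c.87")
  expect_equal(sc$al_site[sc$hgvs_c == "c.65G>T"], "c.56")
  expect_true(is.na(sc$dl_site[sc$hgvs_c == "c.41T>C"]))  # no offset printed
})

test_that("the relevance filter masks losses at undocumented sites only", {
  gm <- spink1_gene_model()
  sc <- apply_relevance_filter(spink1_scores(gm), gm)
  # c.26T>G: DL 0.29 resolves to the c.7_8 pseudo-donor region -> masked
  r <- sc[sc$hgvs_c == "c.26T>G", ]
  expect_false(r$rel_dl)
  expect_equal(r$max_relevant, 0.03)
  # c.56G>T: AL at the c.56 acceptor and DL at the c.87 donor both relevant
  r2 <- sc[sc$hgvs_c == "c.56G>T", ]
  expect_true(r2$rel_al && r2$rel_dl)
  expect_equal(r2$max_relevant, 0.61)
  expect_equal(r2$driving, "al")
  # c.11C>G: DL resolves 44 nt downstream to the real c.55 donor -> relevant
  expect_true(sc$rel_dl[sc$hgvs_c == "c.11C>G"])
  # all-zero scores give max_relevant 0
  expect_equal(sc$max_relevant[sc$hgvs_c == "c.101A>G"], 0)
  # masking never raises a score above the raw maximum
  raw_max <- pmax(sc$ag, sc$al, sc$dg, sc$dl)
  expect_true(all(sc$max_relevant <= raw_max + 1e-12))
  unmasked <- sc$rel_ag & sc$rel_al & sc$rel_dg & sc$rel_dl
  expect_equal(sc$max_relevant[unmasked], raw_max[unmasked])
  # no loss score at a boundary variant is ever masked
  boundary <- sc$c_pos %in% c(55, 56, 87, 88, 194, 195)
  expect_true(all(sc$rel_al[boundary] & sc$rel_dl[boundary]))
})

test_that("gain channels are never masked; kind mismatches mask losses", {
  gm <- spink1_gene_model()
  sc <- apply_relevance_filter(spink1_scores(gm), gm)
  expect_true(all(sc$rel_ag & sc$rel_dg))
  # an AL resolving to a donor position is masked as a kind mismatch
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hgvs_c\tag\tal\tdg\tdl\tal_pos",
               "c.84A>G\t0\t0.49\t0\t0\t-3"), tmp)  # resolves to c.87 (donor)
  x <- apply_relevance_filter(read_score_table(tmp, gm), gm)
  expect_false(x$rel_al)
  expect_equal(x$max_relevant, 0)
})

test_that("score-version diffs flag decision changes at the cutoff", {
  gm <- spink1_gene_model()
  a <- apply_relevance_filter(spink1_scores(gm), gm)
  d0 <- diff_score_versions(a, a, cutoff = 0.20)
  expect_equal(attr(d0, "n_changed"), 0L)
  expect_true(all(abs(d0[paste0("d_", c("ag", "al", "dg", "dl"))]) == 0))

  b <- a
  i <- which(b$hgvs_c == "c.85G>T")  # 0.25 -> below cutoff
  b$al[i] <- 0.10
  b$max_relevant[i] <- 0.17
  d1 <- diff_score_versions(a, b, cutoff = 0.20)
  expect_equal(attr(d1, "n_changed"), 1L)
  expect_equal(d1$hgvs_c[d1$decision_changed], "c.85G>T")

  expect_warning(d2 <- diff_score_versions(a, b[-1, ], 0.2), "universes differ")
  expect_equal(nrow(d2), 66L)
})

test_that("SpliceAI VCF INFO strings parse into score rows", {
  info <- "SpliceAI=G|SPINK1|0.00|0.84|0.00|0.67|12|30|-14|-1"
  x <- parse_spliceai_info(info)
  expect_equal(x$al, 0.84)
  expect_equal(x$dl_pos, -1L)
  expect_equal(x$gene, "SPINK1")
  expect_error(parse_spliceai_info("SpliceAI=G|gene|0.1"), "malformed")
})
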