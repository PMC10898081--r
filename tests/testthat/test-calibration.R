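test_that("confusion counts behave at the extremes and on the fixture", {
  lab <- spink1_labeled()
  c0 <- confusion_at_cutoff(lab, 0)
  expect_equal(c0$sensitivity, 1)
  expect_equal(c0$specificity, 0)
  c30 <- confusion_at_cutoff(lab, 0.30)
  expect_equal(c30$sensitivity, 1)  # every altering variant scores >= 0.31
  expect_equal(c30$tp + c30$fn, 12L)
  expect_equal(c30$tn + c30$fp, 55L)
  expect_error(confusion_at_cutoff(lab[lab$altering, ], 0.2), "negative")
  expect_error(confusion_at_cutoff(lab[0, ], 0.2), "empty")
})

test_that("moving the cutoff 0.20 -> 0.30 trades no sensitivity for specificity", {
  lab <- spink1_labeled()
  a <- confusion_at_cutoff(lab, 0.20)
  b <- confusion_at_cutoff(lab, 0.30)
  expect_equal(b$sensitivity, a$sensitivity)
  expect_gt(b$specificity, a$specificity)
})

test_that("sensitivity falls and specificity rises monotonically over the sweep", {
  lab <- spink1_labeled()
  sw <- sweep_cutoffs(lab, grid = seq(0, 1, 0.05))
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  expect_equal(sw$tp + sw$fn, rep(12L, nrow(sw)))
  # the same exact property on a synthetic screen
  cfg <- synthetic_config(seed = 5)
  gs <- generate_gene_model(cfg)
  st <- generate_score_table(gs$model, gs$cds, cfg)
  fo <- generate_flgsa_outcomes(st$scores, st$truth, cfg)
  scf <- apply_relevance_filter(st$scores, gs$model)
  lab2 <- label_scored_variants(scf, data.frame(variant = fo$variant,
                                                class = fo$class,
                                                ratio = fo$ratio))
  sw2 <- sweep_cutoffs(lab2)
  expect_true(all(diff(sw2$sensitivity) <= 1e-12))
  expect_true(all(diff(sw2$specificity) >= -1e-12))
})

test_that("empirical bands mirror the outcome-vs-score scatter", {
  lab <- spink1_labeled()
  bands <- threshold_bands(lab)
  expect_equal(bands$lower, 0.31)          # smallest altering score
  expect_equal(bands$upper_any, 0.61)      # largest normal_only score
  expect_equal(bands$upper_complete, 0.92) # smallest aberrant_only score
  expect_true(bands$lower <= bands$upper_any)
  expect_true(bands$upper_any <= bands$upper_complete)
  # every fixture variant above 0.90 is aberrant_only, every one below 0.30
  # normal_only
  expect_true(all(lab$splice_class[lab$max_relevant > 0.90] == "aberrant_only"))
  expect_true(all(lab$splice_class[lab$max_relevant < 0.30] == "normal_only"))
})

test_that("the recommended cutoff maximizes Youden's J, smallest on ties", {
  lab <- spink1_labeled()
  sw <- sweep_cutoffs(lab)
  expect_equal(attr(sw, "recommended_cutoff"), 0.30)
  expect_equal(recommend_cutoff(sw), 0.30)
  # explicit tie: two grid points with identical J pick the smaller
  fake <- data.frame(cutoff = c(0.2, 0.3), sensitivity = c(1, 1),
                     specificity = c(0.9, 0.9))
  expect_equal(recommend_cutoff(fake), 0.2)
})

test_that("synthetic screens recover the latent threshold within one grid step", {
  grid <- seq(0, 1, 0.05)
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = seed, label_noise = 0.02)
    gs <- generate_gene_model(cfg)
    st <- generate_score_table(gs$model, gs$cds, cfg)
    fo <- generate_flgsa_outcomes(st$scores, st$truth, cfg)
    scf <- apply_relevance_filter(st$scores, gs$model)
    lab <- label_scored_variants(scf, data.frame(variant = fo$variant,
                                                 class = fo$class,
                                                 ratio = fo$ratio))
    expect_gte(sum(lab$altering), 1)
    rec <- attr(sweep_cutoffs(lab, grid), "recommended_cutoff")
    expect_lte(abs(rec - cfg$latent_threshold), 0.05 + 1e-9)
  }
})

test_that("extrapolation clears all 653 untested fixture variants with a basis", {
  gm <- spink1_gene_model()
  uni <- apply_relevance_filter(spink1_score_universe(gm), gm)
  lab <- spink1_labeled()
  calls <- extrapolate_untested(uni, lab, floor = 0.20)
  expect_equal(nrow(calls), 653L)
  expect_true(all(calls$call == "unlikely_altering"))
  expect_true(all(nchar(calls$basis) > 0))
  # the seven above-floor exon-1 donor-gain variants clear via comparators
  above <- calls[calls$max_relevant >= 0.20, ]
  expect_equal(nrow(above), 7L)
  expect_true(all(grepl("comparator", above$basis)))
})

test_that("pre-validation comparator logic reproduces the c.64/c.81 reasoning", {
  gm <- spink1_gene_model()
  uni <- apply_relevance_filter(spink1_score_universe(gm), gm)
  lab <- spink1_labeled()
  # before the validation arm, the five validation variants were untested
  pre <- lab[!lab$hgvs_c %in% c("c.29G>T", "c.37G>T", "c.64G>T", "c.81A>T",
                                "c.92A>G"), ]
  calls <- extrapolate_untested(uni, pre, floor = 0.20)
  c64 <- calls[calls$hgvs_c == "c.64G>T", ]
  expect_equal(c64$call, "unlikely_altering")
  expect_match(c64$basis, "c.85G>T", fixed = TRUE)
  c81 <- calls[calls$hgvs_c == "c.81A>T", ]
  expect_equal(c81$call, "unlikely_altering")
})

test_that("no variant outscoring every normal_only comparator is auto-cleared", {
  gm <- spink1_gene_model()
  uni <- apply_relevance_filter(spink1_score_universe(gm), gm)
  lab <- spink1_labeled()
  # plant a high score on an untested exon-3 variant: no assayed normal_only
  # comparator reaches 0.95, so it must not be auto-cleared
  uni2 <- uni
  i <- which(uni2$hgvs_c == "c.100A>G")
  uni2$al[i] <- 0.95; uni2$max_relevant[i] <- 0.95; uni2$driving[i] <- "al"
  calls <- extrapolate_untested(uni2, lab, floor = 0.20)
  expect_equal(calls$call[calls$hgvs_c == "c.100A>G"],
               "indeterminate_assay_recommended")
})

test_that("within-position trios rank DL scores and aberrant fractions concordantly", {
  gm <- spink1_gene_model()
  sc <- apply_relevance_filter(spink1_scores(gm), gm)
  conc <- ratio_score_concordance(spink1_labeled(), sc, channel = "dl")
  # pairs arise at c.55 (three mixed), c.56 and c.86 (two mixed each)
  expect_equal(sort(unique(conc$c_pos)), c(55L, 56L, 86L))
  expect_equal(nrow(conc), 5L)
  # the report surfaces ordering exceptions rather than hiding them: the two
  # near-identical c.55 ratios (1/9.03 vs 1/9.38) invert their DL order
  expect_equal(sum(conc$concordant), 4L)
  disc <- conc[!conc$concordant, ]
  expect_equal(disc$c_pos, 55L)
  # the c.56 and c.86 pairs order consistently
  expect_true(all(conc$concordant[conc$c_pos != 55L]))
})
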