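test_that("identical seeds emit byte-identical fixture sets", {
  cfg <- synthetic_config(seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_synthetic_fixtures(cfg, d1)
  p2 <- emit_synthetic_fixtures(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("generated gene models and CDSs satisfy the structural contract", {
  for (seed in c(1, 2, 3)) {
    cfg <- synthetic_config(seed = seed)
    gs <- generate_gene_model(cfg)
    expect_s3_class(gs$model, "gene_model")
    expect_equal(nchar(gs$cds), gs$model$cds_length)
    expect_equal(nchar(gs$cds) %% 3L, 0L)
    expect_equal(substr(gs$cds, 1, 3), "ATG")
    codons <- substring(gs$cds, seq(1, nchar(gs$cds), 3),
                        seq(3, nchar(gs$cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    # inherited coordinate invariant on the random strand
    cpos <- sprintf("c.%d", seq_len(gs$model$cds_length))
    expect_equal(genomic_to_c(gs$model, c_to_genomic(gs$model, cpos)), cpos)
  }
  # mirror of the four-exon study gene: lengths 55/32/107/46 give 240 nt
  cfg4 <- synthetic_config(seed = 4, n_exons = 4,
                           exon_length_range = c(55L, 55L))
  # exact lengths are drawn, so check the published-structure arithmetic
  expect_equal(sum(c(55L, 32L, 107L, 46L)), 240L)
})

test_that("emitted tables parse through the production readers without warnings", {
  cfg <- synthetic_config(seed = 23)
  dir <- withr::local_tempdir()
  paths <- emit_synthetic_fixtures(cfg, dir)
  expect_no_warning(model <- read_gene_model(paths[["model"]]))
  expect_no_warning(scores <- read_score_table(paths[["scores"]], model))
  expect_no_warning(outcomes <- load_outcome_fixture(paths[["outcomes"]]))
  expect_equal(nrow(scores), 3L * model$cds_length)
  expect_equal(nrow(outcomes), nrow(scores))
  expect_no_warning(enumerate_snvs(model))  # ref_cds embedded in the file
})

test_that("planted irrelevant losses are masked exactly; nothing else is", {
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = seed, fraction_irrelevant_losses = 0.05)
    gs <- generate_gene_model(cfg)
    st <- generate_score_table(gs$model, gs$cds, cfg)
    scf <- apply_relevance_filter(st$scores, gs$model)
    expect_identical(which(!scf$rel_dl), which(st$truth$planted_irrelevant))
    expect_true(all(scf$rel_al))
    expect_true(all(scf$rel_ag & scf$rel_dg))
  }
  # with no planted losses the filter masks nothing at all
  cfg0 <- synthetic_config(seed = 3, fraction_irrelevant_losses = 0)
  gs0 <- generate_gene_model(cfg0)
  st0 <- generate_score_table(gs0$model, gs0$cds, cfg0)
  scf0 <- apply_relevance_filter(st0$scores, gs0$model)
  expect_true(all(scf0$rel_al & scf0$rel_dl))
})

test_that("background scores stay below the triage cutoff off the boundaries", {
  cfg <- synthetic_config(seed = 6)
  gs <- generate_gene_model(cfg)
  st <- generate_score_table(gs$model, gs$cds, cfg)
  ex <- gs$model$exons
  boundary <- st$scores$c_pos %in% setdiff(c(ex$cds_start, ex$cds_end),
                                           c(1L, gs$model$cds_length))
  planted <- st$truth$planted_irrelevant
  bg <- st$scores[!boundary & !planted, c("ag", "al", "dg", "dl")]
  expect_true(all(as.matrix(bg) < 0.20))
})

test_that("noise-free outcomes are exactly threshold-determined", {
  cfg <- synthetic_config(seed = 12, label_noise = 0,
                          fraction_irrelevant_losses = 0)
  gs <- generate_gene_model(cfg)
  st <- generate_score_table(gs$model, gs$cds, cfg)
  fo <- generate_flgsa_outcomes(st$scores, st$truth, cfg, intensity_sd = 0)
  scf <- apply_relevance_filter(st$scores, gs$model)
  pos <- fo$class != "normal_only"
  expect_identical(pos, scf$max_relevant >= cfg$latent_threshold)
  # only high aberrant fractions classify as complete aberrance
  comp <- fo$class == "aberrant_only"
  expect_true(all(st$truth$aberrant_fraction[comp] > 0.9))
  # mixed ratios reconstruct roughly the latent aberrant fraction
  mixed <- which(fo$class == "mixed")
  frac <- fo$ratio[mixed] / (1 + fo$ratio[mixed])
  expect_lt(max(abs(frac - st$truth$aberrant_fraction[mixed])), 0.15)
})

test_that("sub-threshold label flips stay invisible in the emitted readout", {
  cfg <- synthetic_config(seed = 9)  # several flips land on near-zero scores
  gs <- generate_gene_model(cfg)
  st <- generate_score_table(gs$model, gs$cds, cfg)
  fo <- generate_flgsa_outcomes(st$scores, st$truth, cfg)
  scf <- apply_relevance_filter(st$scores, gs$model)
  invisible_flips <- st$truth$label & scf$max_relevant < 0.1
  expect_gt(sum(invisible_flips), 0)
  expect_true(all(fo$class[invisible_flips] == "normal_only"))
})
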