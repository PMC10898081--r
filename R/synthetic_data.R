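# Synthetic gene models, delta-score tables and assay outcomes with the
# statistical structure the analysis assumes: near-zero background scores
# away from exon boundaries, elevated loss scores at boundary-disrupting
# SNVs, optional planted physiologically-irrelevant losses, and assay labels
# generated from a latent score threshold with a monotone score-to-aberrant-
# fraction link. Every emitted table round-trips through the production
# readers, so the whole pipeline is testable without any download.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the empirical structure of a small multi-exon gene
#' saturation screen: most scores are (near) zero, the signal concentrates at
#' the three SNVs of each internal exon-boundary position, and occasional
#' high loss scores point at sites no documented isoform uses (exercising the
#' relevance filter).
#'
#' @param seed integer seed; one shared generator per run.
#' @param n_exons number of exons (>= 2).
#' @param exon_length_range nt bounds for exon lengths (each >= 3).
#' @param intron_length_range nt bounds for intron lengths.
#' @param background_score_scale scale of the near-zero background noise
#'   (half-normal, truncated below the 0.10 offset-reporting threshold;
#'   default 0.02).
#' @param boundary_effect range of the uniform distribution of elevated loss
#'   scores at boundary-disrupting SNVs (default `c(0.2, 0.95)`).
#' @param fraction_irrelevant_losses probability that a non-boundary SNV
#'   receives a high loss score resolving to a non-site (default 0.05).
#' @param latent_threshold true splice-altering cutoff used to generate
#'   labels (default 0.30).
#' @param label_noise label flip probability (default 0.02).
#' @param ratio_link monotone map from score to expected aberrant fraction;
#'   default logistic centred at the midpoint of `boundary_effect`.
#' @param faint_band_prob probability a negative variant shows a
#'   sub-threshold faint aberrant band (default 0.10).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_exons = 4L,
                             exon_length_range = c(30L, 110L),
                             intron_length_range = c(200L, 2000L),
                             background_score_scale = 0.02,
                             boundary_effect = c(0.2, 0.95),
                             fraction_irrelevant_losses = 0.05,
                             latent_threshold = 0.30,
                             label_noise = 0.02,
                             ratio_link = NULL,
                             faint_band_prob = 0.10) {
  if (n_exons < 2L) stop_pos("n_exons must be >= 2")
  if (exon_length_range[1] < 3L) stop_pos("exon lengths must be >= 3")
  probs <- c(fraction_irrelevant_losses, latent_threshold, label_noise,
             faint_band_prob)
  if (any(probs < 0 | probs > 1)) stop_pos("probabilities must lie in [0,1]")
  mid <- mean(boundary_effect)
  structure(list(
    seed = as.integer(seed), n_exons = as.integer(n_exons),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    background_score_scale = background_score_scale,
    boundary_effect = boundary_effect,
    fraction_irrelevant_losses = fraction_irrelevant_losses,
    latent_threshold = latent_threshold,
    label_noise = label_noise,
    ratio_link = ratio_link %||% function(s) stats::plogis(8 * (s - mid)),
    faint_band_prob = faint_band_prob
  ), class = "synthetic_config")
}

#' Generate a random gene model and CDS
#'
#' Random exon structure on a random strand with consistent genomic anchors;
#' the CDS begins with ATG, ends with a stop codon, and has no internal
#' stops. Total coding length is trimmed to a multiple of 3. The documented
#' splice-site whitelist is the model's own internal boundaries.
#'
#' @param cfg a [synthetic_config()]; `set.seed(cfg$seed)` is applied.
#' @return list with elements `model` (a [gene_model()]) and `cds`
#'   (character).
#' @export
generate_gene_model <- function(cfg) {
  set.seed(cfg$seed)
  r <- cfg$exon_length_range
  lens <- sample(r[1]:r[2], cfg$n_exons, replace = TRUE)
  excess <- sum(lens) %% 3L
  lens[cfg$n_exons] <- lens[cfg$n_exons] - excess
  L <- sum(lens)
  introns <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
                    cfg$n_exons - 1L, replace = TRUE)
  strand <- sample(c("+", "-"), 1L)
  cds_end <- cumsum(lens)
  cds_start <- cds_end - lens + 1L
  gene_start <- sample(1e6:2e6, 1L)
  if (strand == "+") {
    gstart <- gene_start + c(0L, cumsum(lens[-cfg$n_exons] + introns))
    gend <- gstart + lens - 1L
  } else {
    gend <- gene_start + sum(lens) + sum(introns) - 1L -
      c(0L, cumsum(lens[-cfg$n_exons] + introns))
    gstart <- gend - lens + 1L
  }
  model <- gene_model("SYNTH", "chrS", strand,
                      data.frame(cds_start = cds_start, cds_end = cds_end,
                                 genomic_start = gstart, genomic_end = gend),
                      donors = cds_end[-cfg$n_exons],
                      acceptors = cds_start[-1])

  n_codons <- L %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  body <- sample(sense[sense != "ATG"], n_codons - 2L, replace = TRUE)
  cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
  list(model = model, cds = cds)
}

#' Generate a synthetic delta-score table with ground truth
#'
#' Every coding SNV receives four scores. Background channels draw
#' half-normal noise (scale `background_score_scale`, truncated below the
#' 0.10 reporting threshold). The three SNVs at each internal boundary
#' position get an elevated relevant loss score — DL at exon ends, AL at
#' exon starts — drawn uniformly from `boundary_effect`, with an offset of 0
#' resolving to the true site. A `fraction_irrelevant_losses` share of
#' non-boundary SNVs gets a similarly elevated DL whose offset (0) resolves
#' to the variant's own, non-site, position — irrelevant by construction.
#' Offsets are emitted only for scores at or above 0.10.
#'
#' @param model a [gene_model()].
#' @param cds CDS sequence for enumeration.
#' @param cfg a [synthetic_config()].
#' @return list: `scores` (score data.frame as produced by
#'   [read_score_table()]) and `truth` (data.frame with `hgvs_c`,
#'   `true_max_relevant`, `planted_irrelevant`, `label`, `aberrant_fraction`).
#' @export
generate_score_table <- function(model, cds, cfg) {
  set.seed(cfg$seed + 1L)
  snvs <- enumerate_snvs(model, cds)
  n <- nrow(snvs)
  bg <- function(n) pmin(abs(stats::rnorm(n, 0, cfg$background_score_scale)), 0.09)
  sc <- data.frame(hgvs_c = snvs$hgvs_c, c_pos = snvs$c_pos, exon = snvs$exon,
                   ref = snvs$ref, alt = snvs$alt,
                   ag = bg(n), al = bg(n), dg = bg(n), dl = bg(n),
                   ag_pos = NA_integer_, al_pos = NA_integer_,
                   dg_pos = NA_integer_, dl_pos = NA_integer_,
                   stringsAsFactors = FALSE)
  ends <- model$exons$cds_end[-nrow(model$exons)]
  starts <- model$exons$cds_start[-1]
  at_end <- sc$c_pos %in% ends
  at_start <- sc$c_pos %in% starts
  be <- cfg$boundary_effect
  sc$dl[at_end] <- stats::runif(sum(at_end), be[1], be[2])
  sc$dl_pos[at_end] <- 0L
  sc$al[at_start] <- stats::runif(sum(at_start), be[1], be[2])
  sc$al_pos[at_start] <- 0L

  eligible <- which(!at_end & !at_start)
  planted <- eligible[stats::runif(length(eligible)) < cfg$fraction_irrelevant_losses]
  sc$dl[planted] <- stats::runif(length(planted), be[1], be[2])
  sc$dl_pos[planted] <- 0L  # resolves to the variant's own non-site position

  # offsets only at/above the reporting threshold (boundary/planted all >= 0.2)
  for (ch in SCORE_CHANNELS) {
    pc <- paste0(ch, "_pos")
    sc[[pc]][sc[[ch]] < 0.10] <- NA_integer_
  }

  true_max <- pmax(sc$ag, sc$al, sc$dg, ifelse(seq_len(n) %in% planted, 0, sc$dl))
  true_max[at_end] <- pmax(true_max[at_end], sc$dl[at_end])
  label <- (true_max >= cfg$latent_threshold)
  flip <- stats::runif(n) < cfg$label_noise
  label <- xor(label, flip)
  frac <- ifelse(label, cfg$ratio_link(true_max), 0)
  truth <- data.frame(hgvs_c = sc$hgvs_c,
                      true_max_relevant = true_max,
                      planted_irrelevant = seq_len(n) %in% planted,
                      label = label, aberrant_fraction = frac,
                      stringsAsFactors = FALSE)
  list(scores = sc, truth = truth)
}

#' Generate synthetic assay outcomes from scores and ground truth
#'
#' Positive variants draw their aberrant fraction from the truth table
#' (`ratio_link` of the true relevant score); fractions above 0.95 are
#' emitted as a lone aberrant band, the rest as normal + aberrant bands with
#' intensities reconstructed from the fraction under multiplicative
#' lognormal noise. Negative variants get a normal band, plus an occasional
#' sub-threshold faint aberrant band. Aberrant species are exon skips of the
#' variant's exon (internal exons) or retention of the first 140 bases of
#' the adjacent intron (first/last exon).
#'
#' The emitted splice class is then read from the bands with
#' [classify_outcome()] under the given faint-band policy — exactly as a
#' real readout would be. A flipped label whose linked aberrant fraction is
#' too small to show as a band therefore classifies normal_only: label noise
#' is observable only where the gel could see it.
#'
#' @param scores score data.frame from [generate_score_table()].
#' @param truth matching truth data.frame.
#' @param cfg a [synthetic_config()].
#' @param intensity_sd lognormal sdlog of band-intensity noise (default
#'   0.05; 0 for exact intensities).
#' @param policy the [faint_band_policy()] applied when classifying the
#'   emitted bands.
#' @return outcome data.frame in the shape of [load_outcome_fixture()].
#' @export
generate_flgsa_outcomes <- function(scores, truth, cfg, intensity_sd = 0.05,
                                    policy = faint_band_policy()) {
  set.seed(cfg$seed + 2L)
  stopifnot(identical(scores$hgvs_c, truth$hgvs_c))
  n <- nrow(scores)
  n_exons <- max(scores$exon)
  variant <- scores$hgvs_c
  class <- character(n); ratio_text <- character(n); ratio <- rep(NA_real_, n)
  species <- vector("list", n)
  aberrant_species <- function(exon) {
    if (exon > 1L && exon < n_exons) {
      data.frame(kind = "exon_skip", exon = exon, intron = NA_integer_,
                 retained = NA_integer_, intensity = NA_real_, hybrid = FALSE)
    } else {
      intr <- if (exon == n_exons) exon - 1L else exon
      data.frame(kind = "intron_retention", exon = NA_integer_, intron = intr,
                 retained = 140L, intensity = NA_real_, hybrid = FALSE)
    }
  }
  normal_band <- function(intensity) {
    data.frame(kind = "normal", exon = NA_integer_, intron = NA_integer_,
               retained = NA_integer_, intensity = intensity, hybrid = FALSE)
  }
  for (i in seq_len(n)) {
    total <- stats::rlnorm(1, log(2), intensity_sd)
    if (truth$label[i]) {
      f <- min(max(truth$aberrant_fraction[i], 1e-3), 1)
      ab <- aberrant_species(scores$exon[i])
      if (f > 0.95) {
        ab$intensity <- max(round(total, 4), 1e-4)
        sp <- ab
      } else {
        norm_i <- total * (1 - f) * stats::rlnorm(1, 0, intensity_sd)
        ab$intensity <- max(round(total * f * stats::rlnorm(1, 0, intensity_sd), 4),
                            1e-4)
        sp <- rbind(normal_band(max(round(norm_i, 4), 1e-4)), ab)
      }
    } else {
      sp <- normal_band(max(round(total, 4), 1e-4))
      if (stats::runif(1) < cfg$faint_band_prob) {
        ab <- aberrant_species(scores$exon[i])
        ab$intensity <- round(total * stats::runif(1, 0.01, 0.08), 4)
        if (ab$intensity > 0) sp <- rbind(sp, ab)
      }
    }
    species[[i]] <- sp
    # the emitted class is what the assay readout would report
    class[i] <- classify_outcome(sp, policy)
    if (class[i] == "mixed") {
      r <- estimate_ratio(sp$intensity[sp$kind == "normal"],
                          sum(sp$intensity[sp$kind != "normal"]))
      ratio[i] <- r$ratio
      ratio_text[i] <- r$text
    }
  }
  data.frame(variant = variant, class = class, ratio_text = ratio_text,
             ratio = ratio, species = I(species), stringsAsFactors = FALSE)
}

#' Emit a complete synthetic fixture set to disk
#'
#' Writes the gene model, score table, outcome table and truth table in the
#' formats the production readers consume. Identical seeds produce
#' byte-identical files.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
emit_synthetic_fixtures <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- generate_gene_model(cfg)
  st <- generate_score_table(gm$model, gm$cds, cfg)
  out <- generate_flgsa_outcomes(st$scores, st$truth, cfg)
  paths <- c(model = file.path(dir, "gene_model.txt"),
             scores = file.path(dir, "scores.tsv"),
             outcomes = file.path(dir, "outcomes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  gm$model$ref_cds <- gm$cds
  write_gene_model(gm$model, paths["model"])
  write_score_table(st$scores, paths["scores"])
  write_outcome_table(out, paths["outcomes"])
  utils::write.table(st$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
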