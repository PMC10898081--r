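# Packaged SPINK1 fixtures: the four-exon gene model (NM_001379610.1
# structure, hg19 chr5 anchors, reverse strand), the published per-SNV
# delta-score and assay-outcome tables for the 67 FLGSA-analyzed coding SNVs,
# and synthetic stand-ins for sequence objects that are not redistributed
# here (CDS scaffold, exon1+intron1 region).

spink1_file <- function(name) {
  path <- system.file("extdata", name, package = "satsplice")
  if (!nzchar(path)) stop_pos("packaged fixture %s not found", name)
  path
}

#' The SPINK1 gene model fixture
#'
#' Four coding exons (c.1_55, c.56_87, c.88_194, c.195_240; 240 coding
#' nucleotides) anchored to the hg19 chr5 reverse strand
#' (147,211,086-147,211,140 down to 147,204,224-147,204,269). The documented
#' isoform splice-site whitelist is donors `{c.55, c.87, c.194}` and
#' acceptors `{c.56, c.88, c.195}` — the structure shared by the documented
#' SPINK1 transcript isoforms; notably, no documented isoform uses the GT
#' dinucleotide at c.7_8 inside exon 1 as a donor.
#'
#' @return a [gene_model()].
#' @export
spink1_gene_model <- function() {
  read_gene_model(spink1_file("spink1_gene_model.txt"))
}

# constrained codons: every codon touched by a published variant annotation
# (ref base and, where printed, amino-acid change); all other codons are
# arbitrary filler (GCT).
SPINK1_CONSTRAINED_CODONS <- c(
  `1` = "ATG", `2` = "AAG", `3` = "GTA", `4` = "ACA", `5` = "GGC",
  `9` = "CTG", `10` = "AGC", `12` = "TTG", `13` = "GCA", `14` = "CTG",
  `15` = "TTG", `18` = "GCA", `19` = "GGC", `22` = "GGA", `25` = "TCC",
  `27` = "GGA", `28` = "AGA", `29` = "GAG", `30` = "GCT", `31` = "AAG",
  `34` = "AAT", `37` = "AAC", `41` = "AAG", `42` = "ATA", `45` = "CCA",
  `46` = "GTT", `48` = "GGA", `50` = "GAT", `54` = "TAC", `55` = "CCT",
  `58` = "TGC", `60` = "TTG", `64` = "AAC", `65` = "CGG", `66` = "AAA",
  `67` = "CGT", `68` = "CAG", `69` = "ACA", `77` = "GGG", `79` = "TGT",
  `80` = "TGA")

#' A synthetic SPINK1 CDS scaffold
#'
#' A SYNTHETIC 240-nt coding sequence — not the real SPINK1 CDS, which is not
#' redistributed with this package. It is constrained so that every coding
#' position and amino-acid annotation published for the 67 assayed variants
#' (and the additionally discussed exon-1 positions) is reproduced exactly:
#' the reference base at each published variant position, the amino acid and
#' consequence implied by each published protein annotation, the ATG start,
#' the GT dinucleotide at c.7_8, and a terminal stop codon. Codons untouched
#' by any published annotation are arbitrary filler, so genome-wide summaries
#' computed from this scaffold (e.g. the full missense/synonymous partition)
#' are properties of the scaffold, not of SPINK1.
#'
#' @return character scalar of length 240.
#' @export
spink1_synthetic_cds <- function() {
  codons <- rep("GCT", 80L)
  codons[as.integer(names(SPINK1_CONSTRAINED_CODONS))] <- SPINK1_CONSTRAINED_CODONS
  paste(codons, collapse = "")
}

#' Published delta scores for the 67 FLGSA-analyzed SPINK1 coding SNVs
#'
#' The packaged transcription of the published score tables: 62 variants
#' from the retrospective + prospective sets and 5 further-validation
#' variants, with the four delta scores and the printed pre-mRNA offsets
#' (reported only for scores >= 0.10). The `phase` column records the study
#' arm.
#'
#' @param model a [gene_model()] (default [spink1_gene_model()]).
#' @return score data.frame (see [read_score_table()]).
#' @export
spink1_scores <- function(model = spink1_gene_model()) {
  read_score_table(spink1_file("spink1_scores.tsv"), model,
                   score_version = "illumina-precomputed-50bp")
}

#' Published FLGSA outcomes for the 67 assayed SPINK1 coding SNVs
#'
#' Transcript species, band intensities (normalized to the printed
#' densitometric ratios; `!` marks bands known to contain both transcript
#' isoforms through hybrid-dimer formation), splice class and the printed
#' aberrant/normal ratio strings. 12 of the 67 variants alter splicing: nine
#' mixed (three c.55 intron-1 retentions, six exon-2 skips) and three
#' complete exon-2 skips (c.87G>A/C/T); the five validation variants are all
#' normal_only.
#'
#' @return outcome data.frame (see [load_outcome_fixture()]).
#' @export
spink1_outcomes <- function() {
  load_outcome_fixture(spink1_file("spink1_outcomes.tsv"))
}

# exon-1 SNVs named in the published extrapolation discussion as carrying a
# donor-gain score in 0.20-0.24 at the c.7_8 pseudo-site but never assayed
SPINK1_UNTESTED_DG_VARIANTS <- c("c.3G>A", "c.4A>C", "c.11C>T", "c.14G>T",
                                 "c.28A>T", "c.36G>A", "c.45G>T")

#' Reconstructed score universe for all 720 SPINK1 coding SNVs
#'
#' A SYNTHETIC reconstruction of the full precomputed score table, which is
#' not redistributed here. The 67 published rows are used verbatim; the seven
#' exon-1 donor-gain variants that the published analysis names but never
#' assayed (`c.3G>A`, `c.4A>C`, `c.11C>T`, `c.14G>T`, `c.28A>T`, `c.36G>A`,
#' `c.45G>T`) receive DG = 0.22 — the midpoint of their published 0.20-0.24
#' range — with offsets resolving to the documented c.7_8 pseudo-site; every
#' remaining variant gets zero scores, consistent with the published account
#' that scores away from these positions were (near) zero and nowhere
#' relevant at the 0.20 level. Variant identities come from
#' [spink1_synthetic_cds()].
#'
#' @param model a [gene_model()] (default [spink1_gene_model()]).
#' @return score data.frame covering all 720 variants, relevance-filtered
#'   columns not yet attached.
#' @export
spink1_score_universe <- function(model = spink1_gene_model()) {
  snvs <- enumerate_snvs(model, spink1_synthetic_cds())
  uni <- data.frame(hgvs_c = snvs$hgvs_c, c_pos = snvs$c_pos, exon = snvs$exon,
                    ref = snvs$ref, alt = snvs$alt, hgvs_p = snvs$hgvs_p,
                    ag = 0, al = 0, dg = 0, dl = 0,
                    ag_pos = NA_integer_, al_pos = NA_integer_,
                    dg_pos = NA_integer_, dl_pos = NA_integer_,
                    phase = "untested", stringsAsFactors = FALSE)
  fix <- spink1_scores(model)
  idx <- match(fix$hgvs_c, uni$hgvs_c)
  if (anyNA(idx)) {
    stop_pos("fixture variant(s) not in enumerated universe: %s",
             paste(fix$hgvs_c[is.na(idx)], collapse = ", "))
  }
  for (col in c("ag", "al", "dg", "dl", "ag_pos", "al_pos", "dg_pos", "dl_pos",
                "phase")) {
    uni[[col]][idx] <- fix[[col]]
  }
  j <- match(SPINK1_UNTESTED_DG_VARIANTS, uni$hgvs_c)
  if (anyNA(j)) {
    stop_pos("reconstructed DG variant(s) missing from universe")
  }
  uni$dg[j] <- 0.22
  uni$dg_pos[j] <- uni$c_pos[j] - 6L  # resolves to c.6, the c.7_8 pseudo-site
  attr(uni, "score_version") <- "illumina-precomputed-50bp (synthetic reconstruction)"
  uni
}

#' Synthetic SPINK1 exon-1 + intron-1 regional sequence
#'
#' A SYNTHETIC 215-nt stand-in for the genomic region from c.1 through
#' c.55+160 — the real reference sequence is not redistributed. The exon-1
#' part equals the first 55 bases of [spink1_synthetic_cds()]; the intron-1
#' part is constructed so that the three documented donor-signal windows
#' score as published: physiological donor after c.55 (8/9 U1 pairs),
#' experimentally activated cryptic donor at c.55+141_142 (8/9), and the
#' SpliceAI-favoured pseudo-donor at c.7_8 (6/9, rising to 7/9 under
#' c.11C>G).
#'
#' @return character scalar (215 nt).
#' @export
spink1_region_synthetic <- function() {
  seqs <- Biostrings::readDNAStringSet(spink1_file("spink1_region_synthetic.fa"))
  as.character(seqs[[1]])
}
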