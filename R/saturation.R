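# Saturation enumeration of coding SNVs and protein-consequence calling.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

CONSEQUENCE_LEVELS <- c("initiation_codon", "missense", "synonymous",
                        "nonsense", "termination_codon", "unknown")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop_pos("cannot translate codon '%s'", codon)
  aa
}

#' Enumerate all possible coding SNVs of a gene
#'
#' Every coding position contributes exactly three single-nucleotide
#' substitutions (the three non-reference bases), so a gene with `L` coding
#' nucleotides yields `3 * L` variants. When a CDS is supplied, each variant
#' is also classified for protein consequence; otherwise reference bases are
#' taken from the model's optional `ref_cds` and the consequence is
#' `"unknown"` (score triage does not need protein consequences).
#'
#' @param model a [gene_model()].
#' @param cds CDS nucleotide sequence (character or `Biostrings::DNAString`)
#'   of length `model$cds_length`, or `NULL`.
#' @param exons optional integer vector restricting enumeration to these exon
#'   indices.
#' @return data.frame with columns `c_pos`, `exon`, `ref`, `alt`, `hgvs_c`,
#'   `hgvs_p`, `consequence`, ordered by (`c_pos`, `alt`).
#' @examples
#' gm <- spink1_gene_model()
#' nrow(enumerate_snvs(gm, spink1_synthetic_cds()))  # 720
#' @export
enumerate_snvs <- function(model, cds = NULL, exons = NULL) {
  classify <- !is.null(cds)
  if (is.null(cds)) cds <- model$ref_cds
  if (is.null(cds)) {
    stop_pos("no CDS supplied and model %s carries no ref_cds", model$name)
  }
  cds <- toupper(as.character(cds))
  if (nchar(cds) != model$cds_length) {
    stop_pos("CDS length (%d) does not match model cds_length (%d)",
             nchar(cds), model$cds_length)
  }
  bases <- strsplit(cds, "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop_pos("CDS contains non-ACGT bases")

  positions <- seq_len(model$cds_length)
  exon_of <- findInterval(positions, model$exons$cds_start)
  if (!is.null(exons)) positions <- positions[exon_of %in% exons]

  out <- do.call(rbind, lapply(positions, function(p) {
    ref <- bases[p]
    alts <- setdiff(DNA_BASES, ref)
    data.frame(c_pos = p, exon = exon_of[p], ref = ref, alt = alts,
               stringsAsFactors = FALSE)
  }))
  out$hgvs_c <- sprintf("c.%d%s>%s", out$c_pos, out$ref, out$alt)
  if (classify) {
    cc <- classify_consequence(out$c_pos, out$alt, cds)
    out$hgvs_p <- cc$hgvs_p
    out$consequence <- cc$consequence
  } else {
    out$hgvs_p <- NA_character_
    out$consequence <- "unknown"
  }
  rownames(out) <- NULL
  out[order(out$c_pos, out$alt), ]
}

#' Classify the protein consequence of coding SNVs
#'
#' Codons are assembled in cDNA order, so codons spanning exon junctions are
#' handled naturally. Any SNV within the first codon is an
#' `initiation_codon` variant and any SNV within the final codon a
#' `termination_codon` variant, both regardless of the amino-acid effect;
#' these classes are mutually exclusive with the standard
#' missense/synonymous/nonsense partition of the remaining codons.
#'
#' @param c_pos integer vector of coding positions.
#' @param alt character vector of alternate bases (sense strand).
#' @param cds CDS sequence (character), length a multiple of 3.
#' @return list with character vectors `consequence` and `hgvs_p`.
#' @examples
#' classify_consequence(4, "T", "ATGGGCTAA")
#' @export
classify_consequence <- function(c_pos, alt, cds) {
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  if (L %% 3L != 0L) stop_pos("CDS length %d is not a multiple of 3", L)
  n_codons <- L %/% 3L
  alt <- toupper(alt)
  if (!all(alt %in% DNA_BASES)) stop_pos("alternate bases must be ACGT")
  n <- length(c_pos)
  consequence <- character(n)
  hgvs_p <- character(n)
  for (i in seq_len(n)) {
    p <- c_pos[i]
    ci <- (p + 2L) %/% 3L
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    within <- p - (3L * ci - 3L)
    mut <- codon
    substr(mut, within, within) <- alt[i]
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(mut)
    if (ci == 1L) {
      consequence[i] <- "initiation_codon"
      hgvs_p[i] <- "p.Met1?"
    } else if (ci == n_codons) {
      consequence[i] <- "termination_codon"
      hgvs_p[i] <- if (alt_aa == "*") sprintf("p.Ter%d=", ci)
                   else sprintf("p.Ter%dext", ci)
    } else if (alt_aa == ref_aa) {
      consequence[i] <- "synonymous"
      hgvs_p[i] <- sprintf("p.%s%d=", AA3[[ref_aa]], ci)
    } else if (alt_aa == "*") {
      consequence[i] <- "nonsense"
      hgvs_p[i] <- sprintf("p.%s%d*", AA3[[ref_aa]], ci)
    } else {
      consequence[i] <- "missense"
      hgvs_p[i] <- sprintf("p.%s%d%s", AA3[[ref_aa]], ci, AA3[[alt_aa]])
    }
  }
  list(consequence = consequence, hgvs_p = hgvs_p)
}

#' Normalize an HGVS protein string for comparison
#'
#' Published tables vary in spacing and in synonymous notation
#' (`"p.Leu15 ="` vs `"p.Val3Val"`). This helper strips whitespace and
#' rewrites the repeated-residue form to the canonical `"p.X="`.
#'
#' @param p character vector of protein HGVS strings.
#' @return normalized character vector.
#' @export
normalize_hgvs_p <- function(p) {
  p <- gsub("[[:space:]]", "", p)
  # p.Val3Val -> p.Val3=
  gsub("^p\\.([A-Z][a-z]{2})([0-9]+)\\1$", "p.\\1\\2=", p)
}

#' Tally variants by protein-consequence class
#'
#' @param variants data.frame from [enumerate_snvs()] with a `consequence`
#'   column.
#' @param altering optional character vector of `hgvs_c` identifiers that
#'   were experimentally found to alter splicing; when given, per-class
#'   splice-altering counts and percentages are included.
#' @return data.frame with one row per consequence class plus a `Total` row;
#'   columns `consequence`, `n` and, when `altering` is given,
#'   `n_altering` and `pct_altering`.
#' @export
tally_consequences <- function(variants, altering = NULL) {
  lv <- intersect(CONSEQUENCE_LEVELS, unique(variants$consequence))
  cons <- factor(variants$consequence, levels = lv)
  out <- data.frame(consequence = c(lv, "total"),
                    n = c(as.integer(table(cons)), nrow(variants)),
                    stringsAsFactors = FALSE)
  if (!is.null(altering)) {
    hit <- variants$hgvs_c %in% altering
    n_alt <- as.integer(table(cons[hit]))
    out$n_altering <- c(n_alt, sum(hit))
    out$pct_altering <- round(100 * out$n_altering / out$n, 2)
  }
  out
}

#' Write enumerated variants as a tab-separated table
#'
#' @param variants data.frame from [enumerate_snvs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants[c("exon", "hgvs_c", "ref", "alt", "hgvs_p",
                                "consequence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write enumerated variants as a minimal VCF
#'
#' Genomic coordinates come from [c_to_genomic()]; for minus-strand genes the
#' ref/alt alleles are reverse-complemented onto the reference strand.
#'
#' @param variants data.frame from [enumerate_snvs()].
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, model, path) {
  g <- c_to_genomic(model, variants$c_pos)
  ref <- variants$ref; alt <- variants$alt
  if (model$strand == "-") {
    comp <- function(x) chartr("ACGT", "TGCA", x)
    ref <- comp(ref); alt <- comp(alt)
  }
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##source=satsplice enumerate_snvs (%s)", model$name),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     model$chrom, g, variants$hgvs_c, ref, alt))
  writeLines(lines, path)
  invisible(path)
}
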