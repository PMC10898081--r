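# Shared fixtures and independent oracles for the test suite.

# small two-exon plus-strand toy model: CDS ATG GGC | TGC TAA
toy_plus_model <- function() {
  gene_model("TOY", "chr1", "+",
             data.frame(cds_start = c(1L, 7L), cds_end = c(6L, 12L),
                        genomic_start = c(1001L, 1107L),
                        genomic_end = c(1006L, 1112L)),
             donors = 6L, acceptors = 7L)
}
toy_cds <- function() "ATGGGCTGCTAA"

# independent protein-consequence oracle: mutate the WHOLE CDS string per
# variant and translate every mutant in full with Biostrings (one vectorized
# DNAStringSet call), comparing complete proteins position by position
oracle_consequences <- function(c_pos, alt, cds) {
  n_codons <- nchar(cds) %/% 3L
  ci <- (c_pos + 2L) %/% 3L
  muts <- mapply(function(p, a) {
    s <- cds
    substr(s, p, p) <- a
    s
  }, c_pos, alt, USE.NAMES = FALSE)
  prots <- as.character(Biostrings::translate(Biostrings::DNAStringSet(c(cds, muts))))
  aa_ref <- substr(rep(prots[1], length(ci)), ci, ci)
  aa_mut <- substr(prots[-1], ci, ci)
  ifelse(ci == 1L, "initiation_codon",
         ifelse(ci == n_codons, "termination_codon",
                ifelse(aa_mut == aa_ref, "synonymous",
                       ifelse(aa_mut == "*", "nonsense", "missense"))))
}

# random CDS: ATG + sense codons + stop
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(all_codons, stops)
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
          sample(stops, 1L)), collapse = "")
}

# chunk a CDS into a random exon structure on a random strand
random_model_for_cds <- function(cds, n_exons = NULL) {
  L <- nchar(cds)
  n_exons <- n_exons %||% sample(2:4, 1)
  cuts <- sort(sample(seq_len(L - 1L), n_exons - 1L))
  cds_end <- c(cuts, L)
  cds_start <- c(1L, cuts + 1L)
  lens <- cds_end - cds_start + 1L
  introns <- sample(50:500, n_exons - 1L, replace = TRUE)
  strand <- sample(c("+", "-"), 1)
  if (strand == "+") {
    gstart <- 10000L + c(0L, cumsum(lens[-n_exons] + introns))
    gend <- gstart + lens - 1L
  } else {
    total <- sum(lens) + sum(introns)
    gend <- 10000L + total - 1L - c(0L, cumsum(lens[-n_exons] + introns))
    gstart <- gend - lens + 1L
  }
  gene_model("RND", "chrR", strand,
             data.frame(cds_start = cds_start, cds_end = cds_end,
                        genomic_start = gstart, genomic_end = gend),
             donors = cds_end[-n_exons], acceptors = cds_start[-1],
             ref_cds = cds)
}

# independent U1-pairing oracle: each U1 base has a unique Watson-Crick DNA
# partner, so the pair count equals 9 minus the Hamming distance to the DNA
# rendering of the U1 complement (the consensus window)
oracle_u1 <- function(window) {
  cons <- strsplit("CAGGTAAGT", "")[[1]]
  w <- strsplit(window, "")[[1]]
  9L - sum(w != cons)
}

spink1_labeled <- function() {
  gm <- spink1_gene_model()
  sc <- apply_relevance_filter(spink1_scores(gm), gm)
  label_scored_variants(sc, spink1_outcomes())
}
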