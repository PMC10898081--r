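# Gene models: coding exon structure with genomic anchors on either strand,
# plus cDNA ("c."), pre-mRNA and genomic coordinate arithmetic.
#
# Conventions (HGVS): all public coordinates are 1-based inclusive. Coding
# positions are "c.N" with N in 1..cds_length; intronic positions use the
# nearest-exon-boundary form "c.N+M" (M bases into the intron after the last
# exon base N) or "c.N-M" (M bases before the first base N of the next exon).
# UTR positions are outside the model and rejected.

#' Construct a gene model
#'
#' A gene model holds the coding exon structure of one transcript isoform:
#' per-exon coding (cDNA) spans, their genomic anchor spans, the strand, and
#' the set of splice sites documented across transcript isoforms. Splice sites
#' are expressed in cDNA coordinates: a donor is the last coding base of an
#' exon, an acceptor the first coding base of an exon. The documented-site set
#' is the whitelist used by the physiological-relevance filter in
#' [apply_relevance_filter()].
#'
#' Exon cDNA spans must tile `1..cds_length` contiguously, genomic spans must
#' be disjoint and equal in width to the cDNA spans, and on the minus strand
#' exon 1 carries the highest genomic coordinates. Intron lengths are implied
#' by the gaps between consecutive exon genomic spans, which makes the whole
#' pre-mRNA a single contiguous genomic block.
#'
#' @param name gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `cds_start`, `cds_end`,
#'   `genomic_start`, `genomic_end` (1-based inclusive, `genomic_start <=
#'   genomic_end`), one row per exon in cDNA order.
#' @param donors integer vector of cDNA positions (last coding base of an
#'   exon) used as splice donors by any documented isoform.
#' @param acceptors integer vector of cDNA positions (first coding base of an
#'   exon) used as splice acceptors by any documented isoform.
#' @param ref_cds optional reference CDS sequence (character, length
#'   `cds_length`); used by [enumerate_snvs()] when no explicit CDS is given.
#' @return an object of class `gene_model`.
#' @examples
#' gm <- gene_model("TOY", "chr1", "+",
#'   data.frame(cds_start = c(1, 7), cds_end = c(6, 12),
#'              genomic_start = c(101, 207), genomic_end = c(106, 212)),
#'   donors = 6L, acceptors = 7L)
#' c_to_genomic(gm, "c.1")
#' @export
gene_model <- function(name, chrom, strand, exons, donors = integer(),
                       acceptors = integer(), ref_cds = NULL) {
  stopifnot(is.character(name), is.character(chrom))
  if (!strand %in% c("+", "-")) stop_pos("strand must be '+' or '-'")
  req <- c("cds_start", "cds_end", "genomic_start", "genomic_end")
  if (!all(req %in% names(exons))) {
    stop_pos("exons must have columns %s", paste(req, collapse = ", "))
  }
  exons <- as.data.frame(exons)[req]
  exons[] <- lapply(exons, as.integer)
  n <- nrow(exons)
  if (n < 1L) stop_pos("gene model needs at least one exon")
  exons$index <- seq_len(n)

  cds_w <- exons$cds_end - exons$cds_start + 1L
  gen_w <- exons$genomic_end - exons$genomic_start + 1L
  if (any(cds_w < 1L)) stop_pos("exon cDNA spans must be non-empty")
  if (!all(cds_w == gen_w)) stop_pos("exon cDNA and genomic spans differ in width")
  if (exons$cds_start[1] != 1L) stop_pos("first exon must start at c.1")
  if (n > 1L && !all(exons$cds_start[-1] == exons$cds_end[-n] + 1L)) {
    stop_pos("exon cDNA spans must be contiguous")
  }
  cds_length <- exons$cds_end[n]

  # genomic spans: disjoint, ordered by strand; introns at least 1 nt
  if (n > 1L) {
    if (strand == "+") {
      intron_len <- exons$genomic_start[-1] - exons$genomic_end[-n] - 1L
    } else {
      intron_len <- exons$genomic_start[-n] - exons$genomic_end[-1] - 1L
    }
    if (any(intron_len < 1L)) {
      stop_pos("exon genomic spans must be disjoint and ordered 5'->3' on strand %s",
               strand)
    }
  } else {
    intron_len <- integer()
  }

  # pre-mRNA start coordinate of each exon (introns included)
  premrna_start <- exons$cds_start + c(0L, cumsum(intron_len))

  donors <- as.integer(donors)
  acceptors <- as.integer(acceptors)
  valid_donors <- exons$cds_end[-n]
  valid_acceptors <- exons$cds_start[-1]
  if (length(donors) && !all(donors %in% valid_donors)) {
    stop_pos("every donor must be the last coding base of a non-terminal exon")
  }
  if (length(acceptors) && !all(acceptors %in% valid_acceptors)) {
    stop_pos("every acceptor must be the first coding base of a non-initial exon")
  }
  if (!is.null(ref_cds)) {
    ref_cds <- toupper(as.character(ref_cds))
    if (nchar(ref_cds) != cds_length) {
      stop_pos("ref_cds length (%d) != cds_length (%d)", nchar(ref_cds), cds_length)
    }
  }

  structure(list(
    name = name, chrom = chrom, strand = strand, exons = exons,
    donors = sort(donors), acceptors = sort(acceptors),
    cds_length = cds_length, intron_lengths = intron_len,
    premrna_start = premrna_start,
    premrna_length = cds_length + sum(intron_len),
    ref_cds = ref_cds
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, strand %s): %d exons, CDS %d nt, pre-mRNA %d nt\n",
              x$name, x$chrom, x$strand, nrow(x$exons), x$cds_length,
              x$premrna_length))
  cat(sprintf("  donors: %s | acceptors: %s\n",
              paste0("c.", x$donors, collapse = ", "),
              paste0("c.", x$acceptors, collapse = ", ")))
  invisible(x)
}

#' Parse an HGVS-style coding/intronic position
#'
#' Accepts `"c.N"`, `"c.N+M"`, `"c.N-M"` (the leading `"c."` is optional) or a
#' bare integer. Returns a list with `base` (the anchoring coding position)
#' and `offset` (0 for exonic, +M for `c.N+M`, -M for `c.N-M`).
#'
#' @param pos position string or integer.
#' @return list with elements `base` and `offset` (integers).
#' @export
parse_c_position <- function(pos) {
  if (is.numeric(pos)) {
    return(list(base = as.integer(pos), offset = 0L))
  }
  s <- sub("^c\\.", "", trimws(as.character(pos)))
  m <- regmatches(s, regexec("^([0-9]+)(([+-])([0-9]+))?$", s))[[1]]
  if (length(m) == 0L) stop_pos("cannot parse position '%s'", pos)
  base <- as.integer(m[2])
  offset <- 0L
  if (nzchar(m[3])) {
    offset <- as.integer(m[5])
    if (offset < 1L) stop_pos("intronic offset in '%s' must be >= 1", pos)
    if (m[4] == "-") offset <- -offset
  }
  list(base = base, offset = offset)
}

#' Format a coding/intronic position in HGVS style
#'
#' @param base anchoring coding position.
#' @param offset 0 for exonic, signed intronic offset otherwise.
#' @return character, e.g. `"c.55"`, `"c.55+140"`, `"c.88-3"`.
#' @export
format_c_position <- function(base, offset = 0L) {
  if (offset == 0L) sprintf("c.%d", base)
  else if (offset > 0L) sprintf("c.%d+%d", base, offset)
  else sprintf("c.%d-%d", base, -offset)
}

# pre-mRNA coordinate (1 = first coding base, introns included) of a position
premrna_from_c <- function(model, pos) {
  p <- parse_c_position(pos)
  if (p$base < 1L || p$base > model$cds_length) {
    stop_pos("position %s outside coding region of %s (c.1..c.%d)",
             format_c_position(p$base, p$offset), model$name, model$cds_length)
  }
  ex <- which(model$exons$cds_start <= p$base & model$exons$cds_end >= p$base)
  t <- model$premrna_start[ex] + (p$base - model$exons$cds_start[ex]) + p$offset
  if (t < 1L || t > model$premrna_length) {
    stop_pos("position %s outside modeled gene %s",
             format_c_position(p$base, p$offset), model$name)
  }
  t
}

# inverse: pre-mRNA coordinate back to HGVS form; intronic positions take the
# nearest-boundary form, midpoint ties breaking toward the upstream exon
c_from_premrna <- function(model, t) {
  if (t < 1L || t > model$premrna_length) {
    stop_pos("pre-mRNA position %d outside modeled gene %s", t, model$name)
  }
  ex <- model$exons
  premrna_end <- model$premrna_start + (ex$cds_end - ex$cds_start)
  i <- which(model$premrna_start <= t & premrna_end >= t)
  if (length(i) == 1L) {
    return(format_c_position(ex$cds_start[i] + (t - model$premrna_start[i])))
  }
  i <- max(which(premrna_end < t))  # intron after exon i
  d5 <- t - premrna_end[i]
  d3 <- model$premrna_start[i + 1L] - t
  if (d5 <= d3) format_c_position(ex$cds_end[i], d5)
  else format_c_position(ex$cds_start[i + 1L], -d3)
}

#' Map a cDNA/pre-mRNA position to a genomic coordinate
#'
#' On the minus strand, increasing cDNA position maps to decreasing genomic
#' coordinate. Inverse of [genomic_to_c()].
#'
#' @param model a [gene_model()].
#' @param pos position string(s) (`"c.N"`, `"c.N+M"`, `"c.N-M"`) or integers.
#' @return integer vector of 1-based genomic coordinates.
#' @examples
#' gm <- spink1_gene_model()
#' c_to_genomic(gm, "c.1")   # 147211140
#' c_to_genomic(gm, "c.55")  # 147211086
#' @export
c_to_genomic <- function(model, pos) {
  vapply(pos, function(p) {
    t <- premrna_from_c(model, p)
    if (model$strand == "+") model$exons$genomic_start[1] + (t - 1L)
    else model$exons$genomic_end[1] - (t - 1L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Map a genomic coordinate into cDNA/pre-mRNA coordinates
#'
#' @param model a [gene_model()].
#' @param g integer vector of genomic coordinates within the modeled gene
#'   extent (first through last coding base, introns included).
#' @return character vector of HGVS-style positions.
#' @export
genomic_to_c <- function(model, g) {
  vapply(g, function(gi) {
    gi <- as.integer(gi)
    t <- if (model$strand == "+") gi - model$exons$genomic_start[1] + 1L
         else model$exons$genomic_end[1] - gi + 1L
    if (t < 1L || t > model$premrna_length) {
      stop_pos("genomic coordinate %s:%d outside modeled extent of %s",
               model$chrom, gi, model$name)
    }
    c_from_premrna(model, t)
  }, character(1), USE.NAMES = FALSE)
}

#' Shift a position along the pre-mRNA
#'
#' Distances are counted on the pre-mRNA (introns included), not the spliced
#' mRNA. Following the SpliceAI offset convention for a gene's sense strand, a
#' positive offset moves toward the 5' end (smaller coding coordinate) and a
#' negative offset toward the 3' end. Crossing an exon boundary yields the
#' intronic `"c.N+M"`/`"c.N-M"` form.
#'
#' @param model a [gene_model()].
#' @param pos starting position (HGVS-style string or integer).
#' @param offset signed nucleotide count; positive is 5'-ward.
#' @return HGVS-style position string.
#' @examples
#' gm <- spink1_gene_model()
#' shift_on_premrna(gm, "c.55", 49)   # "c.6"
#' shift_on_premrna(gm, "c.56", -31)  # "c.87"
#' @export
shift_on_premrna <- function(model, pos, offset) {
  t <- premrna_from_c(model, pos) - as.integer(offset)
  if (t < 1L || t > model$premrna_length) {
    stop_pos("shift of %s by %d escapes modeled gene %s",
             as.character(pos), offset, model$name)
  }
  c_from_premrna(model, t)
}

#' Is a position a documented splice site of the given kind?
#'
#' True iff `pos` is exonic and matches a boundary in the model's documented
#' isoform splice-site set: donors are last coding bases of exons, acceptors
#' first coding bases. Intronic positions never match.
#'
#' @param model a [gene_model()].
#' @param pos position (HGVS-style string or integer).
#' @param kind `"donor"` or `"acceptor"`.
#' @return logical.
#' @examples
#' gm <- spink1_gene_model()
#' annotated_site_at(gm, "c.55", "donor")  # TRUE
#' annotated_site_at(gm, "c.8", "donor")   # FALSE
#' @export
annotated_site_at <- function(model, pos, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  p <- parse_c_position(pos)
  if (p$offset != 0L) return(FALSE)
  if (kind == "donor") p$base %in% model$donors else p$base %in% model$acceptors
}

#' Read a gene model from a structured text file
#'
#' Line-oriented key/value format: `name`, `chrom`, `strand` lines; one
#' `exon <i> <cds_start> <cds_end> <genomic_start> <genomic_end>` line per
#' exon; `donor c.N` / `acceptor c.N` lines for documented isoform splice
#' sites; optional `ref_cds <sequence>`. `#` starts a comment.
#'
#' @param path file path.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[ \t]+")
  kv <- list(); exon_rows <- list(); donors <- integer(); acceptors <- integer()
  for (tk in toks) {
    key <- tk[1]
    if (key == "exon") {
      exon_rows[[length(exon_rows) + 1L]] <- as.integer(tk[3:6])
    } else if (key == "donor") {
      donors <- c(donors, parse_c_position(tk[2])$base)
    } else if (key == "acceptor") {
      acceptors <- c(acceptors, parse_c_position(tk[2])$base)
    } else {
      kv[[key]] <- tk[2]
    }
  }
  ex <- do.call(rbind, exon_rows)
  gene_model(
    name = kv$name %||% "gene", chrom = kv$chrom %||% "chr?",
    strand = kv$strand %||% "+",
    exons = data.frame(cds_start = ex[, 1], cds_end = ex[, 2],
                       genomic_start = ex[, 3], genomic_end = ex[, 4]),
    donors = donors, acceptors = acceptors, ref_cds = kv$ref_cds
  )
}

#' Write a gene model to the structured text format read by [read_gene_model()]
#'
#' @param model a [gene_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  ex <- model$exons
  lines <- c(
    sprintf("name\t%s", model$name),
    sprintf("chrom\t%s", model$chrom),
    sprintf("strand\t%s", model$strand),
    sprintf("exon\t%d\t%d\t%d\t%d\t%d", ex$index, ex$cds_start, ex$cds_end,
            ex$genomic_start, ex$genomic_end),
    sprintf("donor\tc.%d", model$donors),
    sprintf("acceptor\tc.%d", model$acceptors)
  )
  if (!is.null(model$ref_cds)) lines <- c(lines, sprintf("ref_cds\t%s", model$ref_cds))
  writeLines(lines, path)
  invisible(path)
}

#' Build exon spans from BED-like lines
#'
#' Convenience reader for exon intervals in BED format (0-based, half-open;
#' columns chrom, start, end, name, score, strand). Intervals are converted to
#' 1-based inclusive coordinates, ordered 5'->3' on the indicated strand, and
#' assembled into a [gene_model()]. Donor/acceptor whitelists default to all
#' internal exon boundaries.
#'
#' @param path BED file path.
#' @param name gene name for the model.
#' @param donors,acceptors optional cDNA splice-site whitelists; by default
#'   all internal boundaries of the assembled model.
#' @return a [gene_model()].
#' @export
read_exons_bed <- function(path, name = "gene", donors = NULL, acceptors = NULL) {
  bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop_pos("BED input needs 6 columns (strand required)")
  strand <- unique(bed[[6]])
  chrom <- unique(bed[[1]])
  if (length(strand) != 1L || length(chrom) != 1L) {
    stop_pos("BED exons must share one chromosome and strand")
  }
  gstart <- bed[[2]] + 1L  # 0-based half-open -> 1-based inclusive
  gend <- bed[[3]]
  ord <- if (strand == "+") order(gstart) else order(-gstart)
  gstart <- gstart[ord]; gend <- gend[ord]
  w <- gend - gstart + 1L
  cds_end <- cumsum(w)
  cds_start <- cds_end - w + 1L
  n <- length(w)
  gene_model(name, chrom, strand,
             data.frame(cds_start = cds_start, cds_end = cds_end,
                        genomic_start = gstart, genomic_end = gend),
             donors = donors %||% cds_end[-n],
             acceptors = acceptors %||% cds_start[-1])
}
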