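# Ingestion of per-SNV SpliceAI delta-score tables: sense-strand orientation,
# offset resolution to pre-mRNA positions, and the physiological-relevance
# filter for loss scores.

SCORE_CHANNELS <- c("ag", "al", "dg", "dl")
# channel priority for reporting the driving channel on ties
CHANNEL_PRIORITY <- c("dl", "al", "dg", "ag")

#' Read a per-SNV delta-score table
#'
#' Expects tab-separated text with one row per SNV carrying the four SpliceAI
#' delta scores — acceptor gain (`ag`), acceptor loss (`al`), donor gain
#' (`dg`), donor loss (`dl`), each in `[0, 1]` — and optional signed offset
#' columns `ag_pos`, `al_pos`, `dg_pos`, `dl_pos` (pre-mRNA nucleotide
#' offsets; positive is 5'-ward on the gene's sense strand; empty when the
#' score fell below the table's offset-reporting threshold). Variants are
#' keyed either by an `hgvs_c` column or by `chrom`/`pos`/`ref`/`alt`
#' columns; genomic keys are converted through [genomic_to_c()], with ref/alt
#' reverse-complemented for minus-strand genes. Rows falling outside the
#' coding region are dropped with a warning giving the count.
#'
#' @param path file path.
#' @param model a [gene_model()].
#' @param score_version free-text tag recorded as the `score_version`
#'   attribute (e.g. `"illumina-precomputed-50bp"`).
#' @param strict if `TRUE` (default) malformed scores abort with the line
#'   number; if `FALSE` such rows are skipped with a warning.
#' @return data.frame with columns `hgvs_c`, `c_pos`, `exon`, `ref`, `alt`,
#'   `hgvs_p` (if present), `ag`..`dl`, `ag_pos`..`dl_pos`, plus any extra
#'   input columns (e.g. `phase`).
#' @export
read_score_table <- function(path, model, score_version = "unspecified",
                             strict = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (nrow(tab) == 0L) {
    warning("empty score table: ", path)
    return(empty_score_table(score_version))
  }
  if (!all(SCORE_CHANNELS %in% names(tab))) {
    stop_pos("score table must have columns %s", paste(SCORE_CHANNELS, collapse = ", "))
  }
  if (!"hgvs_c" %in% names(tab)) {
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(tab))) {
      stop_pos("score table needs either hgvs_c or chrom/pos/ref/alt columns")
    }
    in_gene <- vapply(tab$pos, function(g) {
      !inherits(try(genomic_to_c(model, g), silent = TRUE), "try-error")
    }, logical(1))
    cpos_chr <- rep(NA_character_, nrow(tab))
    cpos_chr[in_gene] <- genomic_to_c(model, tab$pos[in_gene])
    exonic <- in_gene & !grepl("[+-]", cpos_chr)
    if (any(!exonic)) {
      warning(sprintf("%d row(s) outside the coding region dropped", sum(!exonic)))
    }
    tab <- tab[exonic, , drop = FALSE]
    cpos_chr <- cpos_chr[exonic]
    ref <- toupper(tab$ref); alt <- toupper(tab$alt)
    if (model$strand == "-") {
      ref <- chartr("ACGT", "TGCA", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    base <- vapply(cpos_chr, function(x) parse_c_position(x)$base, integer(1))
    tab$hgvs_c <- sprintf("c.%d%s>%s", base, ref, alt)
  }

  for (ch in SCORE_CHANNELS) {
    v <- suppressWarnings(as.numeric(tab[[ch]]))
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad)) {
      msg <- sprintf("score '%s' outside [0,1] or unparsable at line %d of %s",
                     ch, bad[1] + 1L, path)
      if (strict) stop_pos("%s", msg)
      warning(msg, "; row(s) skipped")
      tab <- tab[-bad, , drop = FALSE]
      v <- v[-bad]
    }
    tab[[ch]] <- v
    pc <- paste0(ch, "_pos")
    tab[[pc]] <- if (pc %in% names(tab)) suppressWarnings(as.integer(tab[[pc]]))
                 else rep(NA_integer_, nrow(tab))
  }

  key <- sub("^c\\.", "", tab$hgvs_c)
  tab$c_pos <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", key)))
  tab$ref <- sub("^[0-9]+([ACGTN]?)>?.*$", "\\1", key)
  tab$alt <- sub("^.*>", "", key)
  bad_pos <- which(is.na(tab$c_pos) | tab$c_pos < 1L | tab$c_pos > model$cds_length)
  if (length(bad_pos)) {
    msg <- sprintf("unknown variant key '%s' at line %d", tab$hgvs_c[bad_pos[1]],
                   bad_pos[1] + 1L)
    if (strict) stop_pos("%s", msg)
    warning(msg, "; row(s) skipped")
    tab <- tab[-bad_pos, , drop = FALSE]
  }
  tab$exon <- findInterval(tab$c_pos, model$exons$cds_start)
  if ("hgvs_p" %in% names(tab)) tab$hgvs_p <- normalize_hgvs_p(tab$hgvs_p)

  front <- c("hgvs_c", "c_pos", "exon", "ref", "alt",
             intersect("hgvs_p", names(tab)),
             SCORE_CHANNELS, paste0(SCORE_CHANNELS, "_pos"))
  tab <- tab[c(front, setdiff(names(tab), c(front, "chrom", "pos")))]
  rownames(tab) <- NULL
  attr(tab, "score_version") <- score_version
  tab
}

empty_score_table <- function(score_version = "unspecified") {
  out <- data.frame(hgvs_c = character(), c_pos = integer(), exon = integer(),
                    ref = character(), alt = character(),
                    ag = numeric(), al = numeric(), dg = numeric(), dl = numeric(),
                    ag_pos = integer(), al_pos = integer(), dg_pos = integer(),
                    dl_pos = integer(), stringsAsFactors = FALSE)
  attr(out, "score_version") <- score_version
  out
}

#' Write a score table in the tab-separated format read by [read_score_table()]
#'
#' @param scores score data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  keep <- intersect(c("exon", "hgvs_c", "hgvs_p", "ag", "al", "dg", "dl",
                      "ag_pos", "al_pos", "dg_pos", "dl_pos", "phase"),
                    names(scores))
  out <- scores[keep]
  for (ch in SCORE_CHANNELS) out[[ch]] <- sprintf("%.2f", out[[ch]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Resolve score offsets to pre-mRNA positions
#'
#' Each channel's offset, when present, is resolved with
#' [shift_on_premrna()]: loss channels point at the putatively destroyed
#' splice site, gain channels at the putatively created one. Offsets that
#' escape the modeled gene leave the site `NA` and set the corresponding
#' `*_unresolvable` flag.
#'
#' @param scores score data.frame from [read_score_table()].
#' @param model a [gene_model()].
#' @return `scores` with added character columns `ag_site`, `al_site`,
#'   `dg_site`, `dl_site` and logical `*_unresolvable` columns.
#' @examples
#' sc <- spink1_scores()
#' sc <- resolve_sites(sc, spink1_gene_model())
#' sc$dl_site[sc$hgvs_c == "c.84A>G"]  # "c.87"
#' @export
resolve_sites <- function(scores, model) {
  for (ch in SCORE_CHANNELS) {
    off <- scores[[paste0(ch, "_pos")]]
    site <- rep(NA_character_, nrow(scores))
    unres <- rep(FALSE, nrow(scores))
    has <- which(!is.na(off))
    for (i in has) {
      s <- try(shift_on_premrna(model, scores$c_pos[i], off[i]), silent = TRUE)
      if (inherits(s, "try-error")) unres[i] <- TRUE else site[i] <- s
    }
    scores[[paste0(ch, "_site")]] <- site
    scores[[paste0(ch, "_unresolvable")]] <- unres
  }
  scores
}

#' Apply the physiological-relevance filter
#'
#' Loss scores (AL, DL) are physiologically relevant only when the resolved
#' lost site is a documented splice site of the matching kind in the model's
#' isoform whitelist — a predicted donor loss pointing at a GT that no
#' documented transcript isoform uses as a donor is masked. Gain scores are
#' never masked (a new site can arise anywhere). Scores without an offset
#' (below the table's reporting threshold) stay relevant but cannot exceed
#' that threshold anyway. A loss whose offset escapes the modeled gene is
#' masked; a gain in that situation stays relevant and keeps its
#' `*_unresolvable` flag. Loss scores resolving to a site of the wrong kind
#' (e.g. an AL pointing at a donor) are masked, with a message when
#' `verbose`.
#'
#' `max_relevant` is the highest score among relevance-passing channels and
#' `driving` names the channel attaining it (ties broken DL > AL > DG > AG).
#'
#' @param scores score data.frame; [resolve_sites()] is applied first if the
#'   site columns are absent.
#' @param model a [gene_model()].
#' @param tolerance nucleotide tolerance for matching a resolved loss site to
#'   an annotated boundary (default 0, exact).
#' @param verbose log kind-mismatch maskings via `message()`.
#' @return `scores` with added logical columns `rel_ag`..`rel_dl`, numeric
#'   `max_relevant` and character `driving`.
#' @examples
#' sc <- apply_relevance_filter(spink1_scores(), spink1_gene_model())
#' sc$max_relevant[sc$hgvs_c == "c.26T>G"]  # 0.03: the DL 0.29 is masked
#' @export
apply_relevance_filter <- function(scores, model, tolerance = 0L,
                                   verbose = FALSE) {
  if (!"dl_site" %in% names(scores)) scores <- resolve_sites(scores, model)
  site_matches <- function(site, kind) {
    if (is.na(site)) return(FALSE)
    p <- parse_c_position(site)
    if (tolerance == 0L) return(annotated_site_at(model, site, kind))
    anno <- if (kind == "donor") model$donors else model$acceptors
    p$offset == 0L && any(abs(anno - p$base) <= tolerance)
  }
  n <- nrow(scores)
  for (ch in SCORE_CHANNELS) {
    kind <- if (ch %in% c("al", "ag")) "acceptor" else "donor"
    loss <- ch %in% c("al", "dl")
    rel <- rep(TRUE, n)
    if (loss) {
      off <- scores[[paste0(ch, "_pos")]]
      site <- scores[[paste0(ch, "_site")]]
      unres <- scores[[paste0(ch, "_unresolvable")]]
      for (i in seq_len(n)) {
        if (isTRUE(unres[i])) {
          rel[i] <- FALSE
        } else if (!is.na(off[i])) {
          rel[i] <- site_matches(site[i], kind)
          if (!rel[i] && verbose && !is.na(site[i])) {
            message(sprintf("masking %s %s score %.2f: resolved site %s is not a documented %s",
                            scores$hgvs_c[i], toupper(ch), scores[[ch]][i],
                            site[i], kind))
          }
        }
      }
    }
    scores[[paste0("rel_", ch)]] <- rel
  }
  sc_mat <- as.matrix(scores[SCORE_CHANNELS])
  rel_mat <- as.matrix(scores[paste0("rel_", SCORE_CHANNELS)])
  masked <- sc_mat
  masked[!rel_mat] <- -Inf
  # driving channel by priority on ties
  prio <- match(SCORE_CHANNELS, CHANNEL_PRIORITY)
  scores$max_relevant <- pmax(apply(masked, 1, max), 0)
  scores$max_relevant[!apply(rel_mat, 1, any)] <- 0
  scores$driving <- apply(masked, 1, function(r) {
    if (all(!is.finite(r))) return(NA_character_)
    best <- which(r == max(r))
    SCORE_CHANNELS[best[order(prio[best])][1]]
  })
  scores
}

#' Compare two score-table versions
#'
#' Joins two tables on `hgvs_c`, reports per-channel score deltas, and flags
#' variants whose triage decision (any relevant score at or above `cutoff`)
#' differs between versions. Mismatched variant universes are reported and
#' the comparison proceeds on the intersection.
#'
#' @param a,b score data.frames (filtered with [apply_relevance_filter()] if
#'   relevance-aware decisions are wanted; otherwise raw maxima are used).
#' @param cutoff triage cutoff (default 0.20).
#' @return data.frame with `hgvs_c`, per-channel `d_ag`..`d_dl`, decision
#'   columns and `decision_changed`; attributes `n_changed` and
#'   `only_in_a`/`only_in_b`.
#' @export
diff_score_versions <- function(a, b, cutoff = 0.20) {
  only_a <- setdiff(a$hgvs_c, b$hgvs_c)
  only_b <- setdiff(b$hgvs_c, a$hgvs_c)
  if (length(only_a) || length(only_b)) {
    warning(sprintf("universes differ: %d only in a, %d only in b; comparing intersection",
                    length(only_a), length(only_b)))
  }
  common <- intersect(a$hgvs_c, b$hgvs_c)
  ia <- match(common, a$hgvs_c); ib <- match(common, b$hgvs_c)
  dec <- function(df, idx) {
    if ("max_relevant" %in% names(df)) df$max_relevant[idx] >= cutoff
    else do.call(pmax, df[idx, SCORE_CHANNELS]) >= cutoff
  }
  out <- data.frame(hgvs_c = common, stringsAsFactors = FALSE)
  for (ch in SCORE_CHANNELS) {
    out[[paste0("d_", ch)]] <- b[[ch]][ib] - a[[ch]][ia]
  }
  out$decision_a <- dec(a, ia)
  out$decision_b <- dec(b, ib)
  out$decision_changed <- out$decision_a != out$decision_b
  attr(out, "n_changed") <- sum(out$decision_changed)
  attr(out, "only_in_a") <- only_a
  attr(out, "only_in_b") <- only_b
  out
}

#' Parse SpliceAI VCF INFO strings
#'
#' Parses strings of the form
#' `"SpliceAI=ALT|gene|AG|AL|DG|DL|posAG|posAL|posDG|posDL"` (possibly with
#' several comma-separated entries) into a score data.frame. Scores and
#' offsets are returned exactly as encoded in the INFO field; note that raw
#' SpliceAI VCF offsets are genomic-strand relative, whereas this package's
#' tables use sense-strand offsets (positive = 5'-ward).
#'
#' @param info character vector of INFO strings or full `SpliceAI=` values.
#' @return data.frame with columns `alt`, `gene`, `ag`, `al`, `dg`, `dl`,
#'   `ag_pos`, `al_pos`, `dg_pos`, `dl_pos`.
#' @export
parse_spliceai_info <- function(info) {
  entries <- unlist(lapply(info, function(s) {
    s <- sub("^.*SpliceAI=", "", s)
    strsplit(s, ",", fixed = TRUE)[[1]]
  }))
  fields <- strsplit(entries, "|", fixed = TRUE)
  bad <- lengths(fields) < 10L
  if (any(bad)) stop_pos("malformed SpliceAI INFO entry: '%s'", entries[bad][1])
  m <- do.call(rbind, fields)
  data.frame(alt = m[, 1], gene = m[, 2],
             ag = as.numeric(m[, 3]), al = as.numeric(m[, 4]),
             dg = as.numeric(m[, 5]), dl = as.numeric(m[, 6]),
             ag_pos = as.integer(m[, 7]), al_pos = as.integer(m[, 8]),
             dg_pos = as.integer(m[, 9]), dl_pos = as.integer(m[, 10]),
             stringsAsFactors = FALSE)
}
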