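# FLGSA experimental readouts: transcript species per variant, splice-outcome
# class, and the densitometric aberrant/normal ratio. Band intensities are
# consumed as numbers (gel densitometry happens upstream); this module only
# models and loads them.

SPLICE_CLASSES <- c("normal_only", "mixed", "aberrant_only")

#' Faint-band policy
#'
#' Bands whose intensity falls below `min_relative_intensity` of the
#' strongest band in the lane are ignored as clinically irrelevant: a variant
#' retaining more than `1 - min_relative_intensity` of normal transcript is
#' unlikely to be pathologically significant.
#'
#' @param min_relative_intensity fraction in (0, 1); default 0.10.
#' @return an object of class `faint_band_policy`.
#' @export
faint_band_policy <- function(min_relative_intensity = 0.10) {
  if (min_relative_intensity <= 0 || min_relative_intensity >= 1) {
    stop_pos("min_relative_intensity must be in (0,1)")
  }
  structure(list(min_relative_intensity = min_relative_intensity),
            class = "faint_band_policy")
}

#' Estimate the aberrant:normal transcript ratio from band intensities
#'
#' The densitometric ratio is `aberrant / normal`, reported in the
#' conventional `"x/1"` (aberrant in excess) or `"1/x"` (normal in excess)
#' style. Scale-invariant: multiplying both intensities by any positive
#' constant leaves the ratio unchanged. Zero or negative intensities are an
#' input error — absence of a band is a classification question, handled by
#' [classify_outcome()].
#'
#' @param normal,aberrant positive band intensities (arbitrary units).
#' @return list with `ratio` (numeric, aberrant/normal) and `text` (e.g.
#'   `"1/9.03"`).
#' @examples
#' estimate_ratio(9.03, 1.00)$text  # "1/9.03"
#' @export
estimate_ratio <- function(normal, aberrant) {
  if (!is.finite(normal) || !is.finite(aberrant) || normal <= 0 || aberrant <= 0) {
    stop_pos("band intensities must be positive; use classify_outcome for absent bands")
  }
  r <- aberrant / normal
  list(ratio = r, text = format_ratio(r))
}

#' Format an aberrant/normal ratio in the "x/1" / "1/x" style
#'
#' @param r numeric ratio (aberrant/normal).
#' @return character.
#' @export
format_ratio <- function(r) {
  if (r >= 1) sprintf("%.2f/1", r) else sprintf("1/%.2f", 1 / r)
}

#' Parse a ratio string of the form "x/1", "1/x" or "a/b"
#'
#' @param text character vector; empty strings and `"-"` give `NA`.
#' @return numeric vector of aberrant/normal ratios.
#' @export
parse_ratio <- function(text) {
  vapply(text, function(s) {
    s <- trimws(s)
    if (!nzchar(s) || s %in% c("-", "NA")) return(NA_real_)
    parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(is.na(parts)) || parts[2] == 0) {
      stop_pos("cannot parse ratio '%s'", s)
    }
    parts[1] / parts[2]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse a transcript-species descriptor string
#'
#' Semicolon-separated band tokens `kind:intensity`, where kind is `normal`,
#' `skipE<k>` (exon-k skip), `retI<k>+<len>` (retention of the first `len`
#' bases of intron k), or `other`. A trailing `!` on a token flags a band
#' known to contain both transcript isoforms (hybrid-dimer contamination);
#' the flag is carried through but ignored in ratio arithmetic.
#'
#' @param text species descriptor, e.g. `"normal:9.03;retI1+140:1.00"`.
#' @return data.frame with columns `kind`, `exon`, `intron`, `retained`,
#'   `intensity`, `hybrid`.
#' @export
parse_species <- function(text) {
  toks <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop_pos("empty species descriptor")
  rows <- lapply(toks, function(tk) {
    hybrid <- grepl("!$", tk)
    tk <- sub("!$", "", tk)
    parts <- strsplit(tk, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_pos("malformed species token '%s'", tk)
    kind_raw <- parts[1]
    intensity <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(intensity) || intensity < 0) {
      stop_pos("malformed intensity in species token '%s'", tk)
    }
    exon <- NA_integer_; intron <- NA_integer_; retained <- NA_integer_
    if (kind_raw == "normal") {
      kind <- "normal"
    } else if (grepl("^skipE[0-9]+$", kind_raw)) {
      kind <- "exon_skip"
      exon <- as.integer(sub("^skipE", "", kind_raw))
    } else if (grepl("^retI[0-9]+\\+[0-9]+$", kind_raw)) {
      kind <- "intron_retention"
      m <- regmatches(kind_raw, regexec("^retI([0-9]+)\\+([0-9]+)$", kind_raw))[[1]]
      intron <- as.integer(m[2]); retained <- as.integer(m[3])
      if (retained < 1L) stop_pos("retained length must be >= 1 in '%s'", tk)
    } else if (kind_raw == "other") {
      kind <- "other"
    } else {
      stop_pos("malformed species token '%s'", tk)
    }
    data.frame(kind = kind, exon = exon, intron = intron, retained = retained,
               intensity = intensity, hybrid = hybrid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

format_species <- function(species) {
  tok <- vapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    base <- switch(s$kind,
                   normal = "normal",
                   exon_skip = sprintf("skipE%d", s$exon),
                   intron_retention = sprintf("retI%d+%d", s$intron, s$retained),
                   "other")
    sprintf("%s:%s%s", base, format(s$intensity, trim = TRUE),
            if (isTRUE(s$hybrid)) "!" else "")
  }, character(1))
  paste(tok, collapse = ";")
}

#' Classify a splicing-assay outcome from transcript species and intensities
#'
#' Bands below `min_relative_intensity` of the strongest band are dropped,
#' then the outcome is classified over the surviving species: only normal
#' transcript gives `normal_only`, only aberrant species `aberrant_only`, and
#' both `mixed`.
#'
#' @param species data.frame from [parse_species()] (columns `kind`,
#'   `intensity`).
#' @param policy a [faint_band_policy()].
#' @return one of `"normal_only"`, `"mixed"`, `"aberrant_only"`.
#' @examples
#' classify_outcome(parse_species("normal:1.00;skipE2:0.05"))  # normal_only
#' @export
classify_outcome <- function(species, policy = faint_band_policy()) {
  if (nrow(species) == 0L || all(species$intensity <= 0)) {
    stop_pos("assay failure: no band above zero intensity")
  }
  keep <- species$intensity >= policy$min_relative_intensity * max(species$intensity)
  surv <- species[keep & species$intensity > 0, ]
  has_normal <- any(surv$kind == "normal")
  has_aberrant <- any(surv$kind != "normal")
  if (has_normal && has_aberrant) "mixed"
  else if (has_normal) "normal_only"
  else "aberrant_only"
}

#' Load an assay-outcome fixture table
#'
#' Tab-separated columns: `variant` (hgvs_c), `species` (semicolon token
#' list, see [parse_species()]), `class` (one of the three splice classes,
#' stored ground truth), `ratio_text` (printed aberrant/normal ratio, empty
#' unless mixed). Ratio strings are parsed exactly as printed, not re-derived
#' from the intensities.
#'
#' @param path file path.
#' @return data.frame with columns `variant`, `class`, `ratio_text`, `ratio`
#'   (numeric aberrant/normal, `NA` unless mixed) and list-column `species`.
#' @export
load_outcome_fixture <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("variant", "species", "class")
  if (!all(need %in% names(tab))) {
    stop_pos("outcome fixture needs columns %s", paste(need, collapse = ", "))
  }
  if (!"ratio_text" %in% names(tab)) tab$ratio_text <- ""
  tab$ratio_text[is.na(tab$ratio_text)] <- ""
  bad_class <- which(!tab$class %in% SPLICE_CLASSES)
  if (length(bad_class)) {
    stop_pos("unknown splice class '%s' at line %d", tab$class[bad_class[1]],
             bad_class[1] + 1L)
  }
  species <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sp <- try(parse_species(tab$species[i]), silent = TRUE)
    if (inherits(sp, "try-error")) {
      stop_pos("malformed species descriptor at line %d: %s", i + 1L,
               attr(sp, "condition")$message)
    }
    species[[i]] <- sp
  }
  has_ratio <- nzchar(tab$ratio_text)
  if (any(has_ratio != (tab$class == "mixed"))) {
    stop_pos("ratio_text must be present exactly for mixed outcomes")
  }
  data.frame(variant = tab$variant, class = tab$class,
             ratio_text = tab$ratio_text, ratio = parse_ratio(tab$ratio_text),
             species = I(species), stringsAsFactors = FALSE)
}

#' Write an assay-outcome table in the fixture format
#'
#' @param outcomes data.frame as returned by [load_outcome_fixture()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(outcomes, path) {
  lines <- c("variant\tspecies\tclass\tratio_text",
             vapply(seq_len(nrow(outcomes)), function(i) {
               sprintf("%s\t%s\t%s\t%s", outcomes$variant[i],
                       format_species(outcomes$species[[i]]),
                       outcomes$class[i], outcomes$ratio_text[i])
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
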