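# 9-bp 5' splice-donor signal extraction and scoring against the U1 snRNA
# 5'-end sequence. Windows span positions -3..+6 relative to the exon/intron
# boundary (3 exonic + 6 intronic bases), read 5'->3' on the sense strand and
# kept in the DNA alphabet (U pairing handled as T = U).

#' The U1 snRNA 5'-end sequence written 3'->5'
#'
#' The nine bases of the U1 snRNA 5' end that base-pair position-wise with
#' the 9-bp donor signal window; listing it 3'->5' aligns base `i` with
#' window position `i`.
#'
#' @return character scalar `"GUCCAUUCA"`.
#' @export
u1_5prime_sequence <- function() "GUCCAUUCA"

#' The consensus 9-bp donor signal window
#'
#' Fully complementary to the U1 5' end: `CAG | GTAAGT`.
#'
#' @return character scalar `"CAGGTAAGT"`.
#' @export
donor_consensus <- function() "CAGGTAAGT"

#' Extract a 9-bp donor signal window from a regional sequence
#'
#' The regional sequence must cover the gene starting at the first coding
#' base (pre-mRNA coordinate 1); it may be truncated 3' of the window.
#' `site` names the first intronic (or pseudo-intronic) base — the G of the
#' GT dinucleotide — so the window runs from 3 bases before it (exonic side)
#' through 6 bases from it (intronic side).
#'
#' @param region regional nucleotide sequence (character or
#'   `Biostrings::DNAString`), 5'->3' on the sense strand, starting at c.1.
#' @param model a [gene_model()].
#' @param site position of the G of the GT (e.g. `"c.55+1"` for the
#'   physiological donor after c.55, `"c.7"` for a pseudo-site inside an
#'   exon).
#' @return object of class `donor_signal`: list with `site`, `window`
#'   (9-base character) and `complementarity` (see [u1_complementarity()]).
#' @examples
#' gm <- spink1_gene_model()
#' sig <- extract_signal(spink1_region_synthetic(), gm, "c.55+1")
#' sig$complementarity
#' @export
extract_signal <- function(region, model, site) {
  region <- toupper(as.character(region))
  t <- premrna_from_c(model, site)
  lo <- t - 3L; hi <- t + 5L
  if (lo < 1L || hi > nchar(region)) {
    stop_pos("window for site %s needs pre-mRNA positions %d..%d; supplied sequence covers 1..%d",
             as.character(site), lo, hi, nchar(region))
  }
  window <- substr(region, lo, hi)
  structure(list(site = as.character(site), window = window,
                 complementarity = u1_complementarity(window)),
            class = "donor_signal")
}

#' @export
print.donor_signal <- function(x, ...) {
  cat(sprintf("<donor_signal> %s  %s|%s  %d/9 U1 pairs\n", x$site,
              substr(x$window, 1, 3), substr(x$window, 4, 9),
              x$complementarity))
  invisible(x)
}

#' Count Watson-Crick pairs between a donor window and the U1 5' end
#'
#' Position-wise, fixed alignment, no shifts: window base `i` (DNA) against
#' base `i` of the 3'->5' U1 sequence `GUCCAUUCA`. T is treated as U, so the
#' pairing rules are A:U, T:A, G:C, C:G. Ambiguous bases (N) count as
#' non-pairing with a warning.
#'
#' @param window a 9-base character string or a `donor_signal`.
#' @return integer count in 0..9.
#' @examples
#' u1_complementarity("CAGGTAAGT")  # 9
#' @export
u1_complementarity <- function(window) {
  if (inherits(window, "donor_signal")) window <- window$window
  window <- toupper(as.character(window))
  if (nchar(window) != 9L) stop_pos("donor signal window must be 9 bases")
  w <- strsplit(window, "")[[1]]
  if (any(!w %in% c(DNA_BASES, "N"))) {
    stop_pos("window contains invalid bases: %s", window)
  }
  if (any(w == "N")) warning("ambiguous base N counted as non-pairing")
  u1 <- strsplit(u1_5prime_sequence(), "")[[1]]
  pairs <- c(A = "U", T = "A", G = "C", C = "G")
  sum(vapply(seq_len(9L), function(i) {
    w[i] %in% names(pairs) && pairs[[w[i]]] == u1[i]
  }, logical(1)))
}

#' Rank donor signals by U1 complementarity
#'
#' Descending complementarity; ties break by pre-mRNA proximity to the
#' nearest documented physiological donor boundary (nearer first), reported
#' in the `tie_broken` column.
#'
#' @param signals list of `donor_signal` objects.
#' @param model a [gene_model()] (needed only to break ties; optional).
#' @return data.frame with `site`, `window`, `complementarity`,
#'   `distance_to_donor` and `tie_broken`, best first.
#' @export
compare_sites <- function(signals, model = NULL) {
  if (inherits(signals, "donor_signal")) signals <- list(signals)
  if (!length(signals)) stop_pos("need at least one donor signal")
  df <- data.frame(
    site = vapply(signals, `[[`, character(1), "site"),
    window = vapply(signals, `[[`, character(1), "window"),
    complementarity = vapply(signals, `[[`, integer(1), "complementarity"),
    stringsAsFactors = FALSE)
  df$distance_to_donor <- NA_integer_
  if (!is.null(model) && length(model$donors)) {
    donor_t <- vapply(model$donors, function(d) {
      premrna_from_c(model, d) + 1L  # first intronic base
    }, integer(1))
    df$distance_to_donor <- vapply(df$site, function(s) {
      min(abs(premrna_from_c(model, s) - donor_t))
    }, integer(1))
  }
  ord <- order(-df$complementarity, df$distance_to_donor)
  df <- df[ord, ]
  df$tie_broken <- duplicated(df$complementarity) |
    duplicated(df$complementarity, fromLast = TRUE)
  rownames(df) <- NULL
  df
}

#' Apply a coding SNV to a regional sequence
#'
#' Substitutes the alternate base at the variant's pre-mRNA position,
#' checking the reference base first. Useful for re-scoring donor windows
#' under a variant.
#'
#' @param region regional sequence starting at c.1 (see [extract_signal()]).
#' @param model a [gene_model()].
#' @param hgvs_c variant like `"c.11C>G"`.
#' @return mutated sequence (character).
#' @export
apply_snv_to_region <- function(region, model, hgvs_c) {
  region <- toupper(as.character(region))
  m <- regmatches(hgvs_c, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", hgvs_c))[[1]]
  if (length(m) == 0L) stop_pos("cannot parse variant '%s'", hgvs_c)
  t <- premrna_from_c(model, as.integer(m[2]))
  if (t > nchar(region)) stop_pos("variant %s beyond supplied sequence", hgvs_c)
  ref <- m[3]
  if (substr(region, t, t) != ref) {
    stop_pos("reference mismatch for %s: sequence has %s", hgvs_c,
             substr(region, t, t))
  }
  substr(region, t, t) <- m[4]
  region
}

#' Score a donor window with a user-supplied position weight matrix
#'
#' Optional hook: sums per-position log-odds from a 9x4 matrix (rows =
#' window positions -3..+6, columns named A, C, G, T). No matrix ships with
#' the package.
#'
#' @param window 9-base character string or `donor_signal`.
#' @param pwm numeric 9x4 matrix with column names A, C, G, T.
#' @return numeric score.
#' @export
pwm_score <- function(window, pwm) {
  if (inherits(window, "donor_signal")) window <- window$window
  if (!is.matrix(pwm) || nrow(pwm) != 9L ||
      !all(DNA_BASES %in% colnames(pwm))) {
    stop_pos("pwm must be a 9x4 matrix with columns A, C, G, T")
  }
  w <- strsplit(toupper(window), "")[[1]]
  sum(vapply(seq_len(9L), function(i) pwm[i, w[i]], numeric(1)))
}
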