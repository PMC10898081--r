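# Correlating assay outcomes with relevance-filtered delta scores: confusion
# matrices over a cutoff grid, empirical threshold bands, a recommended
# cutoff, and conservative extrapolation to untested variants.

#' Join scored variants with assay outcomes into a labeled table
#'
#' @param scored relevance-filtered score data.frame (with `max_relevant`).
#' @param outcomes data.frame from [load_outcome_fixture()].
#' @return data.frame with `hgvs_c`, `exon`, `max_relevant`, `driving`,
#'   `splice_class`, `altering` (logical positive label: mixed or
#'   aberrant_only) and `ratio`.
#' @export
label_scored_variants <- function(scored, outcomes) {
  idx <- match(outcomes$variant, scored$hgvs_c)
  if (anyNA(idx)) {
    stop_pos("outcome variant(s) missing from score table: %s",
             paste(outcomes$variant[is.na(idx)], collapse = ", "))
  }
  data.frame(hgvs_c = outcomes$variant,
             exon = scored$exon[idx],
             max_relevant = scored$max_relevant[idx],
             driving = scored$driving[idx],
             splice_class = outcomes$class,
             altering = outcomes$class %in% c("mixed", "aberrant_only"),
             ratio = outcomes$ratio,
             stringsAsFactors = FALSE)
}

#' Confusion counts and rates at one cutoff
#'
#' A variant is predicted splice-altering iff its highest relevant delta
#' score is at or above the cutoff; the positive class is
#' mixed-or-aberrant_only.
#'
#' @param labeled data.frame with columns `max_relevant` and `altering`
#'   (logical), e.g. from [label_scored_variants()].
#' @param cutoff delta-score threshold.
#' @return one-row data.frame: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_at_cutoff <- function(labeled, cutoff) {
  if (nrow(labeled) == 0L) stop_pos("empty label set")
  if (!any(labeled$altering) || all(labeled$altering)) {
    stop_pos("need at least one positive and one negative label")
  }
  pred <- labeled$max_relevant >= cutoff
  tp <- sum(pred & labeled$altering)
  fp <- sum(pred & !labeled$altering)
  tn <- sum(!pred & !labeled$altering)
  fn <- sum(!pred & labeled$altering)
  data.frame(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Empirical outcome-vs-score threshold bands
#'
#' Three landmarks of the outcome-vs-score scatter: `lower`, the smallest
#' score among splice-altering variants (below it only normal_only outcomes
#' were observed); `upper_any`, the largest score among normal_only variants
#' (above it every observed outcome was splice-altering); and
#' `upper_complete`, the smallest score among aberrant_only variants (above
#' it — when it exceeds every mixed score — only complete aberrance was
#' observed). When the classes separate perfectly `lower` can exceed
#' `upper_any`; the values are reported as-is.
#'
#' @param labeled data.frame with `max_relevant` and `splice_class`.
#' @return list with `lower`, `upper_any`, `upper_complete` (numeric, `NA`
#'   when the supporting class is absent).
#' @export
threshold_bands <- function(labeled) {
  pos <- labeled$max_relevant[labeled$splice_class %in% c("mixed", "aberrant_only")]
  neg <- labeled$max_relevant[labeled$splice_class == "normal_only"]
  comp <- labeled$max_relevant[labeled$splice_class == "aberrant_only"]
  list(lower = if (length(pos)) min(pos) else NA_real_,
       upper_any = if (length(neg)) max(neg) else NA_real_,
       upper_complete = if (length(comp)) min(comp) else NA_real_)
}

#' Sweep classification cutoffs over a grid
#'
#' @param labeled data.frame with `max_relevant`, `altering` and
#'   `splice_class`.
#' @param grid numeric vector of cutoffs within `[0, 1]`
#'   (default `seq(0, 1, 0.05)`).
#' @return data.frame of [confusion_at_cutoff()] rows, one per grid value;
#'   attributes `bands` ([threshold_bands()]) and `recommended_cutoff`
#'   ([recommend_cutoff()]).
#' @export
sweep_cutoffs <- function(labeled, grid = seq(0, 1, by = 0.05)) {
  if (any(grid < 0 | grid > 1)) stop_pos("grid must lie within [0,1]")
  pts <- do.call(rbind, lapply(grid, function(ct) confusion_at_cutoff(labeled, ct)))
  attr(pts, "bands") <- threshold_bands(labeled)
  attr(pts, "recommended_cutoff") <- recommend_cutoff(pts)
  pts
}

#' Recommended cutoff from a sweep
#'
#' The smallest grid value maximizing Youden's J
#' (sensitivity + specificity - 1); ties break toward the smaller, more
#' sensitive cutoff.
#'
#' @param points data.frame from [sweep_cutoffs()].
#' @return numeric cutoff.
#' @export
recommend_cutoff <- function(points) {
  j <- points$sensitivity + points$specificity - 1
  points$cutoff[which(j >= max(j) - 1e-12)[1]]
}

#' Extrapolate splice-impact calls to untested variants
#'
#' An untested variant is called `unlikely_altering` when (i) its highest
#' relevant score is below the extrapolation floor, or (ii) an assayed
#' comparator — same coding position preferred, otherwise same exon and same
#' driving channel — with a score at least as high was found normal_only.
#' Every call records its basis. Variants clearing neither test are
#' `indeterminate_assay_recommended`: no variant whose score exceeds every
#' assayed normal_only comparator is ever auto-cleared.
#'
#' @param universe relevance-filtered score data.frame for all candidate
#'   variants (tested rows are ignored).
#' @param assayed labeled data.frame from [label_scored_variants()].
#' @param floor extrapolation floor (default 0.20); scores in the band
#'   between the floor and the assayed evidence are resolved only through
#'   comparators.
#' @return data.frame with `hgvs_c`, `max_relevant`, `call`, `basis`.
#' @export
extrapolate_untested <- function(universe, assayed, floor = 0.20) {
  untested <- universe[!universe$hgvs_c %in% assayed$hgvs_c, , drop = FALSE]
  normals <- assayed[assayed$splice_class == "normal_only", , drop = FALSE]
  n <- nrow(untested)
  call <- character(n); basis <- character(n)
  cpos_of <- function(v) as.integer(sub("^c\\.([0-9]+).*$", "\\1", v))
  normals$c_pos <- cpos_of(normals$hgvs_c)
  for (i in seq_len(n)) {
    s <- untested$max_relevant[i]
    if (s < floor) {
      call[i] <- "unlikely_altering"
      basis[i] <- sprintf("max_relevant %.2f < floor %.2f", s, floor)
      next
    }
    same_pos <- normals[normals$c_pos == untested$c_pos[i] &
                          normals$max_relevant >= s, , drop = FALSE]
    same_ctx <- normals[normals$exon == untested$exon[i] &
                          !is.na(normals$driving) &
                          normals$driving == untested$driving[i] &
                          normals$max_relevant >= s, , drop = FALSE]
    comp <- if (nrow(same_pos)) same_pos else same_ctx
    if (nrow(comp)) {
      # the most closely resembling comparator: smallest adequate score
      j <- which.min(comp$max_relevant)
      call[i] <- "unlikely_altering"
      basis[i] <- sprintf("comparator %s (max_relevant %.2f, normal_only)",
                          comp$hgvs_c[j], comp$max_relevant[j])
    } else {
      call[i] <- "indeterminate_assay_recommended"
      basis[i] <- sprintf("max_relevant %.2f >= floor with no normal_only comparator", s)
    }
  }
  data.frame(hgvs_c = untested$hgvs_c, max_relevant = untested$max_relevant,
             call = call, basis = basis, stringsAsFactors = FALSE)
}

#' Rank concordance between loss scores and aberrant transcript fractions
#'
#' For each coding position with at least two mixed outcomes, compares every
#' pair of variants at that position: a pair is concordant when the variant
#' with the higher score of the chosen channel also has the higher aberrant
#' fraction `ratio / (1 + ratio)`. This is a reported ordering check, not a
#' fitted model — exceptions are surfaced, not adjudicated.
#'
#' @param labeled data.frame from [label_scored_variants()].
#' @param scored relevance-filtered score table (source of the channel
#'   scores).
#' @param channel score channel to rank by (default `"dl"`).
#' @return data.frame with one row per within-position pair: `c_pos`,
#'   `variant_a`, `variant_b`, `score_a`, `score_b`, `fraction_a`,
#'   `fraction_b`, `concordant`.
#' @export
ratio_score_concordance <- function(labeled, scored, channel = "dl") {
  mixed <- labeled[labeled$splice_class == "mixed" & !is.na(labeled$ratio), ]
  mixed$c_pos <- as.integer(sub("^c\\.([0-9]+).*$", "\\1", mixed$hgvs_c))
  mixed$score <- scored[[channel]][match(mixed$hgvs_c, scored$hgvs_c)]
  mixed$fraction <- mixed$ratio / (1 + mixed$ratio)
  rows <- list()
  for (p in unique(mixed$c_pos)) {
    grp <- mixed[mixed$c_pos == p, ]
    if (nrow(grp) < 2L) next
    cmb <- utils::combn(nrow(grp), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      rows[[length(rows) + 1L]] <- data.frame(
        c_pos = p, variant_a = grp$hgvs_c[a], variant_b = grp$hgvs_c[b],
        score_a = grp$score[a], score_b = grp$score[b],
        fraction_a = grp$fraction[a], fraction_b = grp$fraction[b],
        concordant = sign(grp$score[a] - grp$score[b]) ==
          sign(grp$fraction[a] - grp$fraction[b]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
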