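# Rule-based nomination of coding SNVs for functional splicing assay.

#' Construct an assay-selection rule set
#'
#' The rules mirror the candidate-selection procedure used for a saturation
#' splicing screen: (a) all three SNVs at the first and last coding base of
#' every exon, excluding the gene's first and last coding base; (b) every SNV
#' with at least one physiologically relevant delta score at or above the
#' cutoff; (c) per exon, the top-k donor-gain variants; (d) explicit control
#' positions (all three SNVs at each) and manually named extra variants.
#' Judgment-based inclusions that no mechanical rule reproduces are expressed
#' through `control_positions`/`extra_variants`, not inferred.
#'
#' @param include_exon_boundaries include internal exon boundary positions.
#' @param score_cutoff relevance-filtered delta-score threshold in `[0, 1]`
#'   (default 0.20).
#' @param top_k_gain_per_exon integer, or named integer vector keyed by exon
#'   index, giving how many highest-DG variants to add per exon (default 0).
#' @param control_positions integer vector of coding positions whose three
#'   SNVs are added as negative controls.
#' @param extra_variants character vector of `hgvs_c` identifiers to add.
#' @return an object of class `selection_rules`.
#' @export
selection_rules <- function(include_exon_boundaries = TRUE,
                            score_cutoff = 0.20,
                            top_k_gain_per_exon = 0L,
                            control_positions = integer(),
                            extra_variants = character()) {
  if (score_cutoff < 0 || score_cutoff > 1) stop_pos("score_cutoff must be in [0,1]")
  structure(list(include_exon_boundaries = isTRUE(include_exon_boundaries),
                 score_cutoff = score_cutoff,
                 top_k_gain_per_exon = top_k_gain_per_exon,
                 control_positions = as.integer(control_positions),
                 extra_variants = as.character(extra_variants)),
            class = "selection_rules")
}

#' Read selection rules from a key/value text file
#'
#' Recognized keys: `include_exon_boundaries` (true/false), `score_cutoff`,
#' `top_k_gain_per_exon` (either `k` or `exon:k` pairs), `control_positions`
#' (comma list), `extra_variants` (comma list). `#` starts a comment.
#'
#' @param path file path.
#' @return a [selection_rules()] object.
#' @export
read_selection_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[ \t]+")
  args <- list()
  for (tk in kv) {
    key <- tk[1]; val <- paste(tk[-1], collapse = " ")
    if (key == "include_exon_boundaries") {
      args$include_exon_boundaries <- tolower(val) %in% c("true", "yes", "1")
    } else if (key == "score_cutoff") {
      args$score_cutoff <- as.numeric(val)
    } else if (key == "top_k_gain_per_exon") {
      if (grepl(":", val)) {
        pairs <- strsplit(strsplit(val, ",")[[1]], ":")
        k <- vapply(pairs, function(p) as.integer(p[2]), integer(1))
        names(k) <- vapply(pairs, function(p) trimws(p[1]), character(1))
        args$top_k_gain_per_exon <- k
      } else args$top_k_gain_per_exon <- as.integer(val)
    } else if (key == "control_positions") {
      args$control_positions <- as.integer(strsplit(val, ",")[[1]])
    } else if (key == "extra_variants") {
      args$extra_variants <- trimws(strsplit(val, ",")[[1]])
    }
  }
  do.call(selection_rules, args)
}

#' Select SNV candidates for functional assay
#'
#' Applies a [selection_rules()] set to a relevance-filtered score table and
#' returns the union of the boundary, score, top-gain, control and manual
#' selections, each variant tagged with every reason that nominated it.
#'
#' @param scored score data.frame with `max_relevant` (from
#'   [apply_relevance_filter()]); physiologically irrelevant scores are
#'   invisible to the score rule.
#' @param rules a [selection_rules()] object.
#' @param model a [gene_model()].
#' @return data.frame with columns `hgvs_c`, `exon`, `c_pos`, `alt`,
#'   `reasons` (comma-joined subset of boundary/score/top_gain/control/
#'   manual), ordered by (exon, c_pos, alt); attribute `per_exon` holds
#'   per-exon counts.
#' @export
select_candidates <- function(scored, rules, model) {
  if (!"max_relevant" %in% names(scored)) {
    stop_pos("scored table lacks max_relevant; run apply_relevance_filter() first")
  }
  missing_manual <- setdiff(rules$extra_variants, scored$hgvs_c)
  if (length(missing_manual)) {
    stop_pos("extra_variants not in scored universe: %s",
             paste(missing_manual, collapse = ", "))
  }
  if (length(rules$control_positions) &&
      any(rules$control_positions < 1L | rules$control_positions > model$cds_length)) {
    stop_pos("control_positions outside coding region")
  }

  reasons <- stats::setNames(vector("list", nrow(scored)), scored$hgvs_c)
  add <- function(idx, tag) {
    for (i in idx) reasons[[i]] <<- union(reasons[[i]], tag)
  }

  if (rules$include_exon_boundaries) {
    ex <- model$exons
    n <- nrow(ex)
    bpos <- setdiff(c(ex$cds_start, ex$cds_end), c(1L, model$cds_length))
    add(which(scored$c_pos %in% bpos), "boundary")
  }
  add(which(scored$max_relevant >= rules$score_cutoff), "score")
  k <- rules$top_k_gain_per_exon
  for (e in unique(scored$exon)) {
    ke <- if (length(k) > 1L || !is.null(names(k))) {
      if (as.character(e) %in% names(k)) k[[as.character(e)]] else 0L
    } else k
    if (ke > 0L) {
      idx <- which(scored$exon == e)
      top <- idx[order(-scored$dg[idx])][seq_len(min(ke, length(idx)))]
      add(top[scored$dg[top] > 0], "top_gain")
    }
  }
  add(which(scored$c_pos %in% rules$control_positions), "control")
  add(match(rules$extra_variants, scored$hgvs_c), "manual")

  sel <- which(lengths(reasons) > 0L)
  out <- scored[sel, c("hgvs_c", "exon", "c_pos", "alt", "max_relevant")]
  out$reasons <- vapply(reasons[sel], paste, character(1), collapse = ",")
  out <- out[order(out$exon, out$c_pos, out$alt), ]
  rownames(out) <- NULL
  attr(out, "per_exon") <- table(factor(out$exon, levels = model$exons$index))
  out
}

#' One-line summary of a selection report
#'
#' @param report output of [select_candidates()].
#' @return character vector of summary lines, invisibly; also printed.
#' @export
summarize_selection <- function(report) {
  per <- attr(report, "per_exon")
  lines <- c(sprintf("%d variants selected", nrow(report)),
             sprintf("  exon %s: %d", names(per), as.integer(per)))
  cat(lines, sep = "\n")
  invisible(lines)
}
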