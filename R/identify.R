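# Proteome screen for membrane-bound desaturase candidates: best local
# alignment against a panel of reference anchors, then confirmation by
# histidine-box architecture. Boxes 1 and 2 are required; box 3 is not,
# because genuine family members are known to have lost it (the FAD2.1
# pseudogene pattern), so a two-box candidate that scores well is kept.

#' Screen a proteome for desaturase candidates
#'
#' Every proteome entry is scored by its best local alignment against the
#' anchor panel and accepted iff the score and identity thresholds are met
#' and histidine boxes 1 and 2 are found. The result is non-redundant by
#' locus id (first dot-delimited prefix of the sequence id).
#'
#' @param proteome Named character vector of protein sequences.
#' @param anchors Named character vector of anchor proteins spanning the
#'   subfamilies.
#' @param min_score Minimum best local-alignment score (substitution-matrix
#'   units). The default passes planted family members at >= 40% identity to
#'   their anchors; no universal BLAST-equivalent cutoff exists, so it is
#'   configurable.
#' @param min_identity Minimum identity of the best local alignment.
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [local_align()].
#' @param spacing12,spacing23 Spacing windows for the box scan, see
#'   [scan_histidine_boxes()].
#' @return Data frame of class `candidate_hits`: one row per proteome entry
#'   with `id`, `best_anchor`, `score`, `identity`, `coverage_longer`,
#'   `boxes12` (boxes 1 and 2 both present), `complete` (all three),
#'   `accepted`.
#' @export
screen_candidates <- function(proteome, anchors, min_score = 100,
                              min_identity = 0.4, matrix = blosum62(),
                              gap_open = 10, gap_extend = 0.5,
                              spacing12 = c(25, 40), spacing23 = c(100, 200)) {
  if (!length(anchors)) stop("empty anchor set", call. = FALSE)
  stopifnot(!is.null(names(proteome)), !is.null(names(anchors)))

  rows <- lapply(names(proteome), function(id) {
    best <- NULL; best_anchor <- NA_character_
    for (an in names(anchors)) {
      r <- local_align(proteome[[id]], anchors[[an]], matrix,
                       gap_open, gap_extend)
      if (is.null(best) || r$score > best$score) {
        best <- r; best_anchor <- an
      }
    }
    a <- scan_histidine_boxes(proteome[[id]], spacing12, spacing23)
    boxes12 <- !is.null(a$box1) && !is.null(a$box2)
    data.frame(id = id, best_anchor = best_anchor, score = best$score,
               identity = best$identity,
               coverage_longer = best$coverage_longer,
               boxes12 = boxes12, complete = a$complete,
               accepted = best$score >= min_score &&
                 best$identity >= min_identity && boxes12,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # non-redundant by locus id: splice isoforms share an id up to a trailing
  # numeric suffix (locus.1, locus.2, ...); keep the best-scoring isoform
  locus <- sub("\\.[0-9]+$", "", out$id)
  keep <- unlist(lapply(split(seq_len(nrow(out)), locus), function(ix) {
    ix[order(-out$score[ix], out$id[ix])][1]
  }), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_hits", "data.frame")
  out
}

#' Assign family names to accepted candidates
#'
#' Names follow the anchor-orthology convention: each accepted hit takes its
#' best anchor's family stem plus an ordinal suffix (`.1`, `.2`, ...) in
#' order of descending score (ties broken by lexicographic id); a stem with
#' a single hit gets no suffix.
#'
#' @param hits A `candidate_hits` data frame from [screen_candidates()].
#' @param prefix Optional species prefix prepended to every name (e.g.
#'   `"Gr"`).
#' @return `hits` restricted to accepted rows, with a `name` column added.
#' @export
assign_names <- function(hits, prefix = "") {
  acc <- hits[hits$accepted, , drop = FALSE]
  acc <- acc[order(acc$best_anchor, -acc$score, acc$id), , drop = FALSE]
  acc$name <- NA_character_
  for (stem in unique(acc$best_anchor)) {
    ix <- which(acc$best_anchor == stem)
    acc$name[ix] <- if (length(ix) == 1) paste0(prefix, stem) else
      sprintf("%s%s.%d", prefix, stem, seq_along(ix))
  }
  rownames(acc) <- NULL
  acc
}
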