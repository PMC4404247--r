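# Conserved-motif analysis for membrane-bound desaturases: the three
# histidine boxes that form the di-iron active site, the C-terminal
# ER-retrieval pentapeptide of FAD2-type enzymes, and the HPGG proxy for the
# N-terminal cytochrome b5 domain of sphingolipid delta-8 desaturases.
#
# Box patterns (1-based, spacing counted as residues strictly BETWEEN boxes):
#   box1: H x{3,4} H        (4 internal residues in the First Desaturase
#                            subfamily, 3 in the other three)
#   box2: H x{2,3} H H
#   box3: [HQ] x{2,3} H H   (Q opening is the Front-end subfamily signature)

box_patterns <- function(allow_q_box3 = TRUE) {
  list(
    box1 = list(first = "H", gaps = 3:4, tail = "H"),
    box2 = list(first = "H", gaps = 2:3, tail = "HH"),
    box3 = list(first = if (allow_q_box3) c("H", "Q") else "H",
                gaps = 2:3, tail = "HH"))
}

# all (start, end) matches of one box pattern in a character vector;
# ordered by start, then by length (shortest first)
box_matches <- function(chars, pat, from = 1L, to = length(chars)) {
  hits <- NULL
  to <- min(to, length(chars))
  if (from > to) return(NULL)
  for (start in from:to) {
    if (!(chars[start] %in% pat$first)) next
    for (g in pat$gaps) {
      tail_start <- start + 1L + g
      tail_end <- tail_start + nchar(pat$tail) - 1L
      if (tail_end > length(chars)) next
      tail_chars <- chars[tail_start:tail_end]
      if (all(tail_chars == strsplit(pat$tail, "")[[1]])) {
        hits <- rbind(hits, c(start, tail_end))
      }
    }
  }
  hits
}

#' Scan a protein for the three histidine boxes
#'
#' Leftmost-greedy, non-overlapping assignment of box1, then box2, then
#' box3, with configurable windows on the inter-box spacings (residues
#' strictly between the end of one box and the start of the next). Missing
#' boxes are reported as absent, never as errors: the architecture of a
#' protein that lost its third box (a known FAD2 pseudogene pattern) comes
#' back with `complete = FALSE`.
#'
#' @param sequence Protein sequence.
#' @param spacing12 Allowed window (inclusive) for the box1-box2 spacing.
#' @param spacing23 Allowed window for the box2-box3 spacing.
#' @param allow_q_box3 Accept Q as the opening residue of box3 (the
#'   Front-end subfamily divergence).
#' @return Object of class `box_architecture`: per-box `start`, `end`,
#'   `text` (or `NULL` when absent), `spacing12`, `spacing23`, `complete`.
#' @export
scan_histidine_boxes <- function(sequence, spacing12 = c(25, 40),
                                 spacing23 = c(100, 200),
                                 allow_q_box3 = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  pats <- box_patterns(allow_q_box3)
  boxes <- list(box1 = NULL, box2 = NULL, box3 = NULL)

  m1 <- box_matches(chars, pats$box1)
  if (!is.null(m1)) {
    # leftmost start, then shortest match
    m1 <- m1[order(m1[, 1], m1[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(m1))) {
      b1 <- m1[k, ]
      lo2 <- b1[2] + 1L + spacing12[1]
      hi2 <- b1[2] + 1L + spacing12[2]
      if (lo2 > length(chars)) next
      m2 <- box_matches(chars, pats$box2, from = lo2,
                        to = min(hi2, length(chars)))
      if (is.null(m2)) { if (is.null(boxes$box1)) boxes$box1 <- b1; next }
      m2 <- m2[order(m2[, 1], m2[, 2]), , drop = FALSE]
      b2 <- m2[1, ]
      boxes$box1 <- b1
      boxes$box2 <- b2
      lo3 <- b2[2] + 1L + spacing23[1]
      hi3 <- b2[2] + 1L + spacing23[2]
      if (lo3 <= length(chars)) {
        m3 <- box_matches(chars, pats$box3, from = lo3,
                          to = min(hi3, length(chars)))
        if (!is.null(m3)) {
          m3 <- m3[order(m3[, 1], m3[, 2]), , drop = FALSE]
          boxes$box3 <- m3[1, ]
        }
      }
      break
    }
    if (is.null(boxes$box1)) boxes$box1 <- m1[1, ]
  }

  as_hit <- function(b) {
    if (is.null(b)) return(NULL)
    list(start = unname(b[1]), end = unname(b[2]),
         text = paste(chars[b[1]:b[2]], collapse = ""))
  }
  h1 <- as_hit(boxes$box1); h2 <- as_hit(boxes$box2); h3 <- as_hit(boxes$box3)
  structure(list(
    box1 = h1, box2 = h2, box3 = h3,
    spacing12 = if (!is.null(h1) && !is.null(h2)) h2$start - h1$end - 1L else NA_integer_,
    spacing23 = if (!is.null(h2) && !is.null(h3)) h3$start - h2$end - 1L else NA_integer_,
    complete = !is.null(h1) && !is.null(h2) && !is.null(h3)),
    class = "box_architecture")
}

#' @export
print.box_architecture <- function(x, ...) {
  fmt <- function(h) if (is.null(h)) "absent" else
    sprintf("%s @ %d-%d", h$text, h$start, h$end)
  cat(sprintf("<histidine boxes> 1: %s | 2: %s | 3: %s\n",
              fmt(x$box1), fmt(x$box2), fmt(x$box3)))
  cat(sprintf("  spacing 1-2: %s, 2-3: %s, complete: %s\n",
              x$spacing12, x$spacing23, x$complete))
  invisible(x)
}

#' Detect the C-terminal ER-retrieval pentapeptide
#'
#' Tests exactly the final five residues against Phi-X-X-\[KRDE\]-Phi, where
#' Phi is a large hydrophobic residue (F/Y/W/I/L/V). The test is
#' position-strict: any residue appended after the pentapeptide destroys
#' the hit.
#'
#' @param sequence Protein sequence of length >= 5.
#' @return List with `present`, `pentapeptide`, `positions` (the last five
#'   1-based positions).
#' @export
detect_er_motif <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(n >= 5)
  penta <- substr(sequence, n - 4, n)
  present <- grepl("^[FYWILV]..[KRDE][FYWILV]$", penta)
  list(present = present, pentapeptide = penta, positions = (n - 4):n)
}

#' Detect the cytochrome b5 proxy motif
#'
#' Advisory flag for the N-terminal cytochrome b5 domain of sphingolipid
#' delta-8 desaturases: TRUE iff the conserved heme-binding HPGG tetrapeptide
#' occurs within the first `window` residues. A profile-HMM domain search is
#' deliberately out of scope; this proxy keys on the domain's invariant core.
#'
#' @param sequence Protein sequence.
#' @param window N-terminal window in residues (default 80).
#' @return List with `present` and `position` (1-based start, or NA).
#' @export
detect_cytb5 <- function(sequence, window = 80) {
  head <- substr(toupper(sequence), 1, window)
  pos <- regexpr("HPGG", head, fixed = TRUE)
  list(present = pos > 0, position = if (pos > 0) as.integer(pos) else NA_integer_)
}

#' Position-frequency logo over alignment columns
#'
#' Per-column amino-acid frequencies and information content
#' R = log2(20) - H (Shannon entropy in bits) over a column slice of an
#' alignment; gaps are excluded from the counts (frequencies renormalize
#' over residues).
#'
#' @param msa A [msa_object()].
#' @param columns Integer vector of column indices.
#' @return Object of class `box_logo`: `freq` (20 x k matrix) and
#'   `information` (bits per column, in \[0, log2 20\]).
#' @export
build_box_logo <- function(msa, columns) {
  stopifnot(inherits(msa, "fad_msa"),
            all(columns >= 1), all(columns <= msa$ncol))
  m <- msa_matrix(msa)[, columns, drop = FALSE]
  freq <- matrix(0, length(AA20), ncol(m), dimnames = list(AA20, NULL))
  info <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "-" & col %in% AA20]
    if (!length(col)) { info[j] <- 0; next }
    f <- as.numeric(table(factor(col, levels = AA20))) / length(col)
    freq[, j] <- f
    nz <- f[f > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, information = info, columns = columns),
            class = "box_logo")
}

#' @export
print.box_logo <- function(x, ...) {
  cat(sprintf("<box logo> %d columns, information %.2f-%.2f bits\n",
              length(x$columns), min(x$information), max(x$information)))
  invisible(x)
}
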