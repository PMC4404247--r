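# Pairwise and progressive alignment. The affine-gap DP kernel lives in
# src/gotoh.cpp and works on precomputed cell-score matrices, so the same
# code path drives residue-residue alignment and the profile-profile merges
# of the progressive MSA. A gap run of length k costs open + (k-1)*extend.

#' BLOSUM62 substitution matrix
#'
#' The published BLOSUM62 matrix as shipped with Biostrings, restricted to
#' the 20 standard residues plus `X`.
#' @return Integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c(AA20, "X")
  e$BLOSUM62[keep, keep]
}

seq_to_idx <- function(s, matrix, what) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(matrix))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("residue '%s' at position %d of %s not in substitution matrix",
                 chars[pos], pos, what), call. = FALSE)
  }
  idx
}

align_result <- function(a, b, score, path_a, path_b) {
  gap_a <- path_a == 0
  gap_b <- path_b == 0
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  row_a <- ifelse(gap_a, "-", ca[pmax(path_a, 1)])
  row_b <- ifelse(gap_b, "-", cb[pmax(path_b, 1)])
  both <- !gap_a & !gap_b
  identity <- if (any(both)) mean(row_a[both] == row_b[both]) else 0
  n_long <- max(nchar(a), nchar(b))
  longer_path <- if (nchar(a) >= nchar(b)) path_a else path_b
  span <- longer_path[both]
  coverage <- if (length(span)) (max(span) - min(span) + 1) / n_long else 0
  structure(list(aligned_a = paste(row_a, collapse = ""),
                 aligned_b = paste(row_b, collapse = ""),
                 score = score, identity = identity,
                 coverage_longer = coverage),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f  identity %.3f  coverage(longer) %.3f\n",
              x$score, x$identity, x$coverage_longer))
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment with affine gap costs (a gap of length k costs
#' `gap_open + (k-1) * gap_extend`; end gaps are penalized). Ties are broken
#' deterministically: diagonal, then up, then left.
#'
#' @param a,b Protein sequences.
#' @param matrix Substitution matrix, default [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties (ClustalX-like defaults
#'   10 and 0.5).
#' @return An `alignment_result`: gapped sequences, `score`, `identity`
#'   (fraction of residue-residue columns that match) and `coverage_longer`
#'   (aligned span of the longer sequence over its length).
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  ia <- seq_to_idx(a, matrix, "a")
  ib <- seq_to_idx(b, matrix, "b")
  cells <- matrix[ia, ib, drop = FALSE] + 0.0
  r <- gotoh_align_cells(cells, gap_open, gap_extend, local = FALSE)
  align_result(a, b, r$score, r$path_a, r$path_b)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under the same scoring and tie-break conventions
#' as [global_align()]. An all-negative score surface yields the empty
#' alignment with score 0.
#'
#' @inheritParams global_align
#' @return An `alignment_result` (see [global_align()]).
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                        gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  ia <- seq_to_idx(a, matrix, "a")
  ib <- seq_to_idx(b, matrix, "b")
  cells <- matrix[ia, ib, drop = FALSE] + 0.0
  r <- gotoh_align_cells(cells, gap_open, gap_extend, local = TRUE)
  align_result(a, b, r$score, r$path_a, r$path_b)
}

# --- progressive MSA ------------------------------------------------------

# fractional shared 3-mer distance used only for the guide tree
kmer_distance <- function(seqs, k = 3) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- sum(pmin(
      as.numeric(kmers[[i]][names(kmers[[j]])]),
      as.numeric(kmers[[j]])), na.rm = TRUE)
    denom <- max(1, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1)
    d[i, j] <- d[j, i] <- 1 - common / denom
  }
  d
}

msa_profile <- function(rows, matrix) {
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(chars)
  alph <- rownames(matrix)
  f <- matrix(0, length(alph), L, dimnames = list(alph, NULL))
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tt <- table(factor(col, levels = alph))
      f[, j] <- as.numeric(tt) / length(col)
    }
  }
  f
}

merge_profiles <- function(rows_a, rows_b, matrix, gap_open, gap_extend) {
  fa <- msa_profile(rows_a, matrix)
  fb <- msa_profile(rows_b, matrix)
  cells <- t(fa) %*% matrix %*% fb
  r <- gotoh_align_cells(cells, gap_open, gap_extend, local = FALSE)
  expand <- function(rows, path) {
    vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ifelse(path == 0, "-", ch[pmax(path, 1)]), collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  c(expand(rows_a, r$path_a), expand(rows_b, r$path_b))
}

#' Multiple sequence alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @return Object of class `fad_msa` with fields `seqs` and `ncol`.
#' @export
msa_object <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1, !is.null(names(seqs)))
  structure(list(seqs = seqs, ncol = nchar(seqs[[1]])), class = "fad_msa")
}

#' @export
print.fad_msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$seqs), x$ncol))
  invisible(x)
}

# character matrix view of an msa (rows = sequences)
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
}

#' Progressive multiple sequence alignment
#'
#' ClustalX-style progressive alignment: a neighbor-joining guide tree is
#' built on fractional shared 3-mer distances, then profiles are merged by
#' profile-profile global alignment in guide-tree postorder. Deterministic
#' for a given input order.
#'
#' @param seqs Named character vector of at least one protein sequence.
#' @inheritParams global_align
#' @return A `fad_msa` whose rows degap to the inputs.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = 10,
                            gap_extend = 0.5) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) {
    warning("single sequence: returning it unaligned")
    return(msa_object(seqs))
  }
  for (i in seq_along(seqs)) seq_to_idx(seqs[[i]], matrix, names(seqs)[i])
  if (length(seqs) == 2) {
    r <- global_align(seqs[[1]], seqs[[2]], matrix, gap_open, gap_extend)
    return(msa_object(setNames(c(r$aligned_a, r$aligned_b), names(seqs))))
  }
  d <- kmer_distance(seqs)
  tree <- nj_tree(distance_matrix(d))
  merged <- merge_by_tree(tree, seqs, matrix, gap_open, gap_extend)
  msa_object(merged[names(seqs)])
}

# postorder merge of aligned blocks along an ape phylo guide tree
merge_by_tree <- function(tree, seqs, matrix, gap_open, gap_extend) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      return(setNames(seqs[tree$tip.label[node]], tree$tip.label[node]))
    }
    kids <- children[[as.character(node)]]
    blocks <- lapply(kids, rec)
    acc <- blocks[[1]]
    for (b in blocks[-1]) {
      acc <- merge_profiles(acc, b, matrix, gap_open, gap_extend)
    }
    acc
  }
  rec(n_tip + 1L)
}
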