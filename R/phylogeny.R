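# Distance-based phylogeny: p-distances under pairwise deletion, Poisson
# correction, neighbor-joining with a fixed lexicographic tie-break, column
# bootstrap, and anchor-guided subfamily classification. Trees are ape
# "phylo" objects so Newick I/O and plotting come for free.

#' Distance matrix container
#'
#' @param d Symmetric non-negative matrix with zero diagonal and taxon
#'   dimnames.
#' @param p Optional matrix of raw proportions of differing sites.
#' @return Object of class `fad_dist`.
#' @export
distance_matrix <- function(d, p = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix has non-zero diagonal", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  structure(list(taxa = rownames(d), d = d, p = p), class = "fad_dist")
}

#' @export
print.fad_dist <- function(x, ...) {
  cat(sprintf("<distance matrix> %d taxa%s\n", length(x$taxa),
              if (!is.null(x$p)) " (p + corrected d)" else ""))
  invisible(x)
}

#' Pairwise p-distances under pairwise deletion
#'
#' For each sequence pair, alignment columns where either row has a gap are
#' excluded; the p-distance is the fraction of the remaining columns at
#' which the residues differ.
#'
#' @param msa A [msa_object()].
#' @return A [distance_matrix()] with both `p` and (initially uncorrected)
#'   `d` equal to the p-distances.
#' @export
pairwise_p_distance <- function(msa) {
  stopifnot(inherits(msa, "fad_msa"), length(msa$seqs) >= 2)
  m <- msa_matrix(msa)
  n <- nrow(m)
  ids <- names(msa$seqs)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   ids[i], ids[j]), call. = FALSE)
    }
    p[i, j] <- p[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  distance_matrix(p, p = p)
}

#' Poisson correction of p-distances
#'
#' Multiple-hit correction d = -ln(1 - p), applied elementwise. Defined for
#' p < 1 only.
#'
#' @param p A proportion (or vector/matrix of proportions) in \[0, 1), or a
#'   [distance_matrix()] carrying `p`.
#' @return Corrected distance(s) of the same shape; for a `fad_dist` input,
#'   a `fad_dist` with corrected `d`.
#' @export
poisson_correct <- function(p) {
  if (inherits(p, "fad_dist")) {
    if (is.null(p$p)) stop("distance matrix carries no p-distances", call. = FALSE)
    return(distance_matrix(poisson_correct(p$p), p = p$p))
  }
  if (any(p < 0)) stop("p-distance must be non-negative", call. = FALSE)
  if (any(p >= 1)) {
    stop("Poisson correction undefined for p >= 1 (saturated pair)", call. = FALSE)
  }
  -log(1 - p)
}

# representative taxon of a cluster: its lexicographically smallest member
nj_newick <- function(d, labels) {
  n <- nrow(d)
  parts <- labels                      # newick fragment per active cluster
  reps <- labels                       # tie-break representative
  clamped <- 0
  active <- seq_len(n)
  while (length(active) > 3) {
    r <- length(active)
    dd <- d[active, active]
    R <- rowSums(dd)
    Q <- (r - 2) * dd - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(reps[active][cand[, 1]], reps[active][cand[, 2]]),
                 pmax(reps[active][cand[, 1]], reps[active][cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    vi <- dd[pick[1], pick[2]] / 2 +
      (R[pick[1]] - R[pick[2]]) / (2 * (r - 2))
    vj <- dd[pick[1], pick[2]] - vi
    if (vi < 0 || vj < 0) clamped <- clamped + 1
    vi <- max(vi, 0); vj <- max(vj, 0)
    # distances from the new node u to every other active cluster
    new_d <- (d[i, active] + d[j, active] - d[i, j]) / 2
    u <- i # reuse slot i for the merged cluster
    d[u, active] <- new_d
    d[active, u] <- new_d
    d[u, u] <- 0
    parts[u] <- sprintf("(%s:%.10g,%s:%.10g)", parts[i], vi, parts[j], vj)
    reps[u] <- min(reps[i], reps[j])
    active <- setdiff(active, j)
  }
  a <- active
  v <- numeric(3)
  v[1] <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  v[2] <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  v[3] <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  if (any(v < 0)) clamped <- clamped + 1
  v <- pmax(v, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 parts[a[1]], v[1], parts[a[2]], v[2], parts[a[3]], v[3])
  list(newick = nwk, clamped = clamped)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties on Q are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster's smallest member id), so the topology is platform-deterministic.
#' Negative branch lengths are clamped to zero with a message. The returned
#' tree is unrooted (trifurcating root node).
#'
#' @param dm A [distance_matrix()] (its corrected `d` is used) or a plain
#'   symmetric matrix with dimnames; at least 3 taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (!inherits(dm, "fad_dist")) dm <- distance_matrix(dm)
  d <- dm$d
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa", call. = FALSE)
  res <- nj_newick(d, rownames(d))
  if (res$clamped > 0) {
    message(sprintf("nj_tree: clamped %d negative branch length(s) to 0",
                    res$clamped))
  }
  ape::read.tree(text = res$newick)
}

# canonical key of the bipartition induced by the subtree below each
# internal edge: the side NOT containing the reference tip, sorted
bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  ref <- min(tree$tip.label) # canonical side: the one without this taxon
  internal <- setdiff(unique(tree$edge[, 1]), n_tip + 1L)
  keys <- character(0)
  for (node in sort(internal)) {
    tips <- tree$tip.label[subtree_tips(tree, node)]
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) >= 2 && length(side) <= n_tip - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# tip indices below an internal node (tree rooted at n_tip + 1)
subtree_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(nd)]]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  sort(out)
}

#' Bootstrap supports for an alignment's NJ tree
#'
#' Columns of the alignment are resampled with replacement; a
#' Poisson-corrected NJ tree is built per replicate; the support of each
#' internal bipartition of the original tree is the percentage of replicate
#' trees containing it. Fixed seed implies identical supports.
#'
#' @param msa A [msa_object()].
#' @param n_replicates Number of bootstrap replicates (the conventional
#'   full-scale choice is 1000; tests use 100).
#' @param seed Integer seed for the resampling.
#' @return List with `tree` (the original NJ tree, with `node.label`
#'   carrying supports), `supports` (named percentages per bipartition) and
#'   `n_replicates`.
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000, seed = 1) {
  stopifnot(n_replicates >= 1)
  m <- msa_matrix(msa)
  # resampled replicates can saturate a pair (p = 1) even when the original
  # alignment does not; inside the bootstrap such distances are capped at
  # the largest finite correction rather than aborting the replicate
  corrected <- function(msa) {
    dm <- pairwise_p_distance(msa)
    distance_matrix(-log(1 - pmin(dm$p, 1 - 1e-9)), p = dm$p)
  }
  base_tree <- nj_tree(corrected(msa))
  keys <- bipartitions(base_tree)
  counts <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- msa_object(setNames(
        apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
        names(msa$seqs)))
      rep_tree <- suppressMessages(nj_tree(corrected(rep_msa)))
      hit <- keys %in% bipartitions(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / n_replicates
  base_tree$node.label <- node_support_labels(base_tree, supports)
  list(tree = base_tree, supports = supports, n_replicates = n_replicates)
}

node_support_labels <- function(tree, supports) {
  n_tip <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  vapply(nodes, function(node) {
    if (node == n_tip + 1L) return("")
    tips <- tree$tip.label[subtree_tips(tree, node)]
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }, "")
}

#' Classify tree leaves into subfamilies by anchor placement
#'
#' Every unlabeled leaf receives the subfamily of the smallest clade (side
#' of an internal bipartition, on an unrooted tree) that contains the leaf
#' and at least one anchor, provided all anchors in that clade belong to a
#' single subfamily; otherwise the leaf is `"unclassified"`. Anchors keep
#' their own labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param anchor_labels Named character vector: anchor tip id -> subfamily.
#' @return Named character vector of subfamily labels for every tip.
#' @export
classify_subfamilies <- function(tree, anchor_labels) {
  tips <- tree$tip.label
  missing <- setdiff(names(anchor_labels), tips)
  if (length(missing)) {
    stop("anchor(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_tip <- length(tips)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  internal <- sort(unique(tree$edge[, 1]))
  sides <- list()
  for (node in internal) {
    below <- tips[subtree_tips(tree, node)]
    if (node != n_tip + 1L) {
      sides <- c(sides, list(below), list(setdiff(tips, below)))
    }
  }
  for (t in tips) sides <- c(sides, list(setdiff(tips, t)))
  out <- setNames(rep("unclassified", n_tip), tips)
  out[names(anchor_labels)] <- anchor_labels
  for (leaf in setdiff(tips, names(anchor_labels))) {
    # all clades (bipartition sides) holding this leaf and >= 1 anchor
    cand <- Filter(function(s) leaf %in% s &&
                     length(intersect(s, names(anchor_labels))) > 0, sides)
    if (!length(cand)) next
    smallest <- cand[lengths(cand) == min(lengths(cand))]
    labs <- unique(unlist(lapply(smallest, function(s) {
      u <- unique(anchor_labels[intersect(s, names(anchor_labels))])
      if (length(u) == 1) u else "conflict"
    })))
    # equally small clades must agree on a single pure subfamily
    if (length(labs) == 1 && labs != "conflict") out[leaf] <- labs
  }
  out
}

#' Write a tree as Newick
#'
#' Branch lengths kept; bootstrap supports, when present as `node.label`,
#' are written as internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
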