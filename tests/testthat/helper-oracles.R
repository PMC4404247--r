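# Independent oracles used across the suite. Each is written against the
# definition of the quantity, not against the package's algorithm: the
# alignment oracle is a memoized suffix recursion (the package kernel is an
# iterative prefix DP in C++), the pI oracle is a grid scan, the quartet
# oracle is least-squares over all three unrooted topologies, and the
# clustering oracle is a naive agglomeration loop.

# ---- alignment ----------------------------------------------------------
# best score aligning a[i..], b[j..] given the previous column type;
# a gap run of length k costs go + (k-1)*ge, matching the documented
# convention of global_align()/local_align()
oracle_align <- function(a, b, S, go, ge, local = FALSE) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    opts <- if (local) 0 else numeric(0)
    if (!local && i > n && j > m) return(0)
    if (i <= n && j <= m) {
      opts <- c(opts, S[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= n) {
      opts <- c(opts, -(if (last == "x") ge else go) + rec(i + 1, j, "x"))
    }
    if (j <= m) {
      opts <- c(opts, -(if (last == "y") ge else go) + rec(i, j + 1, "y"))
    }
    if (!length(opts)) opts <- if (local) 0 else -Inf
    memo[[key]] <- max(opts)
    memo[[key]]
  }
  if (!local) return(rec(1, 1, "none"))
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- max(best, S[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
  }
  best
}

random_peptide <- function(len, alphabet = fadkit:::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- isoelectric point --------------------------------------------------
oracle_pi_grid <- function(sequence, step = 1e-4) {
  tab <- physchem_table()
  chars <- strsplit(sequence, "")[[1]]
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  grid <- seq(0, 14, by = step)
  charge <- vapply(grid, function(ph) {
    pos <- c(1, counts["K"], counts["R"], counts["H"])
    pos_k <- tab$pka[c("Nterm", "K", "R", "H")]
    neg <- c(1, counts["D"], counts["E"], counts["C"], counts["Y"])
    neg_k <- tab$pka[c("Cterm", "D", "E", "C", "Y")]
    sum(pos / (1 + 10^(ph - pos_k))) - sum(neg / (1 + 10^(neg_k - ph)))
  }, numeric(1))
  grid[which.min(abs(charge))]
}

# ---- quartet least squares ----------------------------------------------
# residual of the best least-squares branch fit of a 4-taxon distance
# matrix to topology (t1,t2)|(t3,t4); columns: v1..v4 tip branches, v5 internal
quartet_ls_residual <- function(d, split) {
  t <- c(split, setdiff(rownames(d), split))
  pairs <- t(combn(4, 2))
  y <- apply(pairs, 1, function(p) d[t[p[1]], t[p[2]]])
  X <- t(apply(pairs, 1, function(p) {
    row <- numeric(5)
    row[p[1]] <- 1; row[p[2]] <- 1
    same_side <- (p[1] <= 2) == (p[2] <= 2)
    if (!same_side) row[5] <- 1
    row
  }))
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

oracle_quartet_topology <- function(d) {
  taxa <- rownames(d)
  splits <- list(taxa[c(1, 2)], taxa[c(1, 3)], taxa[c(1, 4)])
  res <- vapply(splits, quartet_ls_residual, numeric(1), d = d)
  splits[[which.min(res)]]
}

# the pair grouped with taxon 1 in an unrooted 4-taxon tree
quartet_split_of_tree <- function(tree) {
  first <- tree$tip.label[1]
  for (node in setdiff(unique(tree$edge[, 1]),
                       length(tree$tip.label) + 1L)) {
    tips <- tree$tip.label[fadkit:::subtree_tips(tree, node)]
    if (length(tips) == 2) {
      if (first %in% tips) return(sort(tips))
      return(sort(c(first, setdiff(tree$tip.label, c(tips, first)))))
    }
  }
  sort(tree$tip.label[1:2]) # star resolution fallback
}

# ---- naive average-linkage agglomeration --------------------------------
# returns the cophenetic matrix implied by greedy average-linkage merging
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# ---- regex-based histidine-box enumeration ------------------------------
# all (start, end) matches of an H-box pattern, via lookahead regexes; an
# independent route to the package's explicit position loops
regex_box_matches <- function(sequence, lead, gaps, tail) {
  hits <- NULL
  for (g in gaps) {
    pat <- sprintf("(?=([%s].{%d}%s))", lead, g, tail)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] > 0) {
      len <- 1 + g + nchar(tail)
      hits <- rbind(hits, cbind(as.integer(m), as.integer(m) + len - 1L))
    }
  }
  if (!is.null(hits)) hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits
}

# leftmost-greedy box assignment re-derived from the regex enumeration
regex_scan_boxes <- function(sequence, spacing12 = c(25, 40),
                             spacing23 = c(100, 200)) {
  m1 <- regex_box_matches(sequence, "H", 3:4, "H")
  m2 <- regex_box_matches(sequence, "H", 2:3, "HH")
  m3 <- regex_box_matches(sequence, "HQ", 2:3, "HH")
  out <- list(box1 = NULL, box2 = NULL, box3 = NULL)
  if (is.null(m1)) return(out)
  for (k in seq_len(nrow(m1))) {
    b1 <- m1[k, ]
    ok2 <- if (is.null(m2)) logical(0) else
      (m2[, 1] - b1[2] - 1 >= spacing12[1] &
       m2[, 1] - b1[2] - 1 <= spacing12[2])
    if (!any(ok2)) { if (is.null(out$box1)) out$box1 <- b1; next }
    b2 <- m2[which(ok2)[1], ]
    out$box1 <- b1; out$box2 <- b2
    if (!is.null(m3)) {
      ok3 <- m3[, 1] - b2[2] - 1 >= spacing23[1] &
             m3[, 1] - b2[2] - 1 <= spacing23[2]
      if (any(ok3)) out$box3 <- m3[which(ok3)[1], ]
    }
    break
  }
  if (is.null(out$box1)) out$box1 <- m1[1, ]
  out
}

# ---- shared small fixtures ----------------------------------------------
demo_families <- function() {
  list(
    family_spec("Omega", "FAD2", n_members = 3, exon_counts = c(3, 1, 1),
                has_er_motif = TRUE),
    family_spec("Front-end", "SLD", n_members = 2, exon_counts = 1),
    family_spec("Sphingolipid", "DSD", n_members = 2, exon_counts = 2),
    family_spec("First", "FAD5", n_members = 1, exon_counts = 5))
}

demo_duplications <- function() {
  data.frame(family = c("FAD2", "SLD"), member_a = c(2, 1),
             member_b = c(3, 2), type = c("tandem", "segmental"),
             identity = c(0.85, 0.85), coverage = c(1, 1),
             stringsAsFactors = FALSE)
}

demo_genome <- function(seed = 42, n_decoys = 0) {
  gen_genome(sim_plan(seed = seed, n_chromosomes = 5,
                      families = demo_families(),
                      duplications = demo_duplications(),
                      n_decoys = n_decoys))
}
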