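test_that("p-distance under pairwise deletion matches a site-loop oracle", {
  msa <- msa_object(c(a = "AAAA", b = "AAAT", c = "A-AT"))
  dm <- pairwise_p_distance(msa)
  expect_equal(dm$p["a", "b"], 0.25)
  expect_equal(dm$p["a", "c"], 1 / 3) # gap column dropped
  expect_equal(dm$p["a", "a"], 0)

  set.seed(53)
  for (i in 1:10) {
    rows <- vapply(1:4, function(k) {
      ch <- sample(c("A", "C", "G", "-"), 30, replace = TRUE,
                   prob = c(0.3, 0.3, 0.3, 0.1))
      paste(ch, collapse = "")
    }, "")
    names(rows) <- paste0("t", 1:4)
    dm <- pairwise_p_distance(msa_object(rows))
    m <- do.call(rbind, strsplit(rows, ""))
    for (a in 1:3) for (b in (a + 1):4) {
      num <- 0; den <- 0
      for (s in 1:30) {
        if (m[a, s] != "-" && m[b, s] != "-") {
          den <- den + 1
          if (m[a, s] != m[b, s]) num <- num + 1
        }
      }
      expect_equal(dm$p[a, b], num / den)
    }
  }
})

test_that("Poisson correction matches its closed form and dominates p", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2))
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(poisson_correct(p), -log(1 - p))
  expect_true(all(poisson_correct(p) >= p))
  expect_error(poisson_correct(1), "p >= 1")
})

test_that("NJ inverts an additive quartet exactly", {
  # distances generated from tree ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tree <- nj_tree(d)
  expect_identical(quartet_split_of_tree(tree), c("A", "B"))
  # path lengths reproduce the generating distances to 1e-9
  pd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(unname(pd), unname(d), tolerance = 1e-9)
})

test_that("three taxa resolve to the closed-form star", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(unname(pd), unname(d), tolerance = 1e-12)
})

test_that("NJ topology matches least-squares search on random additive quartets", {
  set.seed(59)
  for (i in 1:20) {
    # random additive quartet: two cherries joined by an internal edge
    v <- runif(5, 0.1, 2)
    taxa <- sample(LETTERS[1:4]) # random leaf labelling
    d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    tip <- setNames(v[1:4], taxa)
    pairs <- t(combn(taxa, 2))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      ia <- match(a, taxa); ib <- match(b, taxa)
      same <- (ia <= 2) == (ib <= 2)
      d[a, b] <- d[b, a] <- tip[a] + tip[b] + if (same) 0 else v[5]
    }
    tree <- nj_tree(d)
    got <- quartet_split_of_tree(tree)
    want <- oracle_quartet_topology(d)
    canon <- function(s) if (taxa[1] %in% s) sort(s) else
      sort(setdiff(taxa, s))
    expect_identical(canon(got), canon(want), label = paste("case", i))
  }
})

test_that("NJ agrees with ape's reference implementation on random matrices", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    pts <- matrix(runif(n * 6), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ rejects degenerate input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
})

test_that("clean two-block signal gets 100% support, reproducibly", {
  # two invariant blocks -> every resampled replicate contains the split
  msa <- msa_object(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                      c = "TTTTTTTTTT", d = "TTTTTTTTTT"))
  b1 <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  expect_true(all(b1$supports == 100))
  b2 <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  expect_identical(b1$supports, b2$supports)
  b3 <- bootstrap_supports(msa, n_replicates = 50, seed = 6)
  expect_identical(names(b2$supports), names(b3$supports))
})

test_that("bipartition supports are invariant under leaf reordering", {
  g <- demo_genome()
  seqs <- c(g$proteins[g$genes$id[1:5]], g$anchors["FAD2"])
  msa <- progressive_msa(seqs)
  perm <- msa_object(msa$seqs[c(3, 1, 6, 2, 5, 4)])
  s1 <- bootstrap_supports(msa, 30, seed = 2)$supports
  s2 <- bootstrap_supports(perm, 30, seed = 2)$supports
  expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
})

test_that("subfamily classification recovers planted memberships", {
  g <- demo_genome()
  seqs <- c(g$proteins[g$genes$id], g$anchors)
  msa <- progressive_msa(seqs)
  tree <- nj_tree(poisson_correct(pairwise_p_distance(msa)))
  labs <- setNames(g$anchor_subfamilies, names(g$anchors))
  cls <- classify_subfamilies(tree, labs)
  expect_identical(unname(cls[g$genes$id]), g$genes$subfamily)
  # anchors are fixed points
  expect_identical(cls[names(labs)], labs)
  # idempotence and determinism
  expect_identical(cls, classify_subfamilies(tree, labs))
  expect_error(classify_subfamilies(tree, c(ZZZ = "Omega")), "missing")
})

test_that("a leaf sister to a mixed-anchor clade stays unclassified", {
  tree <- ape::read.tree(text = "((A1:1,B1:1):1,(q:1,o:3):1);")
  cls <- classify_subfamilies(tree, c(A1 = "Alpha", B1 = "Beta"))
  expect_identical(unname(cls["q"]), "unclassified")
})

test_that("Newick output round-trips through ape", {
  g <- demo_genome()
  seqs <- c(g$proteins[g$genes$id[1:5]], g$anchors["FAD2"])
  msa <- progressive_msa(seqs)
  boot <- bootstrap_supports(msa, 20, seed = 3)
  path <- tempfile(fileext = ".nwk")
  write_newick(boot$tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, names(seqs))
  expect_equal(ape::dist.topo(back, boot$tree), 0, ignore_attr = TRUE)
})
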