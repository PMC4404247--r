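test_that("equal Cts give RQ 1 and the ddCt closed form holds", {
  tab <- expand.grid(replicate = 1:3, condition = c("c0", "c1"),
                     gene = c("g1", "UBQ7"), stringsAsFactors = FALSE)
  tab$ct <- 20
  res <- delta_delta_ct(tab, "UBQ7", "c0")
  expect_true(all(res$rq == 1))
  # ddCt = -1 -> RQ = 2
  tab$ct[tab$gene == "g1" & tab$condition == "c1"] <- 19
  res <- delta_delta_ct(tab, "UBQ7", "c0")
  expect_equal(unname(res$rq["g1", "c1"]), 2)
})

test_that("missing reference wells and bad Cts are hard errors", {
  tab <- expand.grid(replicate = 1:2, condition = "c0",
                     gene = c("g1", "UBQ7"), stringsAsFactors = FALSE)
  tab$ct <- 20
  expect_error(delta_delta_ct(tab[-4, ], "UBQ7", "c0"), "reference")
  tab2 <- tab; tab2$ct[1] <- -3
  expect_error(delta_delta_ct(tab2, "UBQ7", "c0"), "positive")
  expect_error(delta_delta_ct(tab, "GAPDH", "c0"), "GAPDH")
  expect_error(delta_delta_ct(tab, "UBQ7", "c9"), "c9")
})

test_that("RQ is invariant only to shifts applied to target and reference alike", {
  design <- matrix(c(1, 2, 1, 0.5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("c0", "c1")))
  plan <- sim_plan(seed = 33, ct_design = design, noise_sd = 0)
  tab <- gen_ct_table(plan)
  res0 <- delta_delta_ct(tab, "UBQ7", "c0")
  # shift every Ct of condition c1 (targets AND reference): RQ unchanged
  both <- tab
  both$ct[both$condition == "c1"] <- both$ct[both$condition == "c1"] + 1.7
  expect_equal(delta_delta_ct(both, "UBQ7", "c0")$rq, res0$rq,
               tolerance = 1e-12)
  # shift only the targets: RQ changes by 2^-shift
  targ <- tab
  sel <- targ$condition == "c1" & targ$gene != "UBQ7"
  targ$ct[sel] <- targ$ct[sel] + 1
  res1 <- delta_delta_ct(targ, "UBQ7", "c0")
  expect_equal(res1$rq[, "c1"], res0$rq[, "c1"] / 2, tolerance = 1e-12)
})

test_that("noisy recovery stays within the expected error envelope", {
  errs <- vapply(1:500, function(s) {
    design <- matrix(c(1, 4), 1, 2, dimnames = list("g", c("c0", "c1")))
    plan <- sim_plan(seed = 5000 + s, ct_design = design, noise_sd = 0.2,
                     n_bio_reps = 3)
    rq <- delta_delta_ct(gen_ct_table(plan), "UBQ7", "c0")$rq["g", "c1"]
    abs(log2(rq / 4))
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})

test_that("identical profiles merge first at distance zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
  cl <- cluster_profiles(m)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- rownames(m)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("a", "b"))
})

test_that("average-linkage clustering matches a naive agglomeration oracle", {
  set.seed(67)
  for (i in 1:6) {
    m <- matrix(rnorm(24), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:4)))
    cl <- cluster_profiles(m, distance = "euclidean")
    d <- as.matrix(dist(m))
    coph_got <- as.matrix(stats::cophenetic(cl$hclust))
    coph_want <- oracle_average_linkage_cophenetic(d)
    dimnames(coph_want) <- dimnames(d)
    expect_equal(coph_got[rownames(d), colnames(d)], coph_want,
                 tolerance = 1e-9)
  }
})

test_that("clustering order is stable under row permutation up to tree isomorphism", {
  set.seed(71)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  cl1 <- cluster_profiles(m)
  cl2 <- cluster_profiles(m[c(4, 2, 5, 1, 3), ])
  c1 <- as.matrix(stats::cophenetic(cl1$hclust))
  c2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(c1[rownames(m), rownames(m)], c2[rownames(m), rownames(m)],
               tolerance = 1e-12)
})

test_that("constant rows are rejected under correlation distances", {
  m <- rbind(flat = c(0, 0, 0), g2 = c(1, 2, 3), g3 = c(3, 1, 0))
  expect_error(cluster_profiles(m), "flat")
  m2 <- rbind(const = c(2, 2, 2), g2 = c(1, 2, 3), g3 = c(3, 1, 0))
  expect_error(cluster_profiles(m2, distance = "correlation"), "const")
})

test_that("response labels follow the documented thresholds", {
  mk_result <- function(log2rq) {
    structure(list(rq = 2^log2rq, log2rq = log2rq, ddct = -log2rq,
                   sd_dct = log2rq * 0, conditions = colnames(log2rq),
                   calibrator = colnames(log2rq)[1]),
              class = "expression_result")
  }
  m <- rbind(up = c(0, 1, 2, 3), flat = c(0, 0, 0, 0),
             slight = c(0, 0.6, 0.2, 0), down = c(0, -0.2, -2, -1),
             sdown = c(0, -0.7, 0, 0))
  colnames(m) <- c("t0", "t3", "t6", "t12")
  labels <- classify_response(mk_result(m))
  expect_identical(unname(labels),
                   c("up", "flat", "slightly-up", "down", "slightly-down"))
  # planted FC course (1, 2, 4, 8) -> up
  fc <- rbind(g = log2(c(1, 2, 4, 8)))
  colnames(fc) <- c("t0", "t3", "t6", "t12")
  expect_identical(unname(classify_response(mk_result(fc))), "up")
})
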