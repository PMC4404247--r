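test_that("planted duplications are recovered with their planted types", {
  g <- demo_genome()
  ev <- find_duplications(g$proteins[g$genes$id], g$models)
  expect_equal(nrow(ev), 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- setNames(ev$type, key(ev$gene_a, ev$gene_b))
  want <- setNames(g$duplications$type,
                   key(g$duplications$gene_a, g$duplications$gene_b))
  expect_identical(got[names(want)], want)
  expect_true(all(ev$identity > 0.8), TRUE)
  expect_true(all(ev$coverage_longer > 0.8))
})

test_that("no planted duplications means no events", {
  plan <- sim_plan(seed = 23, n_chromosomes = 3, families = list(
    family_spec("Omega", "FAD2", n_members = 2),
    family_spec("First", "FAD5", n_members = 1)))
  g <- gen_genome(plan)
  ev <- find_duplications(g$proteins[g$genes$id], g$models)
  expect_equal(nrow(ev), 0)
})

test_that("the >80% thresholds are strict", {
  s <- paste(rep("ACDEF", 20), collapse = "") # 100 residues
  # exactly 80 identical positions out of 100: identity == 0.80 must fail
  chars <- strsplit(s, "")[[1]]
  mut <- chars
  mut[seq(1, 100, by = 5)] <- "W" # 20 substitutions at D-avoiding sites
  t <- paste(mut, collapse = "")
  r <- global_align(s, t)
  expect_equal(r$identity, 0.8, tolerance = 1e-12)
  models <- list(
    a = gene_model("a", "Chr1", "+", 1, 300,
                   data.frame(start = 1, end = 300)),
    b = gene_model("b", "Chr1", "+", 1000, 1300,
                   data.frame(start = 1000, end = 1300)))
  ev <- find_duplications(c(a = s, b = t), models)
  expect_equal(nrow(ev), 0)
})

test_that("pairs below the identity threshold produce no event", {
  plan <- sim_plan(seed = 29, n_chromosomes = 3,
                   families = list(family_spec("Omega", "FAD2", n_members = 2)),
                   duplications = data.frame(
                     family = "FAD2", member_a = 1, member_b = 2,
                     type = "segmental", identity = 0.70, coverage = 1))
  g <- gen_genome(plan)
  ev <- find_duplications(g$proteins[g$genes$id], g$models)
  expect_equal(nrow(ev), 0)
})

test_that("output is independent of input gene order", {
  g <- demo_genome()
  p <- g$proteins[g$genes$id]
  ev1 <- find_duplications(p, g$models)
  ev2 <- find_duplications(rev(p), g$models)
  expect_identical(ev1, ev2)
})

test_that("tightly linked tandem chains collapse to one event", {
  # three near-identical genes adjacent on one chromosome: three passing
  # pairs, one event
  plan <- sim_plan(seed = 31, n_chromosomes = 2, families = list(
    family_spec("Omega", "FAD2", n_members = 3)),
    duplications = data.frame(
      family = "FAD2", member_a = c(1, 2), member_b = c(2, 3),
      type = "tandem", identity = c(0.95, 0.95), coverage = 1))
  g <- gen_genome(plan)
  ev <- find_duplications(g$proteins[g$genes$id], g$models)
  expect_equal(sum(ev$type == "tandem"), 1)
})

test_that("a protein without coordinates is a hard error", {
  g <- demo_genome()
  p <- g$proteins[g$genes$id]
  models <- g$models[-1]
  expect_error(find_duplications(p, models), g$genes$id[1])
})

test_that("recovered events equal planted events over many random plans", {
  types <- c("tandem", "segmental")
  for (i in 1:40) {
    ty <- types[i %% 2 + 1]
    plan <- sim_plan(seed = 1000 + i, n_chromosomes = 3, families = list(
      family_spec("Omega", "FAD2", n_members = 3),
      family_spec("Front-end", "SLD", n_members = 1)),
      duplications = data.frame(
        family = "FAD2", member_a = 1, member_b = 2, type = ty,
        identity = runif(1, 0.84, 0.95), coverage = 1))
    g <- gen_genome(plan)
    ev <- find_duplications(g$proteins[g$genes$id], g$models)
    expect_equal(nrow(ev), 1, label = paste("plan", i))
    expect_identical(ev$type, ty, label = paste("plan", i))
    expect_setequal(c(ev$gene_a, ev$gene_b),
                    c(g$duplications$gene_a, g$duplications$gene_b))
  }
})

test_that("chromosome map lists genes by chromosome and position", {
  g <- demo_genome()
  map <- chromosome_map(g$models)
  expect_equal(nrow(map), nrow(g$genes))
  expect_false(is.unsorted(order(map$chromosome, map$start)))
})
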