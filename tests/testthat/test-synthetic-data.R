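test_that("protein generation is deterministic and sizing errors are informative", {
  spec <- family_spec("Omega", "FAD2", has_er_motif = TRUE)
  p1 <- gen_desaturase_protein(spec, 380, seed = 1)
  p2 <- gen_desaturase_protein(spec, 380, seed = 1)
  expect_identical(p1$sequence, p2$sequence)
  expect_false(identical(
    p1$sequence, gen_desaturase_protein(spec, 380, seed = 2)$sequence))
  expect_equal(scan_histidine_boxes(p1$sequence)$spacing12, 31)
  expect_error(gen_desaturase_protein(spec, 100, seed = 1),
               "minimum feasible length is [0-9]+")
})

test_that("background residues exclude histidine outside planted motifs", {
  p <- gen_desaturase_protein(family_spec("Sphingolipid", "DSD"), seed = 8)
  chars <- strsplit(p$sequence, "")[[1]]
  h_at <- which(chars == "H")
  planted <- c(p$box1[1]:p$box1[2], p$box2[1]:p$box2[2], p$box3[1]:p$box3[2])
  expect_true(all(h_at %in% planted))
})

test_that("genome generation is byte-identical under a fixed seed", {
  g1 <- demo_genome(seed = 42, n_decoys = 5)
  g2 <- demo_genome(seed = 42, n_decoys = 5)
  expect_identical(g1$proteins, g2$proteins)
  expect_identical(g1$cds, g2$cds)
  expect_identical(g1$anchors, g2$anchors)
  d1 <- tempfile(); d2 <- tempfile()
  write_genome(g1, d1); write_genome(g2, d2)
  for (f in c("proteins.fa", "cds.fa", "anchors.fa", "genes.gff3")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted exon counts appear in the GFF3", {
  g <- demo_genome()
  path <- tempfile(); write_gff3(g$models, path)
  models <- read_gff3(path)
  for (k in seq_len(nrow(g$genes))) {
    expect_equal(exon_count(models[[g$genes$id[k]]]), g$genes$exon_count[k])
  }
})

test_that("planted duplicate pairs hit their target identity within 2 points", {
  g <- demo_genome()
  for (k in seq_len(nrow(g$duplications))) {
    r <- global_align(g$proteins[[g$duplications$gene_a[k]]],
                      g$proteins[[g$duplications$gene_b[k]]])
    expect_lt(abs(r$identity - g$duplications$identity[k]), 0.02)
    expect_equal(r$coverage_longer, 1)
  }
})

test_that("tandem pairs are adjacent, segmental pairs on different chromosomes", {
  g <- demo_genome()
  dup <- g$duplications
  tand <- dup[dup$type == "tandem", ]
  m_a <- g$models[[tand$gene_a]]
  m_b <- g$models[[tand$gene_b]]
  expect_identical(m_a$chromosome, m_b$chromosome)
  expect_false(isTRUE(fadkit:::gene_between(m_a, m_b, g$models)))
  seg <- dup[dup$type == "segmental", ]
  expect_false(identical(g$models[[seg$gene_a]]$chromosome,
                         g$models[[seg$gene_b]]$chromosome))
})

test_that("plan validation rejects inconsistent inputs", {
  fams <- list(family_spec("Omega", "FAD2", n_members = 2))
  bad_dup <- data.frame(family = "FAD9", member_a = 1, member_b = 2,
                        type = "tandem", identity = 0.9, coverage = 1)
  expect_error(sim_plan(seed = 1, families = fams, duplications = bad_dup),
               "unknown family")
  bad_member <- data.frame(family = "FAD2", member_a = 1, member_b = 5,
                           type = "tandem", identity = 0.9, coverage = 1)
  expect_error(sim_plan(seed = 1, families = fams, duplications = bad_member),
               "undeclared member")
  seg <- data.frame(family = "FAD2", member_a = 1, member_b = 2,
                    type = "segmental", identity = 0.9, coverage = 1)
  expect_error(sim_plan(seed = 1, n_chromosomes = 1, families = fams,
                        duplications = seg), "chromosomes")
  expect_error(sim_plan(seed = 1, noise_sd = -1), "noise_sd|not TRUE")
  expect_error(family_spec("Omega", "FAD2", box3_lead = "Q"), "Front-end")
})

test_that("Ct tables invert exactly at zero noise and match the noise model", {
  design <- matrix(c(1, 2, 1, 1, 1, 4), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("c0", "c1", "c2")))
  plan <- sim_plan(seed = 12, ct_design = design, noise_sd = 0, n_bio_reps = 3)
  res <- delta_delta_ct(gen_ct_table(plan), "UBQ7", "c0")
  expect_equal(res$rq["g1", "c1"], 2, tolerance = 1e-12)
  expect_equal(res$rq["g2", "c2"], 4, tolerance = 1e-12)
  expect_equal(res$rq[, "c0"], c(g1 = 1, g2 = 1), tolerance = 1e-12)

  # FC = 1 everywhere: all RQ = 1
  flat <- sim_plan(seed = 13, ct_design = matrix(
    1, 2, 2, dimnames = list(c("a", "b"), c("c0", "c1"))), noise_sd = 0)
  expect_true(all(abs(delta_delta_ct(gen_ct_table(flat), "UBQ7", "c0")$rq - 1)
                  < 1e-12))

  # Monte-Carlo at the stated noise: mean recovered RQ within 10% of FC = 4
  fc4 <- matrix(c(1, 4), 1, 2, dimnames = list("g", c("c0", "c1")))
  rqs <- vapply(1:200, function(s) {
    plan <- sim_plan(seed = s, ct_design = fc4, noise_sd = 0.2, n_bio_reps = 3)
    delta_delta_ct(gen_ct_table(plan), "UBQ7", "c0")$rq["g", "c1"]
  }, numeric(1))
  expect_lt(abs(mean(rqs) - 4) / 4, 0.10)
})
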