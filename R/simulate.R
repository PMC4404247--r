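# Synthetic genomes, proteomes and Ct tables with planted, exactly
# recoverable features: histidine boxes at subfamily-specific spacings,
# C-terminal ER-retrieval pentapeptides, N-terminal HPGG (cytochrome b5
# proxy), multi-chromosome GFF3 layouts with tandem/segmental duplicate
# pairs at controlled identity, and qPCR Ct tables with planted fold
# changes under Gaussian noise.
#
# Background residues exclude H (so no spurious histidine boxes can arise)
# and Q (so no spurious Q-opened third box can shift a planted spacing);
# substitutions in duplicate/member copies draw from the same background
# alphabet and avoid planted motif positions, which makes planted-recovery
# tests exact.

BG_ALPHABET <- setdiff(AA20, c("H", "Q"))

SUBFAMILIES <- c("First", "Omega", "Front-end", "Sphingolipid")

subfamily_defaults <- function(subfamily) {
  switch(subfamily,
    "First"        = list(spacing12 = 31, spacing23 = 127, box1_internal = 4,
                          box3_lead = "H", has_cytb5 = FALSE, length = 386),
    "Omega"        = list(spacing12 = 31, spacing23 = 161, box1_internal = 3,
                          box3_lead = "H", has_cytb5 = FALSE, length = 383),
    "Front-end"    = list(spacing12 = 32, spacing23 = 150, box1_internal = 3,
                          box3_lead = "Q", has_cytb5 = TRUE, length = 447),
    "Sphingolipid" = list(spacing12 = 32, spacing23 = 140, box1_internal = 3,
                          box3_lead = "H", has_cytb5 = FALSE, length = 330),
    stop("unknown subfamily: ", subfamily, call. = FALSE))
}

#' Family specification for the synthetic generator
#'
#' One gene cluster of a subfamily (e.g., a FAD2 cluster of the Omega
#' Desaturase subfamily): how many members, their exon counts, and the
#' planted motif geometry. Subfamily defaults encode the field's observed
#' architecture: 31 residues between boxes 1 and 2 in the First and Omega
#' subfamilies versus 32 in Front-end and Sphingolipid; four residues inside
#' box1 for First versus three elsewhere; a glutamine-opened third box and
#' an N-terminal cytochrome-b5 HPGG only in Front-end.
#'
#' @param subfamily One of `"First"`, `"Omega"`, `"Front-end"`,
#'   `"Sphingolipid"`.
#' @param stem Gene-name stem (e.g., `"FAD2"`); also the anchor name.
#' @param n_members Number of genes in the cluster.
#' @param exon_counts Exon count per member (recycled).
#' @param spacing12,spacing23 Residues strictly between consecutive boxes.
#' @param box1_internal Internal residues of box1 (3 or 4).
#' @param box3_lead Opening residue of box3 (`"H"` or `"Q"`; `"Q"` is valid
#'   only for Front-end).
#' @param has_er_motif Plant the C-terminal ER-retrieval pentapeptide.
#' @param has_cytb5 Plant an N-terminal HPGG tetrapeptide.
#' @param length Protein length in residues.
#' @param member_identity Target identity of non-duplicate members to the
#'   cluster founder.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(subfamily, stem, n_members = 1, exon_counts = 1,
                        spacing12 = NULL, spacing23 = NULL,
                        box1_internal = NULL, box3_lead = NULL,
                        has_er_motif = FALSE, has_cytb5 = NULL,
                        length = NULL, member_identity = 0.7) {
  subfamily <- match.arg(subfamily, SUBFAMILIES)
  def <- subfamily_defaults(subfamily)
  spec <- list(
    subfamily = subfamily, stem = stem, n_members = as.integer(n_members),
    exon_counts = rep_len(as.integer(exon_counts), n_members),
    spacing12 = spacing12 %||% def$spacing12,
    spacing23 = spacing23 %||% def$spacing23,
    box1_internal = box1_internal %||% def$box1_internal,
    box3_lead = box3_lead %||% def$box3_lead,
    has_er_motif = has_er_motif,
    has_cytb5 = has_cytb5 %||% def$has_cytb5,
    length = length %||% def$length,
    member_identity = member_identity)
  stopifnot(spec$spacing12 > 0, spec$spacing23 > 0, spec$n_members >= 1)
  if (spec$box3_lead == "Q" && subfamily != "Front-end") {
    stop("a glutamine-opened third box is valid only for the Front-end subfamily",
         call. = FALSE)
  }
  structure(spec, class = "family_spec")
}

#' Simulation plan
#'
#' The full description of a synthetic study: chromosome count, gene
#' clusters, planted duplication events, and the qPCR design (true fold
#' changes, noise, replication). A fixed seed makes every generated artifact
#' byte-identical across runs.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes Number of chromosomes.
#' @param families List of [family_spec()] objects.
#' @param duplications Data frame with columns `family` (stem), `member_a`,
#'   `member_b` (member indices), `type` (`"tandem"` or `"segmental"`),
#'   `identity` (target fraction in (0, 1\]), `coverage` (target fraction in
#'   (0, 1\]); may be NULL.
#' @param ct_design Numeric matrix of true fold changes, genes x conditions
#'   (rownames gene names, colnames conditions; first column is the
#'   calibrator and should be 1).
#' @param noise_sd Gaussian Ct noise, in Ct units (>= 0).
#' @param n_bio_reps Biological replicates per (gene, condition) (>= 1).
#' @param n_decoys Non-desaturase decoy proteins added to the proteome.
#' @return Object of class `sim_plan`.
#' @export
sim_plan <- function(seed, n_chromosomes = 13, families = list(),
                     duplications = NULL, ct_design = NULL, noise_sd = 0.2,
                     n_bio_reps = 3, n_decoys = 0) {
  stopifnot(n_bio_reps >= 1, noise_sd >= 0, n_chromosomes >= 1)
  if (!is.null(ct_design)) stopifnot(all(is.finite(ct_design)))
  if (!is.null(duplications) && nrow(duplications)) {
    stopifnot(all(duplications$identity > 0), all(duplications$identity <= 1),
              all(duplications$coverage > 0), all(duplications$coverage <= 1),
              all(duplications$type %in% c("tandem", "segmental")))
    stems <- vapply(families, `[[`, "", "stem")
    for (k in seq_len(nrow(duplications))) {
      f <- match(duplications$family[k], stems)
      if (is.na(f)) {
        stop("duplication plan references unknown family: ",
             duplications$family[k], call. = FALSE)
      }
      if (duplications$member_b[k] > families[[f]]$n_members ||
          duplications$member_a[k] > families[[f]]$n_members) {
        stop("duplication plan references undeclared member of family ",
             duplications$family[k], call. = FALSE)
      }
    }
    if (any(duplications$type == "segmental") && n_chromosomes < 2) {
      stop("segmental duplications need at least 2 chromosomes", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 families = families, duplications = duplications,
                 ct_design = ct_design, noise_sd = noise_sd,
                 n_bio_reps = as.integer(n_bio_reps),
                 n_decoys = as.integer(n_decoys)),
            class = "sim_plan")
}

min_protein_length <- function(spec) {
  box1_len <- 2 + spec$box1_internal
  40 + box1_len + spec$spacing12 + 5 + spec$spacing23 + 5 + 10
}

#' Generate one synthetic desaturase protein
#'
#' Plants box1, box2 and box3 at exactly the requested spacings (residues
#' strictly between boxes), an N-terminal HPGG when `has_cytb5`, and a
#' C-terminal Phi-X-X-\[KRDE\]-Phi pentapeptide when `has_er_motif`.
#' Non-planted positions are drawn uniformly from the 20 amino acids
#' excluding H (and Q), so the planted architecture is the only one present.
#'
#' @param spec A [family_spec()].
#' @param length Protein length (>= the minimum the geometry needs).
#' @param seed Integer seed; same seed, same sequence.
#' @return List: `sequence`, plus the planted `box1`, `box2`, `box3`
#'   (start, end), `hpgg` start (or NA) and `protected` positions.
#' @export
gen_desaturase_protein <- function(spec, length = spec$length, seed = 1) {
  min_len <- min_protein_length(spec)
  if (length < min_len) {
    stop(sprintf("length %d too small for the requested geometry; minimum feasible length is %d",
                 length, min_len), call. = FALSE)
  }
  with_seed(seed, {
    chars <- sample(BG_ALPHABET, length, replace = TRUE)
    protected <- integer(0)
    hpgg_at <- NA_integer_
    if (spec$has_cytb5) {
      hpgg_at <- 9L
      chars[9:12] <- c("H", "P", "G", "G")
      protected <- c(protected, 9:12)
    }
    plant_box <- function(chars, start, lead, internal, tail_n) {
      idx <- start:(start + 1 + internal + tail_n - 1)
      chars[start] <- lead
      if (tail_n == 1) {
        chars[start + 1 + internal] <- "H"
      } else {
        chars[(start + 1 + internal):(start + internal + tail_n)] <- "H"
      }
      list(chars = chars, idx = idx)
    }
    b1_start <- 41L
    p1 <- plant_box(chars, b1_start, "H", spec$box1_internal, 1L)
    chars <- p1$chars
    b1 <- c(b1_start, b1_start + 1L + spec$box1_internal)
    b2_start <- b1[2] + 1L + spec$spacing12
    p2 <- plant_box(chars, b2_start, "H", 2L, 2L)
    chars <- p2$chars
    b2 <- c(b2_start, b2_start + 4L)
    b3_start <- b2[2] + 1L + spec$spacing23
    p3 <- plant_box(chars, b3_start, spec$box3_lead, 2L, 2L)
    chars <- p3$chars
    b3 <- c(b3_start, b3_start + 4L)
    protected <- c(protected, b1[1]:b1[2], b2[1]:b2[2], b3[1]:b3[2])

    last5 <- (length - 4):length
    if (spec$has_er_motif) {
      chars[last5] <- c(sample(c("F", "Y", "W", "I", "L", "V"), 1),
                        sample(BG_ALPHABET, 2, replace = TRUE),
                        sample(c("K", "R", "D", "E"), 1),
                        sample(c("F", "Y", "W", "I", "L", "V"), 1))
    } else {
      while (grepl("^[FYWILV]..[KRDE][FYWILV]$",
                   paste(chars[last5], collapse = ""))) {
        chars[last5] <- sample(BG_ALPHABET, 5, replace = TRUE)
      }
    }
    protected <- c(protected, last5)

    list(sequence = paste(chars, collapse = ""),
         box1 = b1, box2 = b2, box3 = b3,
         hpgg = hpgg_at, protected = sort(unique(protected)))
  })
}

# substitution-only mutant at a target identity; planted positions untouched
mutate_protein <- function(sequence, identity, protected) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  nsub <- round((1 - identity) * n)
  free <- setdiff(seq_len(n), protected)
  if (nsub > length(free)) {
    stop(sprintf("cannot place %d substitutions with only %d unprotected positions",
                 nsub, length(free)), call. = FALSE)
  }
  at <- sample(free, nsub)
  for (i in at) {
    chars[i] <- sample(setdiff(BG_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# one fixed codon per residue; realism of codon usage is a non-goal
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

protein_to_cds <- function(sequence) {
  paste0(paste(CODON_OF[strsplit(sequence, "")[[1]]], collapse = ""), "TAA")
}

#' Generate a synthetic genome bundle
#'
#' Builds every planted protein (cluster founders de novo, members and
#' duplicate partners by point substitution at target identity), a CDS per
#' gene under a fixed codon map, and a multi-chromosome gene layout in which
#' tandem duplicate pairs sit adjacently on one chromosome with no
#' intervening gene while segmental partners land on different chromosomes.
#' Also emits one anchor protein per cluster (a diverged copy of the
#' founder) for the identification stage.
#'
#' @param plan A [sim_plan()].
#' @return List of class `sim_genome`: `proteins`, `cds`, `anchors` (named
#'   character vectors), `models` (list of [gene_model()]), `genes` (data
#'   frame of ground truth: id, name, family, subfamily, exon count,
#'   chromosome), `duplications` (the planted plan with gene ids filled in),
#'   `architectures` (planted box coordinates per gene).
#' @export
gen_genome <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  with_seed(plan$seed, {
    genes <- list()   # per gene: id, name, family, subfamily, seq, exons
    arch <- list()
    dup_by_family <- list()
    if (!is.null(plan$duplications) && nrow(plan$duplications)) {
      dup_by_family <- split(plan$duplications,
                             plan$duplications$family)
    }
    anchors <- character(0)
    anchor_subfam <- character(0)

    for (spec in plan$families) {
      founder <- gen_desaturase_protein(spec, spec$length,
                                        seed = sample.int(1e6, 1))
      members <- vector("list", spec$n_members)
      members[[1]] <- founder$sequence
      fam_dups <- dup_by_family[[spec$stem]]
      dup_b <- if (!is.null(fam_dups)) fam_dups$member_b else integer(0)
      for (m in seq_len(spec$n_members)[-1]) {
        if (m %in% dup_b) next # filled below from its partner
        members[[m]] <- mutate_protein(founder$sequence,
                                       spec$member_identity,
                                       founder$protected)
      }
      if (!is.null(fam_dups)) {
        for (k in seq_len(nrow(fam_dups))) {
          a <- fam_dups$member_a[k]; b <- fam_dups$member_b[k]
          dup <- mutate_protein(members[[a]], fam_dups$identity[k],
                                founder$protected)
          if (fam_dups$coverage[k] < 1) {
            keep <- ceiling(fam_dups$coverage[k] * nchar(dup))
            dup <- substr(dup, 1, keep)
          }
          members[[b]] <- dup
        }
      }
      anchors[spec$stem] <- mutate_protein(founder$sequence, 0.75,
                                           founder$protected)
      anchor_subfam[spec$stem] <- spec$subfamily
      for (m in seq_len(spec$n_members)) {
        name <- if (spec$n_members == 1) spec$stem else
          sprintf("%s.%d", spec$stem, m)
        genes[[length(genes) + 1]] <- list(
          name = name, family = spec$stem, subfamily = spec$subfamily,
          sequence = members[[m]], exon_count = spec$exon_counts[m],
          member = m)
        arch[[name]] <- founder[c("box1", "box2", "box3", "hpgg")]
      }
    }

    # decoys: background-only proteins, no histidine anywhere
    decoys <- character(0)
    if (plan$n_decoys > 0) {
      decoys <- vapply(seq_len(plan$n_decoys), function(i) {
        paste(sample(BG_ALPHABET, sample(280:460, 1), replace = TRUE),
              collapse = "")
      }, "")
      names(decoys) <- sprintf("Decoy%03d", seq_len(plan$n_decoys))
    }

    # chromosome layout
    n_genes <- length(genes)
    placement <- place_genes(genes, plan)
    ids <- sprintf("Sim.%03dG%04d", placement$chrom, placement$slot * 10)
    for (i in seq_len(n_genes)) genes[[i]]$id <- ids[i]

    models <- list()
    cds <- character(0)
    proteins <- character(0)
    truth <- data.frame(id = ids,
                        name = vapply(genes, `[[`, "", "name"),
                        family = vapply(genes, `[[`, "", "family"),
                        subfamily = vapply(genes, `[[`, "", "subfamily"),
                        exon_count = vapply(genes, function(g) g$exon_count, 1),
                        chromosome = placement$chrom,
                        stringsAsFactors = FALSE)
    for (ch in sort(unique(placement$chrom))) {
      on_ch <- which(placement$chrom == ch)
      on_ch <- on_ch[order(placement$slot[on_ch])]
      pos <- 10001L
      for (i in on_ch) {
        g <- genes[[i]]
        g_cds <- protein_to_cds(g$sequence)
        exlen <- nchar(g_cds)
        k <- g$exon_count
        sizes <- rep(exlen %/% k, k)
        sizes[k] <- sizes[k] + exlen %% k
        starts <- pos + cumsum(c(0L, sizes[-k] + 120L))
        ends <- starts + sizes - 1L
        models[[g$id]] <- gene_model(
          id = g$id, chromosome = sprintf("Chr%02d", ch), strand = "+",
          start = starts[1], end = ends[k],
          exons = data.frame(start = starts, end = ends), cds = g_cds)
        cds[g$id] <- g_cds
        proteins[g$id] <- g$sequence
        pos <- ends[k] + 5000L
      }
    }
    proteins <- c(proteins, decoys)

    dup_truth <- NULL
    if (!is.null(plan$duplications) && nrow(plan$duplications)) {
      dup_truth <- plan$duplications
      name_of <- function(stem, m, specs) {
        f <- plan$families[[match(stem, vapply(plan$families, `[[`, "", "stem"))]]
        if (f$n_members == 1) stem else sprintf("%s.%d", stem, m)
      }
      nm <- vapply(genes, `[[`, "", "name")
      dup_truth$gene_a <- ids[match(
        mapply(name_of, dup_truth$family, dup_truth$member_a), nm)]
      dup_truth$gene_b <- ids[match(
        mapply(name_of, dup_truth$family, dup_truth$member_b), nm)]
    }

    names(arch) <- truth$id[match(names(arch), truth$name)]
    structure(list(proteins = proteins, cds = cds, anchors = anchors,
                   anchor_subfamilies = anchor_subfam, models = models,
                   genes = truth, duplications = dup_truth,
                   architectures = arch),
              class = "sim_genome")
  })
}

# deterministic chromosome/slot assignment honoring the duplication plan
place_genes <- function(genes, plan) {
  n <- length(genes)
  nm <- vapply(genes, `[[`, "", "name")
  fam <- vapply(genes, `[[`, "", "family")
  member <- vapply(genes, function(g) g$member, 1)
  chrom <- rep(NA_integer_, n)
  slot <- rep(NA_integer_, n)
  next_slot <- rep(0L, plan$n_chromosomes)
  rr <- 0L
  partner_of <- rep(NA_integer_, n)
  type_of <- rep(NA_character_, n)
  if (!is.null(plan$duplications) && nrow(plan$duplications)) {
    for (k in seq_len(nrow(plan$duplications))) {
      a <- which(fam == plan$duplications$family[k] &
                 member == plan$duplications$member_a[k])
      b <- which(fam == plan$duplications$family[k] &
                 member == plan$duplications$member_b[k])
      partner_of[b] <- a
      type_of[b] <- plan$duplications$type[k]
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(chrom[i])) next
    rr <- rr %% plan$n_chromosomes + 1L
    chrom[i] <- rr
    next_slot[rr] <- next_slot[rr] + 1L
    slot[i] <- next_slot[rr]
    # place any tandem partner of gene i immediately after it
    tp <- which(partner_of == i & type_of == "tandem")
    for (j in tp) {
      chrom[j] <- chrom[i]
      next_slot[chrom[i]] <- next_slot[chrom[i]] + 1L
      slot[j] <- next_slot[chrom[i]]
    }
    sp <- which(partner_of == i & type_of == "segmental")
    for (j in sp) {
      ch <- chrom[i] %% plan$n_chromosomes + 1L
      chrom[j] <- ch
      next_slot[ch] <- next_slot[ch] + 1L
      slot[j] <- next_slot[ch]
    }
  }
  list(chrom = chrom, slot = slot)
}

#' Default synthetic study conditions
#'
#' The simulation plan the package treats as its reference study: a
#' 13-chromosome genome carrying 19 desaturase genes in the four
#' subfamilies (First 1, Omega 11, Front-end 5, Sphingolipid 2), four
#' planted duplication pairs (one tandem pair inside the FAD2 cluster,
#' three segmental pairs in the Front-end and Sphingolipid subfamilies),
#' the exon-count profile characteristic of the family (eight exons across
#' the FAD3/FAD7/FAD8 cluster, mostly single-exon FAD2 genes with one
#' three-exon outlier, ten exons for FAD6), decoy proteins for the
#' identification screen, and a cold-stress qPCR design over 0/3/6/12 h in
#' which 7 genes are strongly induced and 5 strongly suppressed (the
#' three-exon FAD2 outlier is left out of the expression design, matching
#' its non-expressed, putatively pseudogenic character).
#'
#' @param seed Master seed.
#' @param n_decoys Decoy proteins in the proteome (default 81, giving a
#'   100-protein screening problem).
#' @param noise_sd Ct noise (default 0.2 cycles).
#' @return A [sim_plan()].
#' @export
default_study_plan <- function(seed = 1, n_decoys = 81, noise_sd = 0.2) {
  families <- list(
    family_spec("Omega", "FAD2", n_members = 5,
                exon_counts = c(3, 1, 1, 1, 1), has_er_motif = TRUE),
    family_spec("Omega", "FAD6", n_members = 1, exon_counts = 10),
    family_spec("Omega", "FAD3", n_members = 2, exon_counts = 8),
    family_spec("Omega", "FAD7", n_members = 1, exon_counts = 8),
    family_spec("Omega", "FAD8", n_members = 2, exon_counts = 8),
    family_spec("First", "FAD5", n_members = 1, exon_counts = 5),
    family_spec("Front-end", "SLD", n_members = 5,
                exon_counts = c(1, 1, 3, 1, 1)),
    family_spec("Sphingolipid", "DSD", n_members = 2, exon_counts = 2))
  duplications <- data.frame(
    family = c("FAD2", "DSD", "SLD", "SLD"),
    member_a = c(3, 1, 1, 4), member_b = c(4, 2, 2, 5),
    type = c("tandem", "segmental", "segmental", "segmental"),
    identity = c(0.88, 0.86, 0.87, 0.89), coverage = 1,
    stringsAsFactors = FALSE)
  tp <- c("0h", "3h", "6h", "12h")
  up <- c("FAD8.1", "FAD2.2", "FAD8.2", "SLD.2", "SLD.4", "DSD.1", "SLD.5")
  down <- c("FAD5", "FAD7", "FAD2.3", "SLD.1", "SLD.3")
  flat <- c("FAD2.4", "FAD2.5", "FAD3.1", "FAD3.2", "FAD6", "DSD.2")
  design <- matrix(1, length(c(up, down, flat)), length(tp),
                   dimnames = list(c(up, down, flat), tp))
  design[up, ] <- rep(c(1, 2.5, 4, 6), each = length(up))
  design[down, ] <- rep(c(1, 0.5, 0.3, 0.15), each = length(down))
  sim_plan(seed = seed, n_chromosomes = 13, families = families,
           duplications = duplications, ct_design = design,
           noise_sd = noise_sd, n_bio_reps = 3, n_decoys = n_decoys)
}

#' Write a synthetic genome bundle to disk
#'
#' Standard formats: 60-column-wrapped FASTA for proteins, CDS and anchors;
#' `##gff-version 3` gene models.
#'
#' @param genome A `sim_genome` from [gen_genome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.fa"),
             cds = file.path(dir, "cds.fa"),
             anchors = file.path(dir, "anchors.fa"),
             gff3 = file.path(dir, "genes.gff3"))
  write_fasta(genome$proteins, paths["proteins"])
  write_fasta(genome$cds, paths["cds"])
  write_fasta(genome$anchors, paths["anchors"])
  write_gff3(genome$models, paths["gff3"])
  paths
}

#' Generate a synthetic Ct table
#'
#' Ct(gene, condition, rep) = base_gene - log2(FC) + Normal(0, noise_sd^2),
#' with the reference gene (`UBQ7`, added when absent) at fold change 1
#' everywhere. With `noise_sd = 0`, [delta_delta_ct()] recovers the planted
#' fold changes exactly.
#'
#' @param plan A [sim_plan()] whose `ct_design` is set.
#' @return Data frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  design <- plan$ct_design
  if (is.null(design)) stop("plan has no ct_design", call. = FALSE)
  if (plan$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!("UBQ7" %in% rownames(design))) {
    design <- rbind(design, UBQ7 = rep(1, ncol(design)))
  }
  with_seed(plan$seed + 1L, {
    base <- setNames(runif(nrow(design), 18, 26), rownames(design))
    rows <- expand.grid(replicate = seq_len(plan$n_bio_reps),
                        condition = colnames(design),
                        gene = rownames(design),
                        stringsAsFactors = FALSE)
    fc <- design[cbind(rows$gene, rows$condition)]
    rows$ct <- base[rows$gene] - log2(fc) +
      rnorm(nrow(rows), 0, plan$noise_sd)
    rows[, c("gene", "condition", "replicate", "ct")]
  })
}
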