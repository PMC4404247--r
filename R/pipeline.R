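# End-to-end orchestration: identify -> msa/phylogeny -> motifs ->
# duplications -> exon structure -> expression, with per-stage tables
# written to an output directory and a summary in the shape of a
# per-subfamily count table.

#' Pipeline configuration
#'
#' Collects paths and settings for [run_pipeline()]. All referenced paths
#' must exist when the pipeline runs; missing ones raise a configuration
#' error before any compute.
#'
#' @param proteome,anchors Paths to FASTA files (required).
#' @param gff3 Path to the GFF3 annotation (required for duplication and
#'   structure stages).
#' @param ct_table Optional path to a Ct table; enables the expression
#'   stage.
#' @param anchor_subfamilies Named character vector mapping anchor id to
#'   subfamily.
#' @param ref_gene,calibrator Expression-stage settings.
#' @param min_score,min_identity Screen thresholds, see
#'   [screen_candidates()].
#' @param bootstrap_n,seed Phylogeny settings.
#' @param strong,slight Response-label thresholds, see
#'   [classify_response()].
#' @param name_prefix Species prefix for assigned names.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, anchors, gff3 = NULL, ct_table = NULL,
                            anchor_subfamilies = NULL, ref_gene = "UBQ7",
                            calibrator = NULL, min_score = 100,
                            min_identity = 0.4, bootstrap_n = 100, seed = 1,
                            strong = 1, slight = 0.5, name_prefix = "",
                            out_dir = tempfile("fadkit_report_")) {
  cfg <- list(proteome = proteome, anchors = anchors, gff3 = gff3,
              ct_table = ct_table, anchor_subfamilies = anchor_subfamilies,
              ref_gene = ref_gene, calibrator = calibrator,
              min_score = min_score, min_identity = min_identity,
              bootstrap_n = bootstrap_n, seed = as.integer(seed),
              strong = strong, slight = slight, name_prefix = name_prefix,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the characterization pipeline end to end
#'
#' Identification, naming, alignment + NJ phylogeny with bootstrap,
#' subfamily classification, motif architecture, duplication
#' classification, exon-intron structure, and (when a Ct table is
#' configured) 2^-ddCt expression with profile clustering and response
#' labels. Per-stage tables, the Newick tree and a per-subfamily summary
#' are written under `config$out_dir`; reruns with the same seed produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report` with every stage result and
#'   `files` (the written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c(proteome = config$proteome, anchors = config$anchors)
  optional <- c(gff3 = config$gff3, ct_table = config$ct_table)
  for (nm in names(required)) {
    if (is.null(required[[nm]]) || !file.exists(required[[nm]])) {
      stop("configuration error: missing ", nm, " file: ",
           required[[nm]] %||% "<unset>", call. = FALSE)
    }
  }
  for (nm in names(optional)) {
    if (!is.null(optional[[nm]]) && !file.exists(optional[[nm]])) {
      stop("configuration error: missing ", nm, " file: ", optional[[nm]],
           call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  proteome <- stage("read", read_fasta(config$proteome))
  anchors <- stage("read", read_fasta(config$anchors))
  models <- if (!is.null(config$gff3)) stage("read", read_gff3(config$gff3))

  hits <- stage("identify",
                screen_candidates(proteome, anchors, config$min_score,
                                  config$min_identity))
  named <- stage("identify", assign_names(hits, config$name_prefix))
  accepted <- proteome[named$id]
  files["candidates"] <- write_tsv(hits, out("candidates.tsv"))
  files["names"] <- write_tsv(named, out("accepted_names.tsv"))
  files["accepted_fasta"] <- {
    write_fasta(accepted, out("accepted.fa")); out("accepted.fa")
  }
  ptab <- stage("identify", protein_table(accepted))
  ptab$name <- named$name[match(ptab$id, named$id)]
  files["protein_table"] <- write_tsv(ptab, out("protein_table.tsv"))

  msa <- stage("phylogeny", progressive_msa(c(accepted, anchors)))
  boot <- stage("phylogeny",
                bootstrap_supports(msa, config$bootstrap_n, config$seed))
  subfam <- if (!is.null(config$anchor_subfamilies)) {
    stage("phylogeny",
          classify_subfamilies(boot$tree, config$anchor_subfamilies))
  }
  files["msa"] <- { write_fasta(msa$seqs, out("msa.fa")); out("msa.fa") }
  files["tree"] <- write_newick(boot$tree, out("tree.nwk"))
  if (!is.null(subfam)) {
    files["subfamilies"] <- write_tsv(
      data.frame(id = names(subfam), subfamily = subfam),
      out("subfamilies.tsv"))
  }

  motifs <- stage("motifs", do.call(rbind, lapply(names(accepted), function(id) {
    a <- scan_histidine_boxes(accepted[[id]])
    er <- detect_er_motif(accepted[[id]])
    b5 <- detect_cytb5(accepted[[id]])
    data.frame(id = id,
               box1 = if (is.null(a$box1)) "" else a$box1$text,
               box2 = if (is.null(a$box2)) "" else a$box2$text,
               box3 = if (is.null(a$box3)) "" else a$box3$text,
               spacing12 = a$spacing12, spacing23 = a$spacing23,
               complete = a$complete, er_motif = er$present,
               er_pentapeptide = er$pentapeptide, cytb5 = b5$present,
               stringsAsFactors = FALSE)
  })))
  files["motifs"] <- write_tsv(motifs, out("motifs.tsv"))

  dups <- exons <- NULL
  if (!is.null(models)) {
    dups <- stage("duplication",
                  find_duplications(accepted, models[names(accepted)]))
    files["duplications"] <- write_tsv(dups, out("duplications.tsv"))
    files["chromosome_map"] <- write_tsv(
      chromosome_map(models[names(accepted)]), out("chromosome_map.tsv"))
    exons <- stage("structure", data.frame(
      id = names(accepted),
      exons = vapply(models[names(accepted)], exon_count, 1L),
      row.names = NULL, stringsAsFactors = FALSE))
    files["exons"] <- write_tsv(exons, out("exon_counts.tsv"))
  }

  expr <- clustering <- labels <- NULL
  if (!is.null(config$ct_table)) {
    ct <- stage("expression", read_ct_table(config$ct_table))
    calib <- config$calibrator %||% unique(ct$condition)[1]
    expr <- stage("expression", delta_delta_ct(ct, config$ref_gene, calib))
    labels <- stage("expression",
                    classify_response(expr, config$strong, config$slight))
    clustering <- if (nrow(expr$log2rq) >= 2) {
      tryCatch(cluster_profiles(expr$log2rq), error = function(e) {
        message("expression clustering skipped: ", conditionMessage(e))
        NULL
      })
    }
    files["rq"] <- write_tsv(
      data.frame(gene = rownames(expr$rq), round(expr$rq, 4)),
      out("expression_rq.tsv"))
    files["labels"] <- write_tsv(
      data.frame(gene = names(labels), label = labels),
      out("response_labels.tsv"))
    if (!is.null(clustering)) {
      files["ordered_rq"] <- write_tsv(
        data.frame(gene = rownames(clustering$ordered_matrix),
                   round(clustering$ordered_matrix, 4)),
        out("expression_log2rq_ordered.tsv"))
    }
  }

  summary_tab <- if (!is.null(subfam)) {
    counts <- table(subfam[named$id])
    data.frame(subfamily = names(counts), genes = as.integer(counts),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subfamily = "unclassified", genes = length(accepted))
  }
  files["summary"] <- write_tsv(summary_tab, out("summary.tsv"))
  lines <- c(sprintf("fadkit pipeline report (seed %d)", config$seed),
             sprintf("accepted genes: %d of %d proteome entries",
                     length(accepted), length(proteome)),
             sprintf("bootstrap replicates: %d", config$bootstrap_n),
             "per-subfamily counts:",
             sprintf("  %-14s %d", summary_tab$subfamily, summary_tab$genes))
  writeLines(lines, out("report.txt"))
  files["report"] <- out("report.txt")

  structure(list(hits = hits, named = named, protein_table = ptab,
                 msa = msa, bootstrap = boot, subfamilies = subfam,
                 motifs = motifs, duplications = dups, exons = exons,
                 expression = expr, clustering = clustering,
                 response_labels = labels, summary = summary_tab,
                 files = files, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d accepted genes; outputs in %s\n",
              nrow(x$named), x$config$out_dir))
  print(x$summary)
  invisible(x)
}
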