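# Readers/writers for the standard formats the pipeline consumes, plus the
# per-gene structural accessors. FASTA goes through Biostrings; GFF3 is read
# with a line-aware parser so malformed lines and orphan exons are reported
# with their line numbers.

is_fasta_text <- function(x) {
  length(x) == 1 && grepl("^\\s*>", x)
}

#' Read a protein or nucleotide FASTA file
#'
#' @param input Path to a FASTA file (plain or gzip) or a literal FASTA
#'   string starting with `>`.
#' @return Named character vector of uppercased sequences, in file order.
#'   Names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(input) {
  path <- input
  if (is_fasta_text(input)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Gene model
#'
#' Constructor for the per-gene structural record used by the duplication and
#' exon-structure stages: chromosome, strand, 1-based inclusive gene span,
#' and the ordered exon intervals (5' to 3' on the feature strand).
#'
#' @param id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene coordinates.
#' @param exons Data frame with columns `start`, `end`.
#' @param cds Optional nucleotide string.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chromosome, strand, start, end, exons,
                       cds = NULL) {
  stopifnot(strand %in% c("+", "-"), start <= end,
            all(exons$start <= exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in gene ", id, call. = FALSE)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(id = id, chromosome = chromosome, strand = strand,
                 start = start, end = end, exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s)\n",
              x$id, x$chromosome, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Number of exons of a gene model
#'
#' @param gene A [gene_model()].
#' @return Integer exon count.
#' @export
exon_count <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  nrow(gene$exons)
}

gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon` (and `CDS`) features linked by `Parent`
#' attributes into a list of [gene_model()] objects. Malformed feature lines
#' and exons whose parent cannot be resolved to a gene are reported with
#' their line numbers.
#'
#' @param input Path to a GFF3 file (plain or gzip) or a literal GFF3 string.
#' @return Named list of `gene_model` objects, keyed by gene id.
#' @export
read_gff3 <- function(input) {
  if (length(input) == 1 && grepl("\n", input)) {
    lines <- strsplit(input, "\n", fixed = TRUE)[[1]]
  } else {
    con <- file(input, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) return(list())

  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 rows[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  }
  tab <- data.frame(
    seqid = vapply(fields, `[`, "", 1), type = vapply(fields, `[`, "", 3),
    start = as.integer(vapply(fields, `[`, "", 4)),
    end = as.integer(vapply(fields, `[`, "", 5)),
    strand = vapply(fields, `[`, "", 7),
    attr = vapply(fields, `[`, "", 9), line = rows,
    stringsAsFactors = FALSE)
  tab$id <- vapply(tab$attr, gff3_attr, "", key = "ID")
  tab$parent <- vapply(tab$attr, gff3_attr, "", key = "Parent")

  genes <- tab[tab$type == "gene", ]
  mrnas <- tab[tab$type == "mRNA", ]
  mrna2gene <- setNames(mrnas$parent, mrnas$id)

  exons <- tab[tab$type == "exon", ]
  gene_of_exon <- function(k) {
    p <- exons$parent[k]
    if (!is.na(p) && p %in% genes$id) return(p)
    if (!is.na(p) && p %in% names(mrna2gene)) {
      g <- mrna2gene[[p]]
      if (g %in% genes$id) return(g)
    }
    stop(sprintf("exon at GFF3 line %d has no resolvable gene parent ('%s')",
                 exons$line[k], if (is.na(p)) "" else p), call. = FALSE)
  }
  exon_gene <- vapply(seq_len(nrow(exons)), gene_of_exon, "")

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exon_gene == g$id, , drop = FALSE]
    if (!nrow(ex)) ex <- g # single-exon gene implied by its own span
    gene_model(id = g$id, chromosome = g$seqid, strand = g$strand,
               start = g$start, end = g$end,
               exons = data.frame(start = ex$start, end = ex$end))
  })
  setNames(out, genes$id)
}

#' Write gene models as GFF3
#'
#' Emits `##gff-version 3` with gene/mRNA/exon features (1-based inclusive
#' coordinates) linked by `Parent` attributes.
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in models) {
    ex <- g$exons[order(g$exons$start), , drop = FALSE]
    mrna <- paste0(g$id, ".1")
    lines <- c(lines,
      sprintf("%s\tfadkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome, g$start, g$end, g$strand, g$id),
      sprintf("%s\tfadkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome, g$start, g$end, g$strand, mrna, g$id),
      sprintf("%s\tfadkit\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              g$chromosome, ex$start, ex$end, g$strand, mrna,
              seq_len(nrow(ex)), mrna))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Ct table
#'
#' Tab-delimited text with columns `gene`, `condition`, `replicate`, `ct`.
#'
#' @param input Path (plain or gzip) or literal text with a header line.
#' @return Data frame with the four columns.
#' @export
read_ct_table <- function(input) {
  if (length(input) == 1 && grepl("\n", input)) {
    tab <- utils::read.delim(text = input, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(input, stringsAsFactors = FALSE)
  }
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab[need]
}

#' Write a Ct table
#' @param tab Data frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @param path Output path.
#' @export
write_ct_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary table of identified proteins
#'
#' Length, molecular weight (kDa) and isoelectric point for a set of
#' proteins, in the shape of a gene-family characterization table.
#'
#' @param seqs Named character vector of protein sequences.
#' @param table Constant set, see [physchem_table()].
#' @return Data frame with columns `id`, `length`, `mw_kda`, `pi`.
#' @export
protein_table <- function(seqs, table = physchem_table()) {
  data.frame(
    id = names(seqs),
    length = nchar(seqs),
    mw_kda = round(vapply(seqs, compute_mw, numeric(1), table = table), 2),
    pi = round(vapply(seqs, compute_pi, numeric(1), table = table), 2),
    row.names = NULL, stringsAsFactors = FALSE)
}
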