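# Duplicated-gene classification under the three classical criteria:
# (1) the aligned region covers > 80% of the longer gene, (2) the identity
# of the aligned region is > 80% (both thresholds strict), and (3) tightly
# linked passing pairs count as a single duplication event. A pair is
# tandem iff both genes share a chromosome with no annotated gene between
# them; every other passing pair is segmental.

gene_between <- function(m_a, m_b, models) {
  if (m_a$chromosome != m_b$chromosome) return(NA)
  lo <- min(m_a$end, m_b$end); hi <- max(m_a$start, m_b$start)
  for (m in models) {
    if (m$id %in% c(m_a$id, m_b$id)) next
    if (m$chromosome == m_a$chromosome && m$start > lo && m$end < hi) {
      return(TRUE)
    }
  }
  FALSE
}

#' Find and classify duplicated gene pairs
#'
#' All pairs of the supplied proteins are aligned globally (protein-level
#' by default; the classical criteria do not fix the molecule, and protein
#' alignment is robust to synonymous noise -- pass CDS sequences to work at
#' the nucleotide level). Pairs whose identity and longer-sequence coverage
#' both exceed 0.80 (strictly) become duplication events; chains of tightly
#' linked passing pairs (connected components of the passing-pair graph
#' restricted to adjacency) collapse to one event per cluster, keeping the
#' representative pair with the highest identity.
#'
#' @param proteins Named character vector (ids must have gene models).
#' @param models Named list of [gene_model()] objects.
#' @param min_identity,min_coverage Strict thresholds (defaults 0.80).
#' @param groups Optional named vector mapping protein id to a family
#'   group; when given, only within-group pairs are examined.
#' @param matrix,gap_open,gap_extend See [global_align()].
#' @return Data frame of class `duplication_events`, one row per event:
#'   `gene_a`, `gene_b`, `identity`, `coverage_longer`, `type`
#'   (`"tandem"`/`"segmental"`), `cluster`.
#' @export
find_duplications <- function(proteins, models, min_identity = 0.8,
                              min_coverage = 0.8, groups = NULL,
                              matrix = blosum62(), gap_open = 10,
                              gap_extend = 0.5) {
  ids <- sort(names(proteins)) # output independent of input order
  missing <- ids[!ids %in% names(models)]
  if (length(missing)) {
    stop("protein(s) without gene coordinates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pairs <- NULL
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      if (!is.null(groups) && groups[[a]] != groups[[b]]) next
      r <- global_align(proteins[[a]], proteins[[b]], matrix,
                        gap_open, gap_extend)
      if (r$identity > min_identity && r$coverage_longer > min_coverage) {
        adjacent <- isFALSE(gene_between(models[[a]], models[[b]], models))
        pairs <- rbind(pairs, data.frame(
          gene_a = a, gene_b = b, identity = r$identity,
          coverage_longer = r$coverage_longer,
          type = if (adjacent) "tandem" else "segmental",
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pairs)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage_longer = numeric(0),
                      type = character(0), cluster = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("duplication_events", "data.frame")
    return(out)
  }

  # collapse tightly linked (adjacent) chains to one event per component
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  comp <- setNames(seq_along(nodes), nodes)
  linked <- pairs[pairs$type == "tandem", , drop = FALSE]
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(linked))) {
      a <- linked$gene_a[k]; b <- linked$gene_b[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp %in% c(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed || !nrow(linked)) break
  }
  # tandem chains share a component; every segmental pair is its own event
  pairs$cluster <- ifelse(
    pairs$type == "tandem",
    paste0("t", pmin(comp[pairs$gene_a], comp[pairs$gene_b])),
    paste0("s", seq_len(nrow(pairs))))
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$cluster),
                        function(ix) ix[order(-pairs$identity[ix])][1]),
                 use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  out$cluster <- as.integer(factor(out$cluster))
  rownames(out) <- NULL
  class(out) <- c("duplication_events", "data.frame")
  out
}

#' Chromosome-map summary of gene placement
#'
#' Text analogue of a chromosome localization figure: one row per gene with
#' chromosome and start coordinate, ordered by chromosome then position.
#'
#' @param models Named list of [gene_model()] objects.
#' @return Data frame with `gene`, `chromosome`, `start`, `end`, `strand`.
#' @export
chromosome_map <- function(models) {
  out <- data.frame(
    gene = vapply(models, `[[`, "", "id"),
    chromosome = vapply(models, `[[`, "", "chromosome"),
    start = vapply(models, function(m) m$start, 1),
    end = vapply(models, function(m) m$end, 1),
    strand = vapply(models, `[[`, "", "strand"),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$chromosome, out$start), ]
}
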