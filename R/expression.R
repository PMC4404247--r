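# Relative expression by the 2^-ddCt method, hierarchical clustering of
# expression profiles (uncentered correlation, average linkage), and
# descriptive response labels over a stress time course.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(gene) - Ct(reference gene); per (gene,
#' condition), ddCt = mean dCt(condition) - mean dCt(calibrator) and
#' RQ = 2^-ddCt. Replicates are aggregated as the arithmetic mean of dCt
#' (equivalently the geometric mean of RQ); the replicate standard
#' deviation of dCt is propagated.
#'
#' @param table Data frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (see [read_ct_table()]).
#' @param ref_gene Internal reference gene present in every (condition,
#'   replicate), e.g. `"UBQ7"`.
#' @param calibrator Calibrator condition (e.g., the untreated time point).
#' @return Object of class `expression_result`: `rq` and `log2rq` (gene x
#'   condition matrices), `ddct`, `sd_dct`, `conditions`, `calibrator`.
#' @export
delta_delta_ct <- function(table, ref_gene, calibrator) {
  need <- c("gene", "condition", "replicate", "ct")
  stopifnot(all(need %in% names(table)))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  if (!ref_gene %in% table$gene) {
    stop("reference gene '", ref_gene, "' not in table", call. = FALSE)
  }
  if (!calibrator %in% table$condition) {
    stop("calibrator condition '", calibrator, "' not in table", call. = FALSE)
  }
  conditions <- unique(table$condition)
  genes <- setdiff(unique(table$gene), ref_gene)

  ref <- table[table$gene == ref_gene, ]
  ref_key <- paste(ref$condition, ref$replicate)
  key <- paste(table$condition, table$replicate)
  miss <- unique(key[!key %in% ref_key])
  if (length(miss)) {
    stop("reference gene missing in (condition, replicate): ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  dct_all <- table$ct - ref$ct[match(key, ref_key)]

  mean_dct <- matrix(NA_real_, length(genes), length(conditions),
                     dimnames = list(genes, conditions))
  sd_dct <- mean_dct
  for (g in genes) for (cc in conditions) {
    v <- dct_all[table$gene == g & table$condition == cc]
    if (!length(v)) {
      stop(sprintf("no Ct for gene '%s' in condition '%s'", g, cc),
           call. = FALSE)
    }
    mean_dct[g, cc] <- mean(v)
    sd_dct[g, cc] <- if (length(v) > 1) sd(v) else 0
  }
  ddct <- mean_dct - mean_dct[, calibrator]
  rq <- 2^(-ddct)
  structure(list(rq = rq, log2rq = -ddct, ddct = ddct, sd_dct = sd_dct,
                 conditions = conditions, calibrator = calibrator),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> %d genes x %d conditions (calibrator: %s)\n",
              nrow(x$rq), ncol(x$rq), x$calibrator))
  print(round(x$rq, 3))
  invisible(x)
}

# uncentered (cosine) correlation distance between profile rows
uncentered_correlation_dist <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop("constant zero profile under uncentered-correlation distance: ",
         paste(rownames(m)[norms == 0], collapse = ", "), call. = FALSE)
  }
  s <- (m / norms) %*% t(m / norms)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  as.dist(d)
}

#' Cluster expression profiles
#'
#' Agglomerative clustering of the gene profiles, by default with
#' uncentered-correlation distance and average linkage (the combination
#' popularized by early expression-clustering software), returning the leaf
#' ordering for heat-map rendering.
#'
#' @param m Numeric matrix of profiles (genes x conditions), typically
#'   log2 RQ.
#' @param distance `"uncentered"` (default), `"correlation"` or
#'   `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List of class `profile_clustering`: `order` (gene ids in
#'   dendrogram order), `hclust` (the merge tree), `ordered_matrix`.
#' @export
cluster_profiles <- function(m, distance = c("uncentered", "correlation",
                                             "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(m), nrow(m) >= 2, all(is.finite(m)),
            !is.null(rownames(m)))
  d <- switch(distance,
    uncentered = uncentered_correlation_dist(m),
    correlation = {
      if (any(apply(m, 1, sd) == 0)) {
        stop("constant profile under correlation distance: ",
             paste(rownames(m)[apply(m, 1, sd) == 0], collapse = ", "),
             call. = FALSE)
      }
      as.dist(1 - stats::cor(t(m)))
    },
    euclidean = stats::dist(m))
  hc <- hclust(d, method = linkage)
  structure(list(order = rownames(m)[hc$order], hclust = hc,
                 ordered_matrix = m[hc$order, , drop = FALSE]),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("<profile clustering> leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Label the cold-stress response of each gene
#'
#' Descriptive (not inferential) labels from the extreme log2 relative
#' quantity across the post-calibrator time points: `up` / `down` when
#' |log2 RQ| reaches `strong` (default 1, i.e. two-fold), `slightly-up` /
#' `slightly-down` at `slight` (default 0.5), otherwise `flat`.
#'
#' @param result An [delta_delta_ct()] result whose calibrator is the first
#'   time point.
#' @param strong,slight Thresholds on |log2 RQ|.
#' @return Named character vector of labels, one per gene.
#' @export
classify_response <- function(result, strong = 1, slight = 0.5) {
  stopifnot(inherits(result, "expression_result"), slight <= strong)
  post <- setdiff(colnames(result$log2rq), result$calibrator)
  vapply(rownames(result$log2rq), function(g) {
    v <- result$log2rq[g, post]
    ext <- v[which.max(abs(v))]
    if (ext >= strong) "up"
    else if (ext >= slight) "slightly-up"
    else if (ext <= -strong) "down"
    else if (ext <= -slight) "slightly-down"
    else "flat"
  }, "")
}
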