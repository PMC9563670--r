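#' Bundle a probe-level expression dataset with detection calls
#'
#' Holds the probes-by-samples expression matrix, the matching matrix of
#' Affymetrix detection calls (P/M/A), the probe-to-gene map and the sample
#' metadata. Gene-level quantities are derived once at construction: a gene is
#' called present in a sample when at least one of its probes has call `P`,
#' and its expression is summarized over probes.
#'
#' @param expr Numeric matrix, probes x samples, with dimnames.
#' @param calls Character matrix of identical shape with entries in
#'   `c("P", "M", "A")`.
#' @param probe_map Data frame with columns `probe` and `gene`; every probe in
#'   `expr` must map to at least one gene.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`"pre"`/`"post"`) and optionally `pair_id` plus clinical covariates.
#' @param marginal_present Count `M` calls as present? Default `FALSE`
#'   (marginal treated as absent).
#' @param probe_summary How to summarize multiple probes of a gene into one
#'   expression value per sample: `"max"` (default) or `"mean"`.
#' @return An object of class `detection_dataset` with precomputed
#'   `presence` (genes x samples, logical) and `gene_expr` (genes x samples).
#' @export
detection_dataset <- function(expr, calls, probe_map, samples,
                              marginal_present = FALSE,
                              probe_summary = c("max", "mean")) {
  probe_summary <- match.arg(probe_summary)
  expr <- as.matrix(expr)
  calls <- as.matrix(calls)
  stopifnot(identical(dim(expr), dim(calls)),
            !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (!all(calls %in% c("P", "M", "A"))) {
    stop("detection calls must be 'P', 'M' or 'A'", call. = FALSE)
  }
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "condition") %in% names(samples)))
  if (!all(samples$condition %in% c("pre", "post"))) {
    stop("sample condition must be 'pre' or 'post'", call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(expr))) {
    stop("sample metadata does not match expression columns", call. = FALSE)
  }
  unmapped <- setdiff(rownames(expr), probe_map$probe)
  if (length(unmapped)) {
    stop("probe without gene mapping: ", unmapped[1], call. = FALSE)
  }
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  pm <- probe_map[probe_map$probe %in% rownames(expr), , drop = FALSE]
  genes <- sort(unique(pm$gene))
  present_call <- if (marginal_present) c("P", "M") else "P"
  probe_present <- matrix(calls %in% present_call, nrow = nrow(calls),
                          dimnames = dimnames(calls))

  presence <- matrix(FALSE, length(genes), ncol(expr),
                     dimnames = list(genes, colnames(expr)))
  gene_expr <- matrix(NA_real_, length(genes), ncol(expr),
                      dimnames = list(genes, colnames(expr)))
  probes_by_gene <- split(pm$probe, pm$gene)
  for (gn in genes) {
    pr <- probes_by_gene[[gn]]
    if (length(pr) == 1L) {
      presence[gn, ] <- probe_present[pr, ]
      gene_expr[gn, ] <- expr[pr, ]
    } else {
      presence[gn, ] <- colSums(probe_present[pr, , drop = FALSE]) > 0L
      gene_expr[gn, ] <- if (probe_summary == "max") {
        apply(expr[pr, , drop = FALSE], 2, max)
      } else {
        colMeans(expr[pr, , drop = FALSE])
      }
    }
  }
  structure(
    list(expr = expr, calls = calls, probe_map = probe_map, samples = samples,
         presence = presence, gene_expr = gene_expr,
         marginal_present = marginal_present, probe_summary = probe_summary),
    class = "detection_dataset"
  )
}

#' @export
print.detection_dataset <- function(x, ...) {
  cat("<detection_dataset> ", nrow(x$expr), " probes, ",
      nrow(x$presence), " genes, ", ncol(x$expr), " samples (",
      sum(x$samples$condition == "pre"), " pre / ",
      sum(x$samples$condition == "post"), " post)\n", sep = "")
  invisible(x)
}

#' Gene-level presence matrix
#'
#' @param ds A [detection_dataset()].
#' @return Logical genes x samples matrix; `TRUE` where at least one probe of
#'   the gene is called present in the sample.
#' @export
gene_presence <- function(ds) {
  stopifnot(inherits(ds, "detection_dataset"))
  ds$presence
}

#' McNemar's test on discordant presence counts
#'
#' For paired pre/post samples, `b` counts pairs where a gene is present
#' before but absent after, and `c` the reverse. The statistic is
#' `(b - c)^2 / (b + c)` (no continuity correction by default) with a
#' chi-square reference on 1 df. When `b + c = 0` there is no discordance and
#' the statistic is 0 with p = 1.
#'
#' @param b,c Nonnegative discordant-pair counts (vectorized).
#' @param correction Apply the continuity correction `(|b - c| - 1)^2`?
#' @return List with numeric vectors `chi2` and `p_value`.
#' @examples
#' mcnemar_stat(5, 1)$chi2  # 16/6
#' @export
mcnemar_stat <- function(b, c, correction = FALSE) {
  if (any(b < 0) || any(c < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- b + c
  d <- abs(b - c)
  if (correction) d <- pmax(d - 1, 0)
  chi2 <- ifelse(n == 0, 0, d^2 / n)
  p <- ifelse(n == 0, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = unname(chi2), p_value = unname(p))
}

#' Pearson chi-square test on a 2x2 presence-by-condition table
#'
#' @param tab 2x2 numeric matrix of counts (presence status by condition).
#' @param correction Apply Yates' continuity correction? Default `FALSE`.
#' @return List with `chi2` and `p_value`. A table with a zero margin gives
#'   `chi2 = 0`, `p = 1`; an all-zero table is an error.
#' @examples
#' chisq_presence(matrix(c(30, 10, 10, 30), 2))$chi2  # 20
#' @export
chisq_presence <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(tab)
  if (n == 0) stop("all-zero table", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(chi2 = 0, p_value = 1))
  }
  d <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
  if (correction) d <- max(d - n / 2, 0)
  chi2 <- n * d^2 / prod(rs, cs)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Log2 fold change of mean expression, post over pre
#'
#' A fold change above one (positive log fold change) indicates upregulation
#' after treatment. Expression values are floored before the ratio to guard
#' against nonpositive background-corrected intensities.
#'
#' @param expr_pre,expr_post Mean expression in each condition (vectorized).
#' @param floor Lower bound applied to both means before the log ratio.
#' @return Numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(expr_pre, expr_post, floor = 1) {
  pre <- pmax(expr_pre, floor)
  post <- pmax(expr_post, floor)
  if (any(pre <= 0) || any(post <= 0)) {
    stop("nonpositive mean expression after flooring", call. = FALSE)
  }
  log2(post / pre)
}

#' Per-gene presence-based differential expression statistics
#'
#' Computes, for every gene, the log2 fold change of summarized expression
#' (post over pre) and a presence-shift test: McNemar's test on discordant
#' pairs in paired mode, Pearson's chi-square on the 2x2 presence-by-condition
#' table in unpaired mode.
#'
#' @param ds A [detection_dataset()].
#' @param paired Use the paired (McNemar) test? Requires complete `pair_id`s
#'   (one pre and one post sample per pair).
#' @param p_threshold Significance threshold for the `is_de` flag.
#' @param expr_floor Floor applied to mean expression before the log ratio.
#' @param correction Continuity correction for the presence test.
#' @param samples Optional replacement sample metadata (same sample ids);
#'   used internally to score permuted condition labels without rebuilding
#'   the dataset.
#' @return Data frame with columns `gene`, `delta_e`, `chi2`, `p_value`,
#'   `is_de`, `direction`.
#' @export
gene_stats <- function(ds, paired = TRUE, p_threshold = 0.05,
                       expr_floor = 1, correction = FALSE, samples = NULL) {
  stopifnot(inherits(ds, "detection_dataset"))
  smp <- if (is.null(samples)) ds$samples else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    stopifnot(setequal(samples$sample_id, colnames(ds$expr)))
    samples[match(colnames(ds$expr), samples$sample_id), , drop = FALSE]
  }
  pre_ids <- smp$sample_id[smp$condition == "pre"]
  post_ids <- smp$sample_id[smp$condition == "post"]
  if (!length(pre_ids) || !length(post_ids)) {
    stop("need samples in both conditions", call. = FALSE)
  }
  P <- ds$presence
  E <- ds$gene_expr

  if (paired) {
    if (!"pair_id" %in% names(smp) || anyNA(smp$pair_id)) {
      stop("paired mode requires complete pair_id metadata", call. = FALSE)
    }
    pairs <- split(seq_len(nrow(smp)), smp$pair_id)
    ok <- vapply(pairs, function(i) {
      length(i) == 2L && setequal(smp$condition[i], c("pre", "post"))
    }, logical(1))
    if (!all(ok)) {
      stop("each pair must have exactly one pre and one post sample",
           call. = FALSE)
    }
    pre_of <- vapply(pairs, function(i) smp$sample_id[i][smp$condition[i] == "pre"],
                     character(1))
    post_of <- vapply(pairs, function(i) smp$sample_id[i][smp$condition[i] == "post"],
                      character(1))
    Ppre <- P[, pre_of, drop = FALSE]
    Ppost <- P[, post_of, drop = FALSE]
    b <- rowSums(Ppre & !Ppost)
    cc <- rowSums(!Ppre & Ppost)
    test <- mcnemar_stat(b, cc, correction = correction)
  } else {
    x_pre <- rowSums(P[, pre_ids, drop = FALSE])
    x_post <- rowSums(P[, post_ids, drop = FALSE])
    n_pre <- length(pre_ids); n_post <- length(post_ids)
    a <- x_pre; bb <- x_post; cc2 <- n_pre - x_pre; d <- n_post - x_post
    n <- n_pre + n_post
    det <- abs(a * d - bb * cc2)
    if (correction) det <- pmax(det - n / 2, 0)
    denom <- (a + bb) * (cc2 + d) * n_pre * n_post
    chi2 <- ifelse(denom == 0, 0, n * det^2 / denom)
    test <- list(chi2 = chi2,
                 p_value = ifelse(denom == 0, 1,
                                  stats::pchisq(chi2, 1, lower.tail = FALSE)))
  }

  delta_e <- log_fold_change(
    rowMeans(E[, pre_ids, drop = FALSE]),
    rowMeans(E[, post_ids, drop = FALSE]),
    floor = expr_floor
  )
  data.frame(
    gene = rownames(P),
    delta_e = unname(delta_e),
    chi2 = unname(test$chi2),
    p_value = unname(test$p_value),
    is_de = unname(test$p_value < p_threshold),
    direction = ifelse(delta_e > 0, "up", ifelse(delta_e < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric overlap test between two gene lists
#'
#' Tests whether two gene sets drawn from a common universe share at least the
#' observed number of genes, using the upper-tail hypergeometric probability.
#'
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @param universe_size Size of the common gene universe.
#' @return List with `overlap` (count) and `p_value`.
#' @export
overlap_test <- function(genes_a, genes_b, universe_size) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  if (universe_size < max(length(genes_a), length(genes_b))) {
    stop("universe smaller than a gene set", call. = FALSE)
  }
  k <- length(intersect(genes_a, genes_b))
  p <- stats::phyper(k - 1, length(genes_a),
                     universe_size - length(genes_a),
                     length(genes_b), lower.tail = FALSE)
  list(overlap = k, p_value = p)
}
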