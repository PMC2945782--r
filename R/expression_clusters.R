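# CD2314-specific expression clustering: Welch contrasts against every
# other arm at the same time point, per-contrast BH control, and
# direction-consistent intersection into five clusters.

#' Welch two-sample t-test with degenerate-variance conventions
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Zero-variance pairs are handled by a
#' stated convention rather than dropped: equal means give `t = 0, p = 1`;
#' unequal means with no within-group variance are treated as maximally
#' significant (`p = 0`) with the sign of the mean difference, and flagged
#' `degenerate`.
#'
#' @param group_a,group_b numeric replicate vectors, each of length >= 2.
#' @return a list with `t_statistic`, `p_value`, `direction`
#'   (sign of `mean(group_a) - mean(group_b)`), `df`, and `degenerate`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(7, 8, 9))
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    stop("non-finite input")
  }
  res <- row_welch(matrix(group_a, nrow = 1L), matrix(group_b, nrow = 1L))
  lapply(res, `[`, 1L)
}

# Vectorized row-wise Welch test: a, b are genes x replicates matrices.
row_welch <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  direction <- sign(diff)
  degenerate <- se2 == 0
  t_stat <- ifelse(degenerate, ifelse(diff == 0, 0, Inf * direction),
                   diff / sqrt(pmax(se2, .Machine$double.xmin)))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) +
                          v2^2 / (n2^2 * (n2 - 1L))))
  p <- ifelse(degenerate, ifelse(diff == 0, 1, 0),
              2 * pt(-abs(t_stat), df))
  list(t_statistic = t_stat, p_value = p, direction = direction,
       df = df, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Rejects all hypotheses with `p <= p[(k*)]` where `k*` is the largest
#' rank `k` with `p[(k)] <= k * q / m`.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return a logical rejection vector aligned with `p_values`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value list")
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  p.adjust(p_values, method = "BH") <= q
}

# Moderated two-sample contrast: per-gene pooled variances are shrunk
# toward a common prior by empirical Bayes (limma::squeezeVar), and the t
# statistic gains the prior degrees of freedom. With 3 replicates per arm
# a plain Welch test carries only 2-4 estimated df, which caps the
# attainable significance no matter how large the effect; moderation
# restores power exactly as in standard microarray practice.
row_moderated <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  df_resid <- n1 + n2 - 2L
  v_pooled <- (rowSums((a - m1)^2) + rowSums((b - m2)^2)) / df_resid
  sq <- limma::squeezeVar(v_pooled, df = df_resid)
  se <- sqrt(sq$var.post * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_stat <- diff / se
  df <- df_resid + sq$df.prior
  list(t_statistic = t_stat, p_value = 2 * pt(-abs(t_stat), df),
       direction = sign(diff), df = rep(df, length(t_stat))[seq_along(t_stat)],
       degenerate = rep(FALSE, length(t_stat)))
}

#' Run all CD2314 contrasts at days 6 and 11
#'
#' For each time point in `{d6, d11}` and each comparator arm in
#' `{control, BIO, CD2314+BIO}`, tests CD2314 against the comparator
#' gene-by-gene, then applies BH control at level `fdr_q` *within* each
#' (time point, comparator) family across genes. Day 3 samples are
#' carried in the matrix but never tested, as no treatment arms exist at
#' day 3.
#'
#' The default test moderates per-gene variances by empirical-Bayes
#' shrinkage across genes ([limma::squeezeVar()]), the standard
#' microarray practice for three-replicate designs; `method = "welch"`
#' uses the plain unequal-variance Welch test instead (see
#' [welch_t_test()] for its degenerate-variance conventions).
#'
#' @param mat genes x samples matrix with dimnames.
#' @param design design data.frame (`sample_id`, `time_point`,
#'   `treatment`).
#' @param fdr_q per-family BH level (default 0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return a data.frame of contrast results: `gene_id`, `time_point`,
#'   `comparator`, `t_statistic`, `p_value`, `direction`, `degenerate`,
#'   `fdr_significant`.
#' @export
run_contrasts <- function(mat, design, fdr_q = 0.05,
                          method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  comparators <- c("control", "BIO", "CD2314+BIO")
  out <- list()
  for (tp in c("d6", "d11")) {
    cd_cols <- design$sample_id[design$time_point == tp &
                                  design$treatment == "CD2314"]
    if (length(cd_cols) < 2L) stop("missing CD2314 replicates at ", tp)
    a <- mat[, cd_cols, drop = FALSE]
    for (cmp in comparators) {
      cmp_cols <- design$sample_id[design$time_point == tp &
                                     design$treatment == cmp]
      if (length(cmp_cols) < 2L) {
        stop("missing comparator result: ", cmp, " at ", tp)
      }
      b <- mat[, cmp_cols, drop = FALSE]
      w <- if (method == "moderated") row_moderated(a, b) else row_welch(a, b)
      out[[paste(tp, cmp)]] <- data.frame(
        gene_id = rownames(mat), time_point = tp, comparator = cmp,
        t_statistic = w$t_statistic, p_value = w$p_value,
        direction = w$direction, degenerate = w$degenerate,
        fdr_significant = bh_fdr(w$p_value, fdr_q),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign genes to the five CD2314-specific clusters
#'
#' A gene is CD2314-specific at a time point iff it is FDR-significant
#' against *all three* comparators there with an identical direction.
#' Day-6-only up -> cluster 1, day-6-only down -> cluster 2, day-11-only
#' up -> 3, day-11-only down -> 4; specific at both days with the same
#' direction -> 5. Genes specific at both days with discordant directions,
#' or specific nowhere, get no cluster.
#'
#' @param contrasts a contrast table from [run_contrasts()].
#' @param cluster5 `"same_direction"` (default; up-up or down-down both
#'   qualify for cluster 5) or `"up_only"` (only up-up genes enter
#'   cluster 5; down-down genes get no cluster).
#' @return a data.frame `gene_id`, `cluster` (integer 1-5 or `NA`).
#' @export
assign_clusters <- function(contrasts,
                            cluster5 = c("same_direction", "up_only")) {
  cluster5 <- match.arg(cluster5)
  genes <- unique(contrasts$gene_id)
  spec_dir <- function(tp) {
    sub <- contrasts[contrasts$time_point == tp, ]
    cnt <- table(factor(sub$gene_id, levels = genes))
    if (any(cnt != 3L)) {
      stop("expected results for exactly 3 comparators per gene at ", tp)
    }
    hit <- sub$fdr_significant & sub$direction != 0
    by_gene <- split(data.frame(hit = hit, dir = sub$direction),
                     factor(sub$gene_id, levels = genes))
    vapply(by_gene, function(g) {
      if (all(g$hit) && length(unique(g$dir)) == 1L) g$dir[1] else 0
    }, numeric(1))
  }
  d6 <- spec_dir("d6")
  d11 <- spec_dir("d11")
  cluster <- rep(NA_integer_, length(genes))
  cluster[d6 == 1 & d11 == 0] <- 1L
  cluster[d6 == -1 & d11 == 0] <- 2L
  cluster[d6 == 0 & d11 == 1] <- 3L
  cluster[d6 == 0 & d11 == -1] <- 4L
  both_same <- d6 != 0 & d6 == d11
  if (cluster5 == "same_direction") {
    cluster[both_same] <- 5L
  } else {
    cluster[both_same & d6 == 1] <- 5L
  }
  data.frame(gene_id = genes, cluster = cluster, stringsAsFactors = FALSE)
}

#' Relative expression by the delta-Ct method
#'
#' Returns `2^-(ct_target - mean(ct_refs))`: normalization to the
#' geometric mean of the reference-gene expression levels, since the
#' geometric mean of `2^-Ct` values equals `2^-(arithmetic mean Ct)`.
#'
#' @param ct_target qPCR cycle-threshold value of the target gene.
#' @param ct_refs cycle-threshold values of the reference genes
#'   (typically three housekeeping genes).
#' @return the relative expression level.
#' @export
#' @examples
#' qpcr_relative_expression(25, c(20, 21, 22))  # 2^-4 = 0.0625
qpcr_relative_expression <- function(ct_target, ct_refs) {
  if (length(ct_refs) == 0L) stop("empty reference list")
  stopifnot(is.finite(ct_target), all(is.finite(ct_refs)))
  2^-(ct_target - mean(ct_refs))
}
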