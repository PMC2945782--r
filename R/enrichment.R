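# Score-threshold-optimized hypergeometric enrichment of motifs in a
# promoter cluster against all other promoters.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` marked promoters in a draw of `n` from a
#' universe of `N` containing `K` marked, evaluated with
#' [stats::phyper()] (log-space internally, numerically stable).
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return the upper-tail p-value in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    stop("inconsistent counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Optimize the score threshold for fold enrichment
#'
#' Sweeps every distinct observed score as a candidate threshold
#' (`"scoring over"` means `score >= threshold`, so the sweep is
#' exhaustive). For a candidate `t`, `k` cluster promoters and `K`
#' universe promoters score at or above `t`, the fold enrichment is
#' `(k / n) / ((K - k) / (N - n))` (cluster proportion over the
#' proportion among all *other* promoters; infinite when `K = k`), and
#' the hypergeometric upper-tail p is Bonferroni-multiplied by
#' `correction_factor`. Among candidates with corrected p below `alpha`,
#' the fold-maximizing threshold wins (ties to the larger threshold);
#' `NULL` is returned when no candidate passes both the p criterion and
#' `min_fold`. Promoters with `NA` scores (ineligible under the
#' conservation mode) count toward `n` and `N` but never score over any
#' threshold.
#'
#' @param cluster_scores numeric scores of the cluster promoters (`NA`
#'   allowed).
#' @param background_scores scores of all other promoters in the universe.
#' @param alpha significance level on the corrected p (default 0.01).
#' @param correction_factor Bonferroni multiplier (>= 1).
#' @param min_fold minimum fold enrichment to report (default 1.8).
#' @return `NULL`, or a one-row data.frame with `threshold`, `k`, `n`,
#'   `K`, `N`, `fold`, `p_raw`, `p_bonferroni`.
#' @export
optimize_threshold <- function(cluster_scores, background_scores,
                               alpha = 0.01, correction_factor = 1,
                               min_fold = 1.8) {
  if (length(cluster_scores) == 0L || length(background_scores) == 0L) {
    stop("empty cluster or background")
  }
  stopifnot(correction_factor >= 1, alpha > 0, min_fold >= 0)
  n <- length(cluster_scores)
  N <- n + length(background_scores)
  cl <- cluster_scores[!is.na(cluster_scores)]
  bg <- background_scores[!is.na(background_scores)]
  cand <- sort(unique(c(cl, bg)))
  if (length(cand) == 0L) return(NULL)
  # counts at or above each candidate threshold
  k <- n - findInterval(cand, sort(cl), left.open = TRUE) -
    (n - length(cl))
  Kbg <- length(bg) - findInterval(cand, sort(bg), left.open = TRUE)
  K <- k + Kbg
  p_raw <- hypergeom_upper_tail(k, K, n, N)
  p_bonf <- pmin(1, p_raw * correction_factor)
  fold <- ifelse(Kbg == 0, Inf, (k / n) / (Kbg / (N - n)))
  pass_p <- p_bonf < alpha
  if (!any(pass_p)) return(NULL)
  idx <- which(pass_p)
  # maximize fold; ties -> larger threshold (cand is sorted ascending)
  best <- idx[fold[idx] == max(fold[idx])]
  best <- best[length(best)]
  if (fold[best] < min_fold) return(NULL)
  data.frame(threshold = cand[best], k = k[best], n = n, K = K[best],
             N = N, fold = fold[best], p_raw = p_raw[best],
             p_bonferroni = p_bonf[best])
}

#' Motif enrichment in promoter clusters across conservation modes
#'
#' For each motif, runs [optimize_threshold()] independently under every
#' conservation mode, keeps the mode with the best over-representation
#' (lowest raw p; ties broken by higher fold), and emits one record per
#' motif whose best mode passes both the corrected-p and fold criteria.
#' The default Bonferroni factor is the number of PWMs tested times the
#' number of conservation modes.
#'
#' @param scores a `promoter_scores` object from [scan_promoters()].
#' @param cluster_ids promoter/gene ids forming the tested cluster; must
#'   all be present in the score universe.
#' @param alpha corrected-p significance level (default 0.01).
#' @param min_fold minimum fold enrichment (default 1.8).
#' @param correction_factor Bonferroni multiplier; defaults to
#'   `n_pwms * n_modes`.
#' @param tf_family optional named character vector mapping motif ids to
#'   TF family labels.
#' @return a data.frame with one row per reported motif: `motif_id`,
#'   `tf_family`, `conservation`, `threshold`, `k`, `n`, `K`, `N`,
#'   `fold`, `p_raw`, `p_bonferroni`, sorted by `p_raw`.
#' @export
enrich_clusters <- function(scores, cluster_ids, alpha = 0.01,
                            min_fold = 1.8, correction_factor = NULL,
                            tf_family = NULL) {
  stopifnot(inherits(scores, "promoter_scores"))
  universe <- dimnames(scores$score)[[1]]
  if (!all(cluster_ids %in% universe)) {
    stop("cluster not contained in universe")
  }
  in_cluster <- universe %in% cluster_ids
  motifs <- dimnames(scores$score)[[2]]
  modes <- dimnames(scores$score)[[3]]
  correction_factor <- correction_factor %||%
    (length(motifs) * length(modes))
  out <- list()
  for (mo in motifs) {
    best <- NULL
    best_mode <- NA_character_
    for (md in modes) {
      v <- scores$score[, mo, md]
      rec <- optimize_threshold(v[in_cluster], v[!in_cluster],
                                alpha = alpha,
                                correction_factor = correction_factor,
                                min_fold = min_fold)
      if (is.null(rec)) next
      if (is.null(best) || rec$p_raw < best$p_raw ||
          (rec$p_raw == best$p_raw && rec$fold > best$fold)) {
        best <- rec
        best_mode <- md
      }
    }
    if (!is.null(best)) {
      fam <- if (!is.null(tf_family) && mo %in% names(tf_family)) {
        tf_family[[mo]]
      } else NA_character_
      out[[mo]] <- cbind(
        data.frame(motif_id = mo, tf_family = fam,
                   conservation = best_mode, stringsAsFactors = FALSE),
        best
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_id = character(), tf_family = character(),
                      conservation = character(), threshold = numeric(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p_raw = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$p_raw, -res$fold), ]
  rownames(res) <- NULL
  res
}
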