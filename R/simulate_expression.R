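# Seeded simulator for the nine-condition expression design.

#' The nine-condition, three-replicate expression design
#'
#' Day 3 carries a single untreated arm; days 6 and 11 each carry four
#' treatment arms (control, CD2314, BIO, CD2314+BIO). Every condition has
#' three biological replicates, giving 27 samples.
#'
#' @return a data.frame with columns `sample_id`, `time_point`
#'   (`d3`/`d6`/`d11`) and `treatment`.
#' @export
default_design <- function() {
  conds <- rbind(
    data.frame(time_point = "d3", treatment = "control"),
    expand.grid(time_point = c("d6", "d11"),
                treatment = c("control", "CD2314", "BIO", "CD2314+BIO"),
                stringsAsFactors = FALSE)
  )
  df <- conds[rep(seq_len(nrow(conds)), each = 3L), ]
  df$replicate <- rep(1:3, times = nrow(conds))
  df$sample_id <- sprintf("%s.%s.r%d", df$time_point,
                          gsub("\\+", "_", df$treatment), df$replicate)
  rownames(df) <- NULL
  df[, c("sample_id", "time_point", "treatment", "replicate")]
}

#' Build a ground-truth table of planted differential genes
#'
#' Genes are laid out deterministically: the first `5 * n_per_cluster`
#' genes are planted into clusters 1-5 (up at day 6, down at day 6, up at
#' day 11, down at day 11, up at both days), the next `n_partial` genes
#' receive the day-6 effect in the CD2314 arm *and* in one comparator arm
#' (so they differ from only two of the three comparators and must never be
#' assigned a cluster), and the remainder are null.
#'
#' @param n_genes total number of genes.
#' @param n_per_cluster planted genes per cluster.
#' @param effect absolute log2 effect size of planted genes.
#' @param noise_sd log2-scale replicate noise standard deviation.
#' @param n_partial number of shared-effect (two-of-three-comparator) genes.
#' @param shared_with comparator arm that shares the effect of partial genes.
#' @return a data.frame with one row per gene: `gene_id`, `planted_cluster`
#'   (1-5 or `NA`), `effect_day6`, `effect_day11`, `noise_sd`,
#'   `shared_with` (`NA` or a comparator treatment).
#' @export
make_expression_truth <- function(n_genes, n_per_cluster = 200L,
                                  effect = 2.0, noise_sd = 0.25,
                                  n_partial = 0L, shared_with = "BIO") {
  stopifnot(n_genes >= 5L * n_per_cluster + n_partial, noise_sd > 0,
            is.finite(effect))
  truth <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    planted_cluster = NA_integer_,
    effect_day6 = 0, effect_day11 = 0,
    noise_sd = noise_sd,
    shared_with = NA_character_,
    stringsAsFactors = FALSE
  )
  if (n_per_cluster > 0L) {
    idx <- split(seq_len(5L * n_per_cluster),
                 rep(1:5, each = n_per_cluster))
    truth$planted_cluster[idx[[1]]] <- 1L
    truth$effect_day6[idx[[1]]] <- effect
    truth$planted_cluster[idx[[2]]] <- 2L
    truth$effect_day6[idx[[2]]] <- -effect
    truth$planted_cluster[idx[[3]]] <- 3L
    truth$effect_day11[idx[[3]]] <- effect
    truth$planted_cluster[idx[[4]]] <- 4L
    truth$effect_day11[idx[[4]]] <- -effect
    truth$planted_cluster[idx[[5]]] <- 5L
    truth$effect_day6[idx[[5]]] <- effect
    truth$effect_day11[idx[[5]]] <- effect
  }
  if (n_partial > 0L) {
    p_idx <- 5L * n_per_cluster + seq_len(n_partial)
    truth$effect_day6[p_idx] <- effect
    truth$shared_with[p_idx] <- shared_with
  }
  truth
}

#' Simulate a normalized log-scale expression matrix with planted effects
#'
#' Replicate values are the gene's baseline plus i.i.d. Gaussian noise on
#' the log2 scale; planted genes shift their mean only in the CD2314 arm at
#' their designated time point(s) relative to all of control, BIO and
#' CD2314+BIO. Genes with a `shared_with` comparator additionally shift
#' that comparator's arm, so they are CD2314-specific against only two of
#' the three comparisons.
#'
#' @param n_genes number of genes (ignored when `truth` is given).
#' @param design a design data.frame as from [default_design()]; all nine
#'   conditions with three replicates must be present.
#' @param truth a truth table as from [make_expression_truth()]; defaults
#'   to an all-null table of `n_genes` genes.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @return a list with `matrix` (genes x samples, dimnames set), `design`,
#'   `truth`, and `seed`.
#' @export
simulate_expression <- function(n_genes, design = default_design(),
                                truth = NULL, seed = 1L,
                                baseline_mean = 8, baseline_sd = 1.5) {
  if (is.null(truth)) {
    truth <- make_expression_truth(n_genes, n_per_cluster = 0L)
  }
  n_genes <- nrow(truth)
  stopifnot(n_genes >= 1L)
  if (any(!is.finite(truth$noise_sd)) || any(truth$noise_sd <= 0)) {
    stop("noise_sd must be positive and finite")
  }
  if (any(!is.finite(truth$effect_day6)) || any(!is.finite(truth$effect_day11))) {
    stop("effects must be finite")
  }
  needed <- expand.grid(time_point = c("d6", "d11"),
                        treatment = c("control", "CD2314", "BIO", "CD2314+BIO"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(needed))) {
    nrep <- sum(design$time_point == needed$time_point[i] &
                  design$treatment == needed$treatment[i])
    if (nrep < 2L) {
      stop("design is missing replicates for ", needed$time_point[i], " ",
           needed$treatment[i])
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n_s <- nrow(design)
  baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
  mat <- matrix(baseline, n_genes, n_s) +
    matrix(rnorm(n_genes * n_s, 0, rep(truth$noise_sd, n_s)), n_genes, n_s)

  add_effect <- function(mat, eff, tp, arm) {
    cols <- which(design$time_point == tp & design$treatment == arm)
    mat[, cols] <- mat[, cols] + eff
    mat
  }
  mat <- add_effect(mat, truth$effect_day6, "d6", "CD2314")
  mat <- add_effect(mat, truth$effect_day11, "d11", "CD2314")
  shared <- !is.na(truth$shared_with)
  if (any(shared)) {
    for (arm in unique(truth$shared_with[shared])) {
      eff <- ifelse(shared & truth$shared_with == arm, truth$effect_day6, 0)
      mat <- add_effect(mat, eff, "d6", arm)
    }
  }
  dimnames(mat) <- list(truth$gene_id, design$sample_id)
  list(matrix = mat, design = design, truth = truth,
       seed = as.integer(seed))
}

# Save/restore the global RNG state so simulators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
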