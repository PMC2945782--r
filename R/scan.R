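# Conservation-masked PWM scanning: best eligible hit per promoter, or
# mean of the top three hits when no conservation is required.

# Encode a DNAString/character sequence as integers 1..4 (A, C, G, T);
# ambiguous bases become NA and score -Inf at any window covering them.
encode_seq <- function(s) {
  v <- strsplit(toupper(as.character(s)), "")[[1]]
  match(v, BASES)
}

# Per-offset log-odds scores of `lo` (4 x w) along integer sequence `si`,
# one value per window start. NA bases poison their windows with -Inf.
position_scores <- function(si, lo) {
  w <- ncol(lo)
  L <- length(si)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  na <- anyNA(si)
  if (na) {
    si2 <- si
    si2[is.na(si2)] <- 1L
  } else si2 <- si
  for (j in seq_len(w)) {
    sc <- sc + lo[, j][si2[j:(n + j - 1L)]]
  }
  if (na) {
    bad <- which(is.na(si))
    for (b in bad) {
      lo_i <- max(1L, b - w + 1L)
      hi_i <- min(n, b)
      if (hi_i >= lo_i) sc[lo_i:hi_i] <- -Inf
    }
  }
  sc
}

# Reverse-complement of a log-odds matrix: scanning the forward sequence
# with it gives the minus-strand score at the same window start.
revcomp_lo <- function(lo) lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]

# Windows (width w) whose every base has conservation >= thr.
eligible_windows <- function(cons, w, thr) {
  L <- length(cons)
  n <- L - w + 1L
  if (n < 1L) return(logical(0))
  cs <- c(0, cumsum(cons >= thr))
  (cs[(w + 1L):(L + 1L)] - cs[seq_len(n)]) == w
}

# Min and max attainable log-odds sums, for min-max normalization.
lo_range <- function(lo) {
  c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
}

normalize_score <- function(raw, rng) {
  (raw - rng[["min"]]) / (rng[["max"]] - rng[["min"]])
}

#' Best conservation-eligible PWM hit in a promoter
#'
#' Scans every offset on both strands; a window is eligible iff every base
#' position has conservation at or above `cons_threshold`. Returns the
#' maximum log-odds among eligible windows (ties resolved to the smallest
#' offset, then the plus strand); `eligible = FALSE` if no window passes.
#'
#' @param promoter a single-promoter [promoter_set] (or an element index
#'   into one via `promoter_set[i]`).
#' @param pwm a [pwm] object.
#' @param cons_threshold conservation threshold in `{0.7, 0.8, 0.9, 1.0}`
#'   (any value in `[0, 1]` is accepted).
#' @return a list: `score_raw` (bits), `score_norm` (min-max normalized to
#'   `[0, 1]`), `eligible`, `offset` (0-based), `strand` of the match.
#' @export
best_hit <- function(promoter, pwm, cons_threshold) {
  stopifnot(inherits(promoter, "promoter_set"), length(promoter) == 1L)
  si <- encode_seq(promoter$seqs[[1L]])
  lo <- log_odds(pwm)
  if (length(si) < ncol(lo)) stop("promoter shorter than motif")
  fwd <- position_scores(si, lo)
  rev <- position_scores(si, revcomp_lo(lo))
  el <- eligible_windows(promoter$cons[[1L]], ncol(lo), cons_threshold)
  .pick_best(fwd, rev, el, lo_range(lo))
}

.pick_best <- function(fwd, rev, el, rng) {
  if (!any(el)) {
    return(list(score_raw = NA_real_, score_norm = NA_real_,
                eligible = FALSE, offset = NA_integer_,
                strand = NA_character_))
  }
  f <- ifelse(el, fwd, -Inf)
  r <- ifelse(el, rev, -Inf)
  best <- max(f, r)
  # tie-break: smallest offset, then + strand
  off_f <- which(f == best)
  off_r <- which(r == best)
  o_f <- if (length(off_f)) off_f[1L] else Inf
  o_r <- if (length(off_r)) off_r[1L] else Inf
  if (o_f <= o_r) {
    list(score_raw = best, score_norm = unname(normalize_score(best, rng)),
         eligible = TRUE, offset = as.integer(o_f - 1L), strand = "+")
  } else {
    list(score_raw = best, score_norm = unname(normalize_score(best, rng)),
         eligible = TRUE, offset = as.integer(o_r - 1L), strand = "-")
  }
}

#' Mean of the three highest PWM hits in a promoter (no conservation)
#'
#' All offsets on both strands are candidate hits (overlapping windows
#' allowed); the score is the arithmetic mean of the three largest
#' log-odds values, or of all candidates when fewer than three windows
#' exist.
#'
#' @inheritParams best_hit
#' @return a list: `score_raw` (bits), `score_norm`, `eligible` (always
#'   `TRUE` when at least one window exists).
#' @export
top3_mean <- function(promoter, pwm) {
  stopifnot(inherits(promoter, "promoter_set"), length(promoter) == 1L)
  si <- encode_seq(promoter$seqs[[1L]])
  lo <- log_odds(pwm)
  if (length(si) < ncol(lo)) stop("promoter shorter than motif")
  cand <- c(position_scores(si, lo), position_scores(si, revcomp_lo(lo)))
  cand <- cand[is.finite(cand)]
  if (length(cand) == 0L) {
    return(list(score_raw = NA_real_, score_norm = NA_real_,
                eligible = FALSE))
  }
  top <- sort(cand, decreasing = TRUE)[seq_len(min(3L, length(cand)))]
  raw <- mean(top)
  list(score_raw = raw,
       score_norm = unname(normalize_score(raw, lo_range(lo))),
       eligible = TRUE)
}

#' Score every promoter against every PWM under every conservation mode
#'
#' Position scores are computed once per (promoter, PWM) pair and reused
#' across modes. Conservation modes are the threshold values (best
#' eligible hit) plus `"none"` (top-three mean, no masking).
#'
#' @param promoters a [promoter_set].
#' @param pwms a named list of [pwm] objects.
#' @param modes character vector of modes, a subset of
#'   `c("0.7", "0.8", "0.9", "1", "none")`.
#' @return an object of class `promoter_scores`: a list with `score`
#'   (promoter x pwm x mode array of normalized scores; `NA` where no
#'   eligible window exists) and `eligible` (logical array of the same
#'   shape).
#' @export
scan_promoters <- function(promoters, pwms,
                           modes = c("0.7", "0.8", "0.9", "1", "none")) {
  stopifnot(inherits(promoters, "promoter_set"), length(pwms) >= 1L)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  }
  thr_modes <- setdiff(modes, "none")
  thr <- as.numeric(thr_modes)
  if (any(is.na(thr))) stop("unknown conservation mode")
  n_p <- length(promoters)
  ids <- promoters$meta$gene_id
  score <- array(NA_real_, dim = c(n_p, length(pwms), length(modes)),
                 dimnames = list(ids, names(pwms), modes))
  elig <- array(FALSE, dim = dim(score), dimnames = dimnames(score))

  los <- lapply(pwms, log_odds)
  rlos <- lapply(los, revcomp_lo)
  rngs <- lapply(los, lo_range)
  widths <- vapply(los, ncol, integer(1))

  for (i in seq_len(n_p)) {
    si <- encode_seq(promoters$seqs[[i]])
    cons <- promoters$cons[[i]]
    # per-threshold cumulative counts, shared across PWMs of any width
    css <- lapply(thr, function(t) c(0, cumsum(cons >= t)))
    for (k in seq_along(pwms)) {
      w <- widths[k]
      if (length(si) < w) next
      fwd <- position_scores(si, los[[k]])
      rev <- position_scores(si, rlos[[k]])
      pair_max <- pmax(fwd, rev)
      n_win <- length(fwd)
      for (m in seq_along(modes)) {
        if (modes[m] == "none") {
          cand <- c(fwd, rev)
          cand <- cand[is.finite(cand)]
          if (length(cand) == 0L) next
          top <- sort(cand, decreasing = TRUE)[seq_len(min(3L, length(cand)))]
          score[i, k, m] <- normalize_score(mean(top), rngs[[k]])
          elig[i, k, m] <- TRUE
        } else {
          ti <- match(modes[m], thr_modes)
          cs <- css[[ti]]
          el <- (cs[(w + 1L):(length(cons) + 1L)] - cs[seq_len(n_win)]) == w
          if (!any(el)) next
          best <- max(pair_max[el])
          if (!is.finite(best)) next
          score[i, k, m] <- normalize_score(best, rngs[[k]])
          elig[i, k, m] <- TRUE
        }
      }
    }
  }
  structure(list(score = score, eligible = elig, modes = modes),
            class = "promoter_scores")
}

#' @export
print.promoter_scores <- function(x, ...) {
  d <- dim(x$score)
  cat(sprintf("promoter_scores: %d promoters x %d motifs x %d modes\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Rebuild a `promoter_scores` object from its long-format table
#'
#' Inverse of [as.data.frame.promoter_scores()]; promoter, motif and mode
#' order follow their first appearance in the table.
#'
#' @param df a data.frame with columns `promoter_id`, `motif_id`, `mode`,
#'   `score`, `eligible`.
#' @return a `promoter_scores` object.
#' @export
as_promoter_scores <- function(df) {
  stopifnot(all(c("promoter_id", "motif_id", "mode", "score",
                  "eligible") %in% names(df)))
  ids <- unique(df$promoter_id)
  motifs <- unique(df$motif_id)
  modes <- unique(as.character(df$mode))
  score <- array(NA_real_, dim = c(length(ids), length(motifs),
                                   length(modes)),
                 dimnames = list(ids, motifs, modes))
  elig <- array(FALSE, dim = dim(score), dimnames = dimnames(score))
  idx <- cbind(match(df$promoter_id, ids), match(df$motif_id, motifs),
               match(as.character(df$mode), modes))
  score[idx] <- df$score
  elig[idx] <- df$eligible
  structure(list(score = score, eligible = elig, modes = modes),
            class = "promoter_scores")
}

#' Long-format data.frame of a [scan_promoters()] result
#'
#' @param x a `promoter_scores` object.
#' @param ... unused.
#' @return a data.frame `promoter_id`, `motif_id`, `mode`, `score`
#'   (normalized), `eligible`.
#' @method as.data.frame promoter_scores
#' @export
as.data.frame.promoter_scores <- function(x, ...) {
  d <- dimnames(x$score)
  out <- expand.grid(promoter_id = d[[1]], motif_id = d[[2]],
                     mode = d[[3]], stringsAsFactors = FALSE)
  out$score <- as.vector(x$score)
  out$eligible <- as.vector(x$eligible)
  out
}
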