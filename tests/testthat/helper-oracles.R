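# Independent oracles used across the suite. Each is a deliberately naive
# reference implementation, kept free of any package internals it checks.

# Hypergeometric upper tail by literal enumeration of all C(N, n) draws
# from a population of N items of which the first K are marked.
enum_hyper_tail <- function(k, K, n, N) {
  draws <- combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s) {
  paste(rev(DNA_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive double-strand scan: every offset, direct per-base log-odds sums.
# Returns the per-offset score vectors for both strands.
naive_position_scores <- function(seq_chr, lo) {
  w <- ncol(lo)
  L <- nchar(seq_chr)
  bases <- strsplit(seq_chr, "")[[1]]
  rc <- strsplit(revcomp_chr(seq_chr), "")[[1]]
  score_at <- function(b, off) {
    sum(vapply(seq_len(w), function(j) lo[b[off + j - 1L], j], 0))
  }
  n <- L - w + 1L
  fwd <- vapply(seq_len(n), function(o) score_at(bases, o), 0)
  # minus-strand hit starting at forward offset o spans the same window
  rev_s <- vapply(seq_len(n), function(o) score_at(rc, L - w - o + 2L), 0)
  list(fwd = fwd, rev = rev_s)
}

# Naive best eligible hit (max over both strands of eligible windows).
naive_best_hit <- function(seq_chr, cons, lo, thr) {
  ps <- naive_position_scores(seq_chr, lo)
  w <- ncol(lo)
  n <- length(ps$fwd)
  elig <- vapply(seq_len(n), function(o) all(cons[o:(o + w - 1L)] >= thr),
                 NA)
  if (!any(elig)) return(NA_real_)
  max(c(ps$fwd[elig], ps$rev[elig]))
}

naive_top3 <- function(seq_chr, lo) {
  ps <- naive_position_scores(seq_chr, lo)
  cand <- sort(c(ps$fwd, ps$rev), decreasing = TRUE)
  mean(cand[seq_len(min(3L, length(cand)))])
}

# Brute-force family of maximal retention subsets for the overlap rule:
# all subsets with no pair overlapping > max_overlap to which no further
# promoter can be added.
overlap_bp <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

maximal_retention_sets <- function(meta, max_overlap = 1500L) {
  n <- nrow(meta)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && meta$chrom[i] == meta$chrom[j]) {
      conflict[i, j] <- overlap_bp(meta$start[i], meta$end[i],
                                   meta$start[j], meta$end[j]) > max_overlap
    }
  }
  subsets <- lapply(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  valid <- Filter(function(s) {
    length(s) < 2L || !any(conflict[s, s])
  }, subsets)
  maximal <- Filter(function(s) {
    extra <- setdiff(seq_len(n), s)
    all(vapply(extra, function(e) any(conflict[e, s]), NA))
  }, valid[lengths(valid) > 0L | n == 0L])
  lapply(maximal, function(s) sort(meta$gene_id[s]))
}

# Connected components by flood fill over an adjacency list.
flood_fill_components <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1L]][i]; b <- edges[[2L]][i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cur
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# Build a promoter_set directly from character sequences + conservation.
make_promoters <- function(seqs_chr, cons, ids = NULL,
                           chrom = "chrT", strand = "+") {
  n <- length(seqs_chr)
  ids <- ids %||% sprintf("p%03d", seq_len(n))
  lens <- nchar(seqs_chr)
  starts <- cumsum(c(0L, head(lens + 10L, -1L)))
  seqs <- Biostrings::DNAStringSet(seqs_chr)
  names(seqs) <- ids
  names(cons) <- ids
  promoter_set(
    meta = data.frame(gene_id = ids, chrom = chrom, start = starts,
                      end = starts + lens,
                      strand = rep(strand, length.out = n),
                      stringsAsFactors = FALSE),
    seqs = seqs, cons = cons
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Promoters that are pure interval stand-ins (A-runs, zero conservation),
# for exercising the overlap-deduplication rule.
interval_promoters <- function(starts, ends, chrom = "chr1") {
  n <- length(starts)
  seqs <- Biostrings::DNAStringSet(vapply(ends - starts, function(l) {
    paste(rep("A", l), collapse = "")
  }, ""))
  ids <- sprintf("g%02d", seq_len(n))
  names(seqs) <- ids
  cons <- setNames(lapply(ends - starts, function(l) rep(0, l)), ids)
  promoter_set(
    data.frame(gene_id = ids, chrom = chrom, start = starts, end = ends,
               strand = "+", stringsAsFactors = FALSE),
    seqs, cons
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive threshold-sweep oracle for optimize_threshold on small
# instances (N small enough for enum_hyper_tail).
sweep_threshold_oracle <- function(cl, bg, alpha, corr, min_fold) {
  n <- length(cl); N <- n + length(bg)
  cand <- sort(unique(c(cl, bg)))
  best <- NULL
  for (t in cand) {
    k <- sum(cl >= t)
    Kbg <- sum(bg >= t)
    K <- k + Kbg
    p <- enum_hyper_tail(k, K, n, N)
    pb <- min(1, p * corr)
    fold <- if (Kbg == 0) Inf else (k / n) / (Kbg / (N - n))
    if (pb < alpha) {
      if (is.null(best) || fold > best$fold ||
          (fold == best$fold && t > best$threshold)) {
        best <- list(threshold = t, k = k, K = K, fold = fold, p_raw = p)
      }
    }
  }
  if (is.null(best) || best$fold < min_fold) return(NULL)
  best
}
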