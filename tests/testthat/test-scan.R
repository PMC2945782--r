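test_that("best_hit and top3_mean equal naive enumeration on random pairs", {
  set.seed(11)
  for (i in 1:60) {
    L <- sample(25:80, 1)
    w <- sample(4:12, 1)
    p <- random_pwm(w, seed = i)
    s <- random_dna(L)
    cons <- round(runif(L), 2)
    pr <- make_promoters(s, list(cons))
    lo <- log_odds(p)
    rng <- c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
    thr <- sample(c(0.3, 0.5, 0.7, 0.9), 1)
    mine <- best_hit(pr, p, thr)
    ref <- naive_best_hit(s, cons, lo, thr)
    if (is.na(ref)) {
      expect_false(mine$eligible)
    } else {
      expect_equal(mine$score_raw, ref, tolerance = 1e-12)
      expect_equal(mine$score_norm,
                   (ref - rng[["min"]]) / (rng[["max"]] - rng[["min"]]),
                   tolerance = 1e-12)
    }
    expect_equal(top3_mean(pr, p)$score_raw, naive_top3(s, lo),
                 tolerance = 1e-12)
  }
})

test_that("conservation filtering is strict per-base over the whole window", {
  p <- random_pwm(6, seed = 1)
  s <- paste0("AAAA", pwm_consensus(p), "AAAA")
  cons <- rep(1, nchar(s))
  pr <- make_promoters(s, list(cons))
  hit <- best_hit(pr, p, 0.7)
  expect_true(hit$eligible)
  expect_equal(hit$offset, 4L)
  expect_equal(hit$score_norm, 1, tolerance = 1e-12)

  # one sub-threshold base inside every window kills threshold-1.0 scans
  cons2 <- rep(1, nchar(s))
  cons2[seq(3, nchar(s), by = 4)] <- 0.99
  pr2 <- make_promoters(s, list(cons2))
  expect_false(best_hit(pr2, p, 1.0)$eligible)
  expect_true(best_hit(pr2, p, 0.9)$eligible)
})

test_that("palindromic motifs score identically on both strands", {
  counts <- cbind(c(9, 1, 1, 1), c(1, 9, 1, 1), c(1, 1, 9, 1),
                  c(1, 1, 1, 9))  # ACGT = its own reverse complement
  p <- pwm(counts, "pal")
  lo <- log_odds(p)
  expect_equal(unname(lo), unname(lo[4:1, 4:1]))
  s <- random_dna(60)
  pr <- make_promoters(s, list(rep(1, 60)))
  ps <- naive_position_scores(s, lo)
  expect_equal(ps$fwd, ps$rev, tolerance = 1e-12)
})

test_that("short promoters follow the fewer-than-three-hits convention", {
  p <- random_pwm(8, seed = 3)
  s <- random_dna(8)  # exactly one window, two strands
  pr <- make_promoters(s, list(rep(1, 8)))
  lo <- log_odds(p)
  ps <- naive_position_scores(s, lo)
  expect_equal(top3_mean(pr, p)$score_raw, mean(c(ps$fwd, ps$rev)),
               tolerance = 1e-12)
  expect_error(top3_mean(make_promoters(random_dna(5), list(rep(1, 5))), p),
               "shorter than motif")
})

test_that("three identical maximal sites average to the single-site score", {
  p <- random_pwm(6, seed = 4)
  cons <- pwm_consensus(p)
  s <- paste0(cons, "AA", cons, "AA", cons)
  pr <- make_promoters(s, list(rep(1, nchar(s))))
  expect_equal(top3_mean(pr, p)$score_norm, 1, tolerance = 1e-12)
})

test_that("scan_promoters reproduces per-pair calls across all modes", {
  set.seed(21)
  n <- 12
  seqs <- vapply(seq_len(n), function(i) random_dna(60), "")
  cons <- lapply(seq_len(n), function(i) round(runif(60), 2))
  pr <- make_promoters(seqs, cons)
  pwms <- list(a = random_pwm(5, "a", seed = 1),
               b = random_pwm(9, "b", seed = 2))
  sc <- scan_promoters(pr, pwms)
  expect_equal(dim(sc$score), c(12L, 2L, 5L))
  for (i in seq_len(n)) {
    for (k in c("a", "b")) {
      for (md in c("0.7", "0.9")) {
        ref <- best_hit(pr[i], pwms[[k]], as.numeric(md))
        if (ref$eligible) {
          expect_equal(sc$score[i, k, md], ref$score_norm,
                       tolerance = 1e-12)
        } else {
          expect_true(is.na(sc$score[i, k, md]))
        }
      }
      expect_equal(sc$score[i, k, "none"],
                   top3_mean(pr[i], pwms[[k]])$score_norm,
                   tolerance = 1e-12)
    }
  }
  df <- as.data.frame(sc)
  expect_equal(nrow(df), 12 * 2 * 5)
  expect_true(all(df$score >= 0 & df$score <= 1, na.rm = TRUE))
  # long-format round trip restores the score object exactly
  back <- as_promoter_scores(df)
  expect_equal(back$score, sc$score)
  expect_equal(back$eligible, sc$eligible)
})

test_that("raising the conservation threshold never raises the best score", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna(70)
    cons <- round(rbeta(70, 2, 1), 2)
    pr <- make_promoters(s, list(cons))
    p <- random_pwm(7, seed = 50 + i)
    prev <- Inf
    for (thr in c(0.7, 0.8, 0.9, 1.0)) {
      hit <- best_hit(pr, p, thr)
      cur <- if (hit$eligible) hit$score_raw else -Inf
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})
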