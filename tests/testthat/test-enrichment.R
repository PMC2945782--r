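test_that("hypergeometric upper tail matches draw enumeration", {
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(6, 6, 6, 6), 1)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "inconsistent")
  expect_error(hypergeom_upper_tail(2, 11, 5, 10), "inconsistent")

  for (N in c(5, 7, 9)) {
    for (n in 1:N) {
      for (K in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper_tail(k, K, n, N),
                       enum_hyper_tail(k, K, n, N), tolerance = 1e-10,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("upper tail is monotone non-increasing in k", {
  for (i in 1:20) {
    N <- sample(10:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    ks <- 0:min(K, n)
    p <- hypergeom_upper_tail(ks, K, n, N)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("threshold optimization reproduces the worked example", {
  res <- optimize_threshold(c(0.9, 0.8, 0.2), c(0.85, rep(0.1, 6)),
                            alpha = 0.05, correction_factor = 1)
  expect_equal(res$threshold, 0.2)
  expect_equal(res$k, 3)
  expect_equal(res$K, 4)
  expect_equal(res$fold, 7.0)
  expect_equal(res$p_raw, 4 / 120, tolerance = 1e-12)
  # at the default alpha = 0.01 no candidate passes
  expect_null(optimize_threshold(c(0.9, 0.8, 0.2), c(0.85, rep(0.1, 6)),
                                 alpha = 0.01, correction_factor = 1))
})

test_that("threshold optimization agrees with the exhaustive-sweep oracle", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    nb <- sample(3:7, 1)
    cl <- round(runif(n), 1)
    bg <- round(runif(nb), 1)
    # alpha values chosen away from attainable p-value fractions so the
    # pass/fail boundary is never an exact floating-point tie
    alpha <- sample(c(0.057, 0.213, 0.493), 1)
    corr <- sample(1:3, 1)
    mine <- optimize_threshold(cl, bg, alpha = alpha,
                               correction_factor = corr, min_fold = 1.8)
    ref <- sweep_threshold_oracle(cl, bg, alpha, corr, 1.8)
    if (is.null(ref)) {
      expect_null(mine)
    } else {
      expect_equal(mine$threshold, ref$threshold)
      expect_equal(mine$k, ref$k)
      expect_equal(mine$K, ref$K)
      expect_equal(mine$fold, ref$fold)
      expect_equal(mine$p_raw, ref$p_raw, tolerance = 1e-10)
    }
  }
})

test_that("identical score distributions are never reported", {
  set.seed(3)
  v <- runif(40)
  expect_null(optimize_threshold(v, rep(v, 3), alpha = 0.01,
                                 correction_factor = 1))
})

test_that("candidates failing the corrected-p gate are excluded from the argmax", {
  # background has one promoter over the top threshold -> huge fold but
  # weak p at tiny counts; a large correction factor forces exclusion
  cl <- c(1, 1, 0.1)
  bg <- c(rep(0.05, 20), 0.9)
  with_corr <- optimize_threshold(cl, bg, alpha = 0.01,
                                  correction_factor = 1000)
  no_corr <- optimize_threshold(cl, bg, alpha = 0.01,
                                correction_factor = 1)
  expect_null(with_corr)
  expect_false(is.null(no_corr))
})

test_that("optimization is invariant under strictly monotone score transforms", {
  set.seed(23)
  for (i in 1:10) {
    cl <- runif(8)
    bg <- runif(30)
    a <- optimize_threshold(cl, bg, alpha = 0.3, correction_factor = 1)
    b <- optimize_threshold(exp(3 * cl), exp(3 * bg), alpha = 0.3,
                            correction_factor = 1)
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_equal(b$k, a$k)
      expect_equal(b$K, a$K)
      expect_equal(b$fold, a$fold)
      expect_equal(b$p_raw, a$p_raw, tolerance = 1e-12)
      expect_equal(b$threshold, exp(3 * a$threshold), tolerance = 1e-12)
      expect_lte(a$k, a$n)
    }
  }
})

test_that("NA (ineligible) scores count in the universe but never score over", {
  cl <- c(0.9, 0.9, NA, NA)
  bg <- c(rep(0.1, 10), NA, NA)
  # P(X >= 2 | K = 2, n = 4, N = 16) = 0.05 exactly, so test at 0.1
  res <- optimize_threshold(cl, bg, alpha = 0.1, correction_factor = 1)
  expect_equal(res$n, 4)
  expect_equal(res$N, 16)
  expect_equal(res$k, 2)
  expect_error(optimize_threshold(numeric(0), bg), "empty")
})

test_that("cluster enrichment recovers a planted motif and skips decoys", {
  p <- random_pwm(8, seed = 6)
  gs <- simulate_genome(60, 300, p, foreground_rate = 0.8,
                        background_rate = 0.05, upstream = 100,
                        downstream = 30, seed = 8)
  pr <- extract_promoter_windows(gs$tss, gs$genome, gs$conservation,
                                 upstream = 100, downstream = 30)
  pwms <- list(planted = p,
               dec1 = shuffle_pwm_columns(p, "dec1", seed = 1),
               dec2 = shuffle_pwm_columns(p, "dec2", seed = 2))
  sc <- scan_promoters(pr, pwms)
  fg <- gs$truth$gene_id[gs$truth$is_foreground]
  en <- enrich_clusters(sc, fg)
  expect_true("planted" %in% en$motif_id)
  rec <- en[en$motif_id == "planted", ]
  expect_gte(rec$fold, 1.8)
  expect_lt(rec$p_bonferroni, 0.01)
  expect_true(all(en$k <= en$n))
  expect_error(enrich_clusters(sc, c(fg, "nosuchgene")), "not contained")

  # a motif passing p but below the fold floor is absent
  high_fold <- enrich_clusters(sc, fg, min_fold = 1.8)
  all_folds <- enrich_clusters(sc, fg, min_fold = 0)
  expect_true(all(high_fold$fold >= 1.8))
  expect_gte(nrow(all_folds), nrow(high_fold))
})
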