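test_that("Welch test matches hand formula and reference implementation", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, 0)

  r <- welch_t_test(c(1, 2, 3), c(7, 8, 9))
  expect_equal(r$t_statistic, -6 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-abs(-6 / sqrt(2 / 3)), 4),
               tolerance = 1e-12)
  expect_equal(r$direction, -1)

  set.seed(42)
  for (i in 1:50) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -2, 2))
    mine <- welch_t_test(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    # symmetry: swapping groups negates t and direction, preserves p
    swp <- welch_t_test(b, a)
    expect_equal(swp$t_statistic, -mine$t_statistic)
    expect_equal(swp$p_value, mine$p_value)
    expect_equal(swp$direction, -mine$direction)
  }
})

test_that("zero-variance pairs follow the stated degenerate conventions", {
  r <- welch_t_test(c(5, 5, 5), c(6, 6, 6))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  expect_equal(r$direction, -1)
  r <- welch_t_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, 0)
  expect_error(welch_t_test(c(1), c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(1, NA), c(1, 2)), "non-finite")
})

test_that("BH step-up agrees with the brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_true(bh_fdr(0.04, 0.05))
  expect_equal(bh_fdr(c(0.06, 0.7), 0.05), c(FALSE, FALSE))
  expect_error(bh_fdr(numeric(0)), "empty")

  brute_bh <- function(p, q) {
    m <- length(p)
    sp <- sort(p)
    ks <- which(sp <= seq_len(m) * q / m)
    if (length(ks) == 0L) return(rep(FALSE, m))
    p <= sp[max(ks)]
  }
  set.seed(7)
  for (i in 1:60) {
    p <- round(runif(sample(1:8, 1)), 3)
    q <- sample(c(0.01, 0.05, 0.2), 1)
    expect_identical(bh_fdr(p, q), brute_bh(p, q))
  }
})

# Builds a contrast table for one gene from per-(time, comparator)
# (significant, direction) pairs.
contrast_row <- function(gene, tp, cmp, sig, dir) {
  data.frame(gene_id = gene, time_point = tp, comparator = cmp,
             t_statistic = dir * 5, p_value = ifelse(sig, 1e-4, 0.5),
             direction = dir, degenerate = FALSE, fdr_significant = sig,
             stringsAsFactors = FALSE)
}

gene_table <- function(gene, d6_sig, d6_dir, d11_sig, d11_dir) {
  cmps <- c("control", "BIO", "CD2314+BIO")
  do.call(rbind, c(
    lapply(seq_len(3), function(i) {
      contrast_row(gene, "d6", cmps[i], d6_sig[i], d6_dir[i])
    }),
    lapply(seq_len(3), function(i) {
      contrast_row(gene, "d11", cmps[i], d11_sig[i], d11_dir[i])
    })
  ))
}

test_that("cluster labels require direction-consistent wins in all three comparisons", {
  tab <- rbind(
    gene_table("up6", rep(TRUE, 3), rep(1, 3), rep(FALSE, 3), rep(1, 3)),
    gene_table("up6only2", c(TRUE, TRUE, FALSE), rep(1, 3),
               rep(FALSE, 3), rep(1, 3)),
    gene_table("down6", rep(TRUE, 3), rep(-1, 3), rep(FALSE, 3), rep(1, 3)),
    gene_table("up11", rep(FALSE, 3), rep(1, 3), rep(TRUE, 3), rep(1, 3)),
    gene_table("down11", rep(FALSE, 3), rep(1, 3), rep(TRUE, 3), rep(-1, 3)),
    gene_table("upboth", rep(TRUE, 3), rep(1, 3), rep(TRUE, 3), rep(1, 3)),
    gene_table("downboth", rep(TRUE, 3), rep(-1, 3), rep(TRUE, 3), rep(-1, 3)),
    gene_table("discord", rep(TRUE, 3), rep(1, 3), rep(TRUE, 3), rep(-1, 3)),
    gene_table("mixdir6", rep(TRUE, 3), c(1, 1, -1), rep(FALSE, 3), rep(1, 3))
  )
  cl <- assign_clusters(tab)
  got <- setNames(cl$cluster, cl$gene_id)
  expect_equal(got[["up6"]], 1L)
  expect_true(is.na(got[["up6only2"]]))
  expect_equal(got[["down6"]], 2L)
  expect_equal(got[["up11"]], 3L)
  expect_equal(got[["down11"]], 4L)
  expect_equal(got[["upboth"]], 5L)
  expect_equal(got[["downboth"]], 5L)
  expect_true(is.na(got[["discord"]]))
  expect_true(is.na(got[["mixdir6"]]))

  cl2 <- assign_clusters(tab, cluster5 = "up_only")
  got2 <- setNames(cl2$cluster, cl2$gene_id)
  expect_equal(got2[["upboth"]], 5L)
  expect_true(is.na(got2[["downboth"]]))

  expect_error(assign_clusters(tab[-1, ]), "3 comparators")
})

test_that("delta-Ct relative expression follows the base-2 formula", {
  expect_identical(qpcr_relative_expression(25, c(20, 21, 22)), 0.0625)
  expect_equal(qpcr_relative_expression(21, c(20, 21, 22)), 1.0)
  x <- qpcr_relative_expression(24.3, c(20, 21, 22))
  expect_equal(qpcr_relative_expression(23.3, c(20, 21, 22)), 2 * x)
  # geometric mean of reference expressions = 2^-(arithmetic mean Ct)
  refs <- c(18.2, 20.1, 23.7)
  expect_equal(prod(2^-refs)^(1 / 3), 2^-mean(refs))
  expect_error(qpcr_relative_expression(25, numeric(0)), "empty")
})

test_that("moderated and welch contrasts agree on direction and ranking", {
  tr <- make_expression_truth(300, n_per_cluster = 20)
  ex <- simulate_expression(300, truth = tr, seed = 9)
  cm <- run_contrasts(ex$matrix, ex$design, method = "moderated")
  cw <- run_contrasts(ex$matrix, ex$design, method = "welch")
  expect_equal(nrow(cm), 300 * 6)
  expect_equal(cm$direction, cw$direction)
  # both flavors see the planted day-6 effects in the vs-control family
  sub <- cm$time_point == "d6" & cm$comparator == "control"
  planted_up <- cm$gene_id %in% tr$gene_id[!is.na(tr$planted_cluster) &
                                             tr$planted_cluster == 1L]
  expect_gt(min(cm$t_statistic[sub & planted_up]), 3)
})
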