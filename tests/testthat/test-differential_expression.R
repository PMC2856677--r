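test_that("ztest matches the pooled two-proportion formula", {
  # symmetry and degenerate rules
  expect_equal(ztest(30, 1e6, 30, 1e6)[, c("z", "p")],
               data.frame(z = 0, p = 1))
  expect_equal(ztest(0, 100, 0, 100)[, c("z", "p")], data.frame(z = 0, p = 1))

  # independently hand-computed oracle
  hand_z <- function(x1, n1, x2, n2) {
    p0 <- (x1 + x2) / (n1 + n2)
    (x1 / n1 - x2 / n2) / sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  }
  r <- ztest(10, 1e6, 50, 1e6)
  expect_equal(r$z, hand_z(10, 1e6, 50, 1e6), tolerance = 1e-12)
  expect_equal(r$z, -5.164055, tolerance = 1e-6)
  # sanity: the exact conditional binomial test agrees on significance
  expect_lt(stats::binom.test(10, 60, 0.5)$p.value, 1e-4)
  expect_lt(r$p, 1e-4)

  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(1e4:1e6, 1); n2 <- sample(1e4:1e6, 1)
    x1 <- rbinom(1, n1, 1e-4); x2 <- rbinom(1, n2, 1e-4)
    expect_equal(ztest(x1, n1, x2, n2)$z, hand_z(x1, n1, x2, n2),
                 tolerance = 1e-9)
  }

  # antisymmetry under swapping libraries
  a <- ztest(13, 5e5, 40, 6e5)
  b <- ztest(40, 6e5, 13, 5e5)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  expect_error(ztest(1, 0, 1, 10), "positive")
  expect_error(ztest(11, 10, 1, 10), "0 <= x <= n")
})

test_that("empirical null pools within-condition replicate comparisons", {
  tags <- fixture_tags(30)
  cnt <- stats::setNames(rep(10, 30), tags)
  mk <- function(id, cond, st, r, counts = cnt)
    lib_of(id, cond, st, r, counts, sum(counts))

  # identical replicates: every null value is exactly zero
  libs <- list(mk("a1", "gbm", "2-step", 1), mk("a2", "gbm", "2-step", 2),
               mk("b1", "normal", "2-step", 1), mk("b2", "normal", "2-step", 2))
  null <- build_empirical_null(libs)
  expect_true(all(null$z == 0))
  # two conditions x one pair x 30 tags
  expect_length(null$z, 60L)
  expect_equal(null$n_comparisons, 2L)

  # fewer than 2 replicates in a condition is an error
  expect_error(build_empirical_null(libs[c(1, 3, 4)]), "fewer than 2")

  # 2 replicates per stepper -> two pairs per condition
  libs8 <- c(libs, list(mk("a3", "gbm", "3-step", 1), mk("a4", "gbm", "3-step", 2),
                        mk("b3", "normal", "3-step", 1),
                        mk("b4", "normal", "3-step", 2)))
  expect_equal(build_empirical_null(libs8)$n_comparisons, 4L)
})

test_that("null Z values are approximately standard normal", {
  # multinomial replicates of one fixed profile
  set.seed(123)
  k <- 400
  prob <- rgamma(k, 2); prob <- prob / sum(prob)
  tags <- fixture_tags(k)
  mk <- function(id, cond, st, r) {
    cnt <- stats::setNames(stats::rmultinom(1, 2e5, prob)[, 1], tags)
    lib_of(id, cond, st, r, cnt[cnt > 0])
  }
  libs <- list(mk("a1", "gbm", "2-step", 1), mk("a2", "gbm", "2-step", 2),
               mk("b1", "normal", "2-step", 1), mk("b2", "normal", "2-step", 2))
  z <- build_empirical_null(libs)$z
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(stats::sd(z) - 1), 0.15)
  expect_lt(abs(mean(abs(z) > 1.96) - 0.05), 0.035)
})

test_that("pi0 follows the doubled upper-half rule with clipping", {
  expect_equal(estimate_pi0(c(rep(0.6, 50), rep(0.1, 50))), 1.0)
  expect_equal(estimate_pi0(c(rep(0.6, 25), rep(0.1, 75))), 0.5)
  expect_equal(estimate_pi0(c(rep(0.9, 60), rep(0.1, 40))), 1.0)
  expect_error(estimate_pi0(numeric(0)), "degenerate")
  expect_error(estimate_pi0(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("empirical tail probabilities match brute-force counting", {
  set.seed(7)
  null <- structure(list(z = round(stats::rnorm(57), 2),
                         source = rep("x", 57), n_comparisons = 2L),
                    class = "empirical_null")
  obs <- ztest(x1 = rbinom(15, 1000, 0.3), n1 = 1000,
               x2 = rbinom(15, 1000, 0.3), n2 = 1000,
               tag = fixture_tags(15))
  res <- compute_fdr(obs, null, mode = "storey")
  for (i in seq_len(nrow(res))) {
    brute <- (1 + sum(abs(null$z) >= abs(res$z[i]))) / (length(null$z) + 1)
    expect_equal(res$p_emp[i], brute)
  }
  # and the unsmoothed storey quantity, reconstructed by hand
  pi0 <- min(1, 2 * sum(obs$p > 0.5) / nrow(obs))
  raw <- vapply(seq_len(nrow(res)), function(i) {
    min(1, pi0 * res$p_emp[i] * nrow(res) / sum(abs(res$z) >= abs(res$z[i])))
  }, 0)
  # res rows are already ordered by (p_emp, tag)
  expect_equal(res$fdr, rev(cummin(rev(raw))))
})

test_that("fdr is monotone in p_emp and modes behave as documented", {
  set.seed(11)
  null <- structure(list(z = stats::rnorm(500), source = rep("x", 500),
                         n_comparisons = 2L), class = "empirical_null")
  obs <- ztest(x1 = rbinom(100, 5000, 0.1), n1 = 5000,
               x2 = rbinom(100, 5000, 0.1), n2 = 5000,
               tag = fixture_tags(100))
  st <- compute_fdr(obs, null, mode = "storey")
  expect_true(all(diff(st$fdr) >= -1e-12))
  expect_true(all(st$fdr >= 0 & st$fdr <= 1))
  expect_true(all(st$p_emp > 0 & st$p_emp <= 1))

  lit <- compute_fdr(obs, null, mode = "literal")
  expect_equal(lit$fdr, rev(cummin(rev(pmin(1, lit$pi0 * lit$p_emp)))))
  expect_error(compute_fdr(obs, null, mode = "banana"), "arg")

  # all-zero observed z: p_emp near 1, fdr = pi0, nothing called at 0.1
  obs0 <- ztest(rep(5, 10), 1000, rep(5, 10), 1000, tag = fixture_tags(10))
  r0 <- compute_fdr(obs0, null, cutoff = 0.1)
  expect_true(all(r0$p_emp == 1))
  expect_equal(r0$fdr, rep(r0$pi0[1], 10))
  expect_length(call_degs(r0, 0.1), 0L)
})

test_that("calls use a strict FDR cutoff", {
  fr <- structure(data.frame(tag = fixture_tags(3), z = c(3, 2, 0),
                             fdr = c(0.09, 0.1, 0.9)),
                  class = c("fdr_result", "data.frame"))
  expect_equal(call_degs(fr, 0.1), fr$tag[1])
  expect_error(call_degs(fr, 0), "cutoff")
  expect_length(call_degs(fr[0, ], 0.1), 0L)
})

test_that("gene rollup follows the any-tag rule with direction handling", {
  tags <- fixture_tags(7)
  fr <- structure(
    data.frame(tag = tags,
               z = c(3, -1, 0.5, 3, -3, 2.5, 1),
               p = rep(0.01, 7),
               fdr = c(0.05, 0.5, 0.8, 0.02, 0.03, 0.04, 0.9)),
    class = c("fdr_result", "data.frame"))
  attr(fr, "cutoff") <- 0.1
  t2g <- data.frame(tag = tags,
                    gene_id = c("gA", "gA", "gB", "gC", "gC", "gD", NA),
                    stringsAsFactors = FALSE)
  g <- rollup_genes(fr, t2g)
  gl <- split(g, g$gene_id)
  expect_true(gl$gA$gene_de)                    # one called tag suffices
  expect_equal(gl$gA$direction, "up")
  expect_false(gl$gB$gene_de)
  expect_equal(gl$gB$direction, "none")
  expect_equal(gl$gC$direction, "conflict")     # +3 and -3 both called
  expect_equal(gl$gD$direction, "up")
  expect_equal(gl$gA$min_fdr, 0.05)
  expect_false("NA" %in% g$gene_id)             # unannotated tags dropped
})

test_that("condition swap negates z and preserves the called set", {
  cfg <- tiny_config(n_genes = 150L, frac_de = 0.15, library_size = 1e5,
                     seed = 31L)
  tx <- generate_transcriptome(cfg)
  truth <- simulate_expression(tx, cfg)
  libs <- simulate_mpss_libraries(tx, truth, cfg)
  d1 <- mpss_de(libs, conditions = c("gbm", "normal"))
  d2 <- mpss_de(libs, conditions = c("normal", "gbm"))
  i <- match(d1$fdr$tag, d2$fdr$tag)
  expect_equal(d1$fdr$z, -d2$fdr$z[i])
  expect_equal(d1$fdr$p_emp, d2$fdr$p_emp[i])
  expect_equal(d1$fdr$fdr, d2$fdr$fdr[i])
  expect_setequal(d1$called, d2$called)
})

test_that("planted signal is recovered with good sensitivity", {
  cfg <- tiny_config(n_genes = 400L, isoform_prob = 0, frac_de = 0.1,
                     log2_fc_mean = 2, log2_fc_sd = 0, library_size = 5e5,
                     decoy_frac = 0, n_decoys = 0L, seed = 37L)
  r <- simulate_de_experiment(cfg)
  # documented floor; typical sensitivity at these settings is ~0.8
  expect_gt(r$sensitivity, 0.3)
  expect_gt(r$n_called, 0)
})
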