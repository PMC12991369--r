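test_that("binomial p-values match closed forms and are monotone in k", {
  expect_equal(binomial_pvalue(0, 10, 0.1), 0.9^10)
  expect_equal(binomial_pvalue(1, 10, 0.1), 0.9^10 + 10 * 0.1 * 0.9^9)
  expect_equal(binomial_pvalue(10, 10, 0.1), 1)
  expect_equal(binomial_pvalue(0, 10, 0.2, w = 0.5), 0.9^10) # weight on theta
  k <- 0:50
  expect_true(all(diff(binomial_pvalue(k, 50, 0.07)) >= 0))
  expect_error(binomial_pvalue(0, 10, 1.2), "< 1")
})

test_that("geometric p-values match closed forms and are monotone in l", {
  expect_equal(geometric_pvalue(1, 0.1), 1)
  expect_equal(geometric_pvalue(0, 0.1), 1)
  expect_equal(geometric_pvalue(11, 0.1), 0.9^10)
  expect_equal(geometric_pvalue(5, 0.5), 0.0625)
  expect_equal(geometric_pvalue(5, 1, w = 0.5), 0.5^4)
  expect_true(all(diff(geometric_pvalue(0:100, 0.05)) <= 0))
})

test_that("geometric tail bridges to the exact tail for long genes", {
  b <- 1e5; theta <- 0.05
  l <- 1:100
  expect_lt(max(abs(geometric_pvalue(l, theta) -
                      connis_tail(l, b, round(b * theta), 1))), 0.01)
})

test_that("Tn5Gaps Gumbel p-values match the stated closed form", {
  # p_ins = 0.1, n = 1000: beta = 9.49122, mu = 48.687
  expect_equal(tn5gaps_pvalue(60, 1000, 0.1), 0.261871, tolerance = 1e-4)
  beta <- 1 / log(1 / 0.9)
  mu <- log(1000 * 0.1) * beta + 0.57721566490153286 * beta - 0.5
  expect_equal(tn5gaps_pvalue(mu, 1000, 0.1), 1 - exp(-1), tolerance = 1e-12)
  expect_lt(tn5gaps_pvalue(1e4, 1000, 0.1), 1e-12) # deep tail
  expect_true(all(diff(tn5gaps_pvalue(0:200, 1000, 0.1)) <= 0))
})

test_that("Tn5Gaps approximation is a conservative envelope of the run tail", {
  # The Gumbel location equals the *expected* longest run, which places the
  # approximation above the true tail probability; check the ordering and a
  # coarse agreement against Monte-Carlo longest-run simulation.
  long <- mc_longest_run(n = 1000, p = 0.1, reps = 5000, seed = 99)
  for (x in c(45, 55, 65)) {
    mc <- mean(long >= x)
    approx <- tn5gaps_pvalue(x, 1000, 0.1)
    expect_gt(approx, mc - 0.02)
    expect_lt(abs(approx - mc), 0.2)
  }
})

test_that("the longest overlapping run is reported at full length", {
  iss <- insertion_set(c(8, 25), genome_length = 40)
  ov <- longest_overlapping_run(truncate_genes(gene_set("g", 11, 20)), iss)
  expect_equal(ov$l_ov, 16) # run 9..24 overlaps the gene
  expect_equal(ov$n, 10 + (16 - 10)) # effective length + non-overlap

  # insertion sites everywhere in and adjacent to the gene
  dense <- insertion_set(10:21, genome_length = 40)
  ov2 <- longest_overlapping_run(truncate_genes(gene_set("g", 11, 20)), dense)
  expect_equal(ov2$l_ov, 0)

  expect_warning(
    ov3 <- longest_overlapping_run(truncate_genes(gene_set("g", 11, 20)),
                                   insertion_set(integer(0), genome_length = 40)),
    "empty")
  expect_equal(ov3$l_ov, 40)
})

test_that("the exp-gamma mixture recovers planted parameters", {
  set.seed(7)
  d <- c(rexp(300, rate = 200), rgamma(2700, shape = 3, rate = 30))
  fit <- fit_exp_gamma(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$exp_rate - 200) / 200, 0.2)
  expect_lt(abs(fit$gamma_shape - 3) / 3, 0.2)
  expect_equal(fit$mix_weight, 0.1, tolerance = 0.5)
  # EM objective never decreases
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("degenerate insertion-index data fall back with a warning", {
  expect_warning(fit <- fit_exp_gamma(rep(0.07, 60)), "antimode")
  expect_s3_class(fit, "exp_gamma_fit")
  expect_error(fit_exp_gamma(rep(0.1, 10)), "at least 50")
  expect_error(fit_exp_gamma(c(rep(-1, 60))), ">= 0")
})

test_that("likelihood-ratio labels follow the threshold rule", {
  fit <- structure(list(mix_weight = 0.1, exp_rate = 50, gamma_shape = 3,
                        gamma_rate = 30, converged = TRUE,
                        split_point = 0.02, zero_repl = NA_real_),
                   class = "exp_gamma_fit")
  lab <- exp_gamma_label(0.001, fit, t = 2)
  expect_equal(lab$LR, log2(dexp(0.001, 50) / dgamma(0.001, 3, rate = 30)))
  expect_equal(lab$LR, 11.83, tolerance = 1e-3)
  expect_equal(lab$label, "essential")
  # equal densities: LR = 0 is ambiguous at any positive threshold
  d_eq <- uniroot(function(x) dexp(x, 50) - dgamma(x, 3, rate = 30),
                  c(0.001, 0.2))$root
  expect_equal(exp_gamma_label(d_eq, fit, 2)$label, "ambiguous")
  # at the gamma mode the exponential density is negligible
  expect_equal(exp_gamma_label(2 / 30, fit, 2)$label, "non-essential")
})

test_that("weighted callers produce consistent result tables", {
  lib <- easy_library()
  s <- summarize_genes(lib$genes, lib$iss, 0.05)
  theta <- genome_density(lib$iss)
  for (m in c("connis", "binomial", "geometric", "tn5gaps")) {
    res <- call_method(lib$genes, lib$iss, method = m, tuning = 0.5,
                       trunc_frac = 0.05)
    expect_equal(nrow(res), nrow(lib$genes))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
    expect_equal(res$essential, res$p_adjusted <= 0.05)
  }
  resx <- call_method(lib$genes, lib$iss, method = "exp_gamma", tuning = 4,
                      trunc_frac = 0.05)
  expect_true(all(resx$label %in% c("essential", "ambiguous",
                                    "non-essential")))
  expect_equal(resx$essential, resx$label == "essential")
})
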