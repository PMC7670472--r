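study_row <- function(mt, st, nt, ma, sa, na, variable = "gpp") {
  tibble::tibble(variable = variable, source = "model",
                 mean_treat = mt, sd_treat = st, n_treat = nt,
                 mean_ambient = ma, sd_ambient = sa, n_ambient = na)
}

test_that("log response ratio and sampling variance follow the defining formulas", {
  s <- study_row(1.2, 0.2, 5, 1.0, 0.1, 6)
  eff <- log_response_ratio(s)
  expect_equal(eff$lnr, log(1.2), tolerance = 1e-12)
  expect_equal(eff$lnr, 0.1823215568, tolerance = 1e-9)
  expect_equal(eff$v, 0.2^2 / (5 * 1.2^2) + 0.1^2 / (6 * 1.0^2),
               tolerance = 1e-12)
  # identity case and degenerate variance
  expect_equal(log_response_ratio(study_row(3, 0.5, 4, 3, 0.5, 4))$lnr, 0)
  expect_equal(log_response_ratio(study_row(2, 0, 4, 1, 0, 4))$v, 0)
  # optional normalized-sd interpretation
  eff_cv <- log_response_ratio(s, normalized_sd = TRUE)
  expect_equal(eff_cv$v, 0.2^2 / 5 + 0.1^2 / 6, tolerance = 1e-12)
})

test_that("non-positive means raise an error naming the study", {
  expect_error(log_response_ratio(study_row(-1, 0.1, 4, 1, 0.1, 4,
                                            variable = "reco")),
               "reco")
})

test_that("pooling is an inverse-variance weighted mean with symmetric log-scale CI", {
  eff <- tibble::tibble(lnr = c(0.1, 0.3), v = c(0.02, 0.02))
  pooled <- pooled_effect(eff)
  expect_equal(pooled$lnr_bar, 0.2, tolerance = 1e-12)  # equal weights
  expect_equal(pooled$se, sqrt(1 / sum(1 / eff$v)), tolerance = 1e-12)
  expect_equal(pooled$ci_hi - pooled$lnr_bar, pooled$lnr_bar - pooled$ci_lo,
               tolerance = 1e-12)
  # single study: pooled equals the study
  one <- pooled_effect(tibble::tibble(lnr = 0.25, v = 0.04))
  expect_equal(one$lnr_bar, 0.25)
  expect_equal(one$se, 0.2)
  # percent divergence transform
  expect_equal(pooled_effect(tibble::tibble(lnr = log(1.2), v = 1))$
                 percent_divergence, 20, tolerance = 1e-9)
  expect_error(pooled_effect(tibble::tibble(lnr = numeric(), v = numeric())),
               "no studies")
})

test_that("pooling is invariant to study order and common variance rescaling", {
  set.seed(42)
  eff <- tibble::tibble(lnr = rnorm(8, 0.2, 0.1), v = runif(8, 0.01, 0.1))
  p1 <- pooled_effect(eff)
  p2 <- pooled_effect(eff[sample(8), ])
  p3 <- pooled_effect(transform(eff, v = v * 7.3))
  expect_equal(p1$lnr_bar, p2$lnr_bar, tolerance = 1e-12)
  expect_equal(p1$lnr_bar, p3$lnr_bar, tolerance = 1e-12)
})

test_that("pooled results match brute-force arithmetic and the metafor fixed-effect fit", {
  set.seed(7)
  studies <- simulate_ratio_studies(1.3, n_reps = 8, k_studies = 6, seed = 3)
  eff <- log_response_ratio(studies)
  pooled <- pooled_effect(eff)
  ora <- oracle_pool(eff$lnr, eff$v)
  expect_equal(pooled$lnr_bar, unname(ora["est"]), tolerance = 1e-12)
  expect_equal(pooled$se, unname(ora["se"]), tolerance = 1e-12)
  skip_if_not_installed("metafor")
  fit <- metafor::rma(yi = eff$lnr, vi = eff$v, method = "FE")
  expect_equal(pooled$lnr_bar, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(pooled$se, as.numeric(fit$se), tolerance = 1e-10)
})

test_that("parameter recovery: pooled ratio converges to the generating truth", {
  reps <- vapply(1:60, function(i) {
    st <- simulate_ratio_studies(1.2, n_reps = 50, k_studies = 4, seed = i)
    exp(pooled_effect(log_response_ratio(st))$lnr_bar)
  }, numeric(1))
  expect_lt(abs(mean(reps) - 1.2) / 1.2, 0.02)
})

test_that("the forest table pools per variable x source and flags one-sided variables", {
  m <- rbind(study_row(1.25, 0.2, 5, 1.0, 0.2, 5, "gpp"),
             study_row(1.30, 0.2, 5, 1.0, 0.2, 5, "reco"))
  e <- m
  tab <- model_vs_empirical_table(m, e)
  expect_equal(nrow(tab), 4)
  # identical inputs give identical pooled rows per source
  for (v in c("gpp", "reco")) {
    sub <- tab[tab$variable == v, ]
    expect_equal(sub$percent_divergence[1], sub$percent_divergence[2])
  }
  expect_warning(
    model_vs_empirical_table(m, e[e$variable == "gpp", ]),
    "one source only")
})

test_that("a replicated warming pair feeds the meta-analysis with the right shape and sign", {
  pe <- gen_warming_pair(site_preset("foothills-tundra"), delta = 1,
                         n_years = 4, n_reps = 3, seed = 5)
  expect_s3_class(pe, "paired_experiment")
  expect_length(pe$control_runs, 3)
  expect_length(pe$treated_runs, 3)
  expect_equal(nrow(pe$studies), 2)
  expect_setequal(pe$studies$variable, c("gpp", "reco"))
  # respiration-dominant site warms: treated ecosystem respiration higher
  reco <- pe$studies[pe$studies$variable == "reco", ]
  expect_gt(reco$mean_treat / reco$mean_ambient, 1)
  expect_error(gen_warming_pair(site_preset("boreal-forest"), 1, n_reps = 1),
               "n_reps")
  expect_error(gen_warming_pair(site_preset("boreal-forest"), 4), "\\[0, 3\\]")
})
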