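test_that("latent-scale ICC identities hold", {
  expect_equal(icc_latent(0), 0)
  expect_equal(icc_latent(pi^2 / 3), 0.5)
  expect_equal(icc_latent(1), 1 / (1 + pi^2 / 3))
  expect_true(all(diff(icc_latent(seq(0, 5, 0.1))) > 0))  # strictly increasing
  expect_error(icc_latent(-0.1), "non-negative")
})

test_that("range odds ratio matches direct percentile computation", {
  expect_equal(range_or(rep(0, 10)), 1.0)
  set.seed(31)
  x <- rnorm(20)
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  expect_equal(range_or(x), exp(q[2] - q[1]))
  # location invariance
  expect_equal(range_or(x + 3.7), range_or(x))
  # large standard-normal sample approaches exp(2 * 1.6449) ~ 26.8
  z <- rnorm(2e5)
  expect_equal(range_or(z), exp(2 * qnorm(0.95)), tolerance = 0.02)
  expect_error(range_or(0.5), "at least 2")
})

test_that("odds ratios exponentiate coefficients with Wald intervals", {
  m <- structure(list(beta = c(a = 0, b = log(2)),
                      beta_cov = diag(c(0.04, 0))),
                 class = "fitted_cluster_model")
  or <- odds_ratios(m)
  expect_equal(or$or, c(1, 2))
  expect_equal(or$ci_low[2], 2)
  expect_equal(or$ci_high[2], 2)
  expect_lt(or$ci_low[1], 1); expect_gt(or$ci_high[1], 1)
  expect_equal(or$ci_low[1], exp(-qnorm(0.975) * 0.2))
})

test_that("without clustering the fit degenerates to plain logistic regression", {
  sim <- generate_clustered_binary(30, 40, sigma_b = 0,
                                   beta = c(intercept = -0.4, male = 0.6),
                                   seed = 8)
  fit <- fit_random_intercept_logistic(sim$data, "y", "male")
  expect_lt(fit$sigma2_b, 0.05)
  plain <- glm(y ~ male, data = sim$data, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(plain)), tolerance = 0.02)
})

test_that("marginal log-likelihood agrees with fine-grid quadrature", {
  # adaptive Gauss-Hermite fit on a small clustered dataset
  sim <- generate_clustered_binary(5, 12, sigma_b = 0.8,
                                   beta = c(intercept = -0.2), seed = 14)
  fit <- fit_random_intercept_logistic(sim$data, "y", character(), nagq = 25L)
  X <- matrix(1, nrow(sim$data), 1)
  ll <- grid_loglik(fit$beta, sqrt(fit$sigma2_b), sim$data$y, X,
                    sim$data$gp_id)
  expect_equal(fit$loglik, ll, tolerance = 1e-4)

  # 2-cluster, 4-row hand dataset
  hand <- tibble::tibble(y = c(1, 0, 1, 1), gp_id = c("a", "a", "b", "b"))
  fit2 <- fit_random_intercept_logistic(hand, "y", character(), nagq = 25L)
  ll2 <- grid_loglik(fit2$beta, max(sqrt(fit2$sigma2_b), 1e-8), hand$y,
                     matrix(1, 4, 1), hand$gp_id)
  expect_equal(fit2$loglik, ll2, tolerance = 1e-4)
})

test_that("predicted intercepts are shrunken conditional modes", {
  sim <- generate_clustered_binary(60, 25, sigma_b = 1, seed = 3)
  fit <- fit_random_intercept_logistic(sim$data, "y")
  expect_equal(fit$n_clusters, 60)
  expect_lte(var(fit$intercepts), fit$sigma2_b)
  # intercepts correlate with the realised truth
  expect_gt(cor(fit$intercepts, sim$truth$intercepts), 0.5)
})

test_that("degenerate inputs are rejected", {
  sim <- generate_clustered_binary(2, 5, 0.5, seed = 2)
  one <- sim$data[sim$data$gp_id == "c0001", ]
  expect_error(fit_random_intercept_logistic(one, "y"), "2 clusters")
  bad <- sim$data; bad$y <- bad$y + 2
  expect_error(fit_random_intercept_logistic(bad, "y"), "binary")
})

test_that("full/null variation analysis returns coherent summaries", {
  sim <- generate_clustered_binary(40, 30, sigma_b = 0.8,
                                   beta = c(intercept = 0, male = 0.4),
                                   seed = 99)
  # dress the harness output up as a qi_result + covariates
  flags <- tibble::tibble(patient_id = sprintf("p%05d", seq_len(nrow(sim$data))),
                          gp_id = sim$data$gp_id, in_denominator = TRUE,
                          achieved = sim$data$y == 1)
  qi <- structure(list(qi_id = 1L, category = "assessment",
                       description = "test", flags = flags,
                       n_denominator = nrow(flags),
                       n_numerator = sum(flags$achieved),
                       achievement_rate = 100 * mean(flags$achieved)),
                  class = "qi_result")
  covs <- tibble::tibble(patient_id = flags$patient_id,
                         patient_gender = ifelse(sim$data$male == 1, "male",
                                                 "female"))
  v <- analyse_qi_variation(qi, covs)
  expect_s3_class(v, "variation_summary")
  expect_true(v$ror >= 1)
  expect_true(v$icc >= 0 && v$icc < 1)
  expect_equal(v$icc, icc_latent(v$sigma2_b_null))
  expect_equal(v$ror, range_or(v$null_model$intercepts))
  expect_true("patient_gendermale" %in% v$or_table$term)
  # the male effect estimate should be near its true log-odds
  est <- log(v$or_table$or[v$or_table$term == "patient_gendermale"])
  expect_lt(abs(est - 0.4), 0.3)
})

test_that("Wald intervals cover the true odds ratio at near-nominal rate", {
  true_beta <- 0.5
  covered <- vapply(1:60, function(i) {
    sim <- generate_clustered_binary(30, 40, sigma_b = 0.6,
                                     beta = c(intercept = -0.3,
                                              male = true_beta),
                                     seed = 7000 + i)
    fit <- fit_random_intercept_logistic(sim$data, "y", "male")
    or <- odds_ratios(fit)
    row <- or[or$term == "male", ]
    row$ci_low <= exp(true_beta) && exp(true_beta) <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)  # nominal 95%, binomial MC noise allowed
})

test_that("patients of 'other' gender are excluded from model rows", {
  flags <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                          gp_id = c("g1", "g1", "g2", "g2"),
                          in_denominator = TRUE,
                          achieved = c(TRUE, FALSE, TRUE, FALSE))
  covs <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                         patient_gender = c("female", "other", "male",
                                            "female"))
  qi <- structure(list(qi_id = 2L, flags = flags), class = "qi_result")
  rows <- model_rows(qi, covs)
  expect_equal(nrow(rows), 3)
  expect_false(any(is.na(rows$patient_gender)))
})
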