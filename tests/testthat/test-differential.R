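test_that("per-feature OLS recovers exact group differences", {
  ss <- toy_sample_sheet(3, 3)
  x <- rbind(f1 = c(3, 3, 3, 1, 1, 1))
  colnames(x) <- ss$sample_id
  design <- build_design(ss, covariates = NULL)
  fit <- fit_feature_lm(x, design)
  expect_equal(fit$logfc[1], 2)
  expect_equal(fit$s2[1], 0)

  # logfc equals the difference of group means to 1e-12 without covariates
  set.seed(2)
  ss2 <- toy_sample_sheet(6, 5)
  y <- matrix(rnorm(11 * 20), 20, 11, dimnames = list(paste0("f", 1:20), ss2$sample_id))
  f2 <- fit_feature_lm(y, build_design(ss2, covariates = NULL))
  is_ad <- ss2$group == "AD"
  expect_equal(f2$logfc, rowMeans(y[, is_ad]) - rowMeans(y[, !is_ad]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a covariate orthogonal to group leaves logfc unchanged
  ss3 <- toy_sample_sheet(4, 4)
  ss3$age <- rep(c(30, 40, 50, 60), 2)      # identical within both groups
  y3 <- matrix(rnorm(8 * 10), 10, 8, dimnames = list(paste0("f", 1:10), ss3$sample_id))
  fa <- fit_feature_lm(y3, build_design(ss3, covariates = NULL))
  fb <- fit_feature_lm(y3, build_design(ss3, covariates = "age"))
  expect_equal(fa$logfc, fb$logfc, tolerance = 1e-10)
})

test_that("missing values are handled by complete-sample fitting", {
  ss <- toy_sample_sheet(4, 4)
  x <- matrix(rnorm(16), 2, 8, dimnames = list(c("f1", "f2"), ss$sample_id))
  x[2, 1:2] <- NA
  fit <- fit_feature_lm(x, build_design(ss, covariates = NULL))
  is_ad <- ss$group == "AD"
  expect_equal(fit$logfc[2],
               mean(x[2, is_ad], na.rm = TRUE) - mean(x[2, !is_ad]),
               tolerance = 1e-12)
  expect_equal(fit$df[2], 4)
  # a feature left with too few samples is flagged untested
  x[2, 1:7] <- NA
  fit2 <- fit_feature_lm(x, build_design(ss, covariates = NULL))
  expect_false(fit2$tested[2])
})

test_that("subject blocking is honored only when estimable", {
  ss <- toy_sample_sheet(3, 3)
  expect_warning(build_design(ss, covariates = NULL, subject = TRUE),
                 "confounded")
  # honored when subjects are crossed with group (paired samples)
  ss2 <- data.frame(
    sample_id = paste0("x", 1:12),
    group = rep(c("AD", "HC"), 6),
    age = rep(30:35, each = 2),
    subject_id = rep(paste0("S", 1:6), each = 2),
    stringsAsFactors = FALSE
  )
  d <- build_design(ss2, covariates = NULL, subject = TRUE)
  expect_true(any(grepl("subject_id", colnames(d))))
  # repeated measures nested in group stay confounded and are dropped
  ss3 <- toy_sample_sheet(3, 3)
  ss3 <- rbind(ss3, ss3)
  ss3$sample_id <- paste0(ss3$sample_id, rep(c("a", "b"), each = 6))
  expect_warning(d3 <- build_design(ss3, covariates = NULL, subject = TRUE),
                 "confounded")
  expect_false(any(grepl("subject_id", colnames(d3))))
})

test_that("variance prior recovers hierarchical hyperparameters", {
  set.seed(11)
  d0 <- 4; s0 <- 1; d <- 12; nfeat <- 5000
  sigma2 <- s0 * d0 / rchisq(nfeat, d0)        # scaled inverse chi-square prior
  s2 <- sigma2 * rchisq(nfeat, d) / d
  pr <- estimate_prior(s2, d)
  expect_lt(abs(pr$d0 - d0), 0.5)
  expect_lt(abs(pr$s0_sq - s0), 0.1)

  # identical variances: no excess spread, d0 = Inf
  pr2 <- estimate_prior(rep(2, 100), 10)
  expect_identical(pr2$d0, Inf)

  expect_error(estimate_prior(c(1, 2), 10), "at least 10")
  expect_error(estimate_prior(rep(0, 50), 10), "zero")
})

test_that("moderated test with d0 = 0 is exactly the classical t-test", {
  set.seed(3)
  ss <- toy_sample_sheet(6, 5)
  x <- matrix(rnorm(11 * 50), 50, 11, dimnames = list(paste0("f", 1:50), ss$sample_id))
  design <- build_design(ss, covariates = "age")
  fit <- fit_feature_lm(x, design)
  tab <- moderated_test(fit, list(d0 = 0, s0_sq = 1))
  # oracle: per-feature lm summary t for the group coefficient
  ss_f <- transform(ss, group = factor(group, levels = c("HC", "AD")))
  for (i in c(1, 7, 23, 50)) {
    sm <- summary(lm(x[i, ] ~ group + age, data = ss_f))
    expect_equal(tab$t_mod[i], sm$coefficients["groupAD", "t value"],
                 tolerance = 1e-10)
    expect_equal(tab$p[i], sm$coefficients["groupAD", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("moderated test matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  ss <- toy_sample_sheet(6, 6)
  x <- matrix(rnorm(12 * 300, sd = rep(sqrt(0.5 * 4 / rchisq(300, 4)), 12)),
              300, 12, dimnames = list(paste0("f", 1:300), ss$sample_id))
  design <- build_design(ss, covariates = "age")
  fit <- fit_feature_lm(x, design)
  prior <- estimate_prior(fit$s2, fit$df)
  tab <- moderated_test(fit, prior)

  lf <- limma::lmFit(x, design)
  eb <- limma::eBayes(lf)
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t_mod, unname(eb$t[, "groupAD"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(eb$p.value[, "groupAD"]), tolerance = 1e-8)
})

test_that("shrinkage limit d0 = Inf pools variances", {
  ss <- toy_sample_sheet(4, 4)
  x <- rbind(f1 = c(2, 2.1, 1.9, 2, 0, 0.1, -0.1, 0),
             f2 = c(2, 1.9, 2.1, 2, 0, -0.1, 0.1, 0))
  colnames(x) <- ss$sample_id
  fit <- fit_feature_lm(x, build_design(ss, covariates = NULL))
  tab <- moderated_test(fit, list(d0 = Inf, s0_sq = 0.25))
  # equal logfc implies equal p under the pooled variance
  expect_equal(tab$logfc[1], tab$logfc[2])
  expect_equal(tab$p[1], tab$p[2])
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 9)), rep(0.07, 9))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("DMP calling thresholds and partitions by direction", {
  dmps <- load_cla_dmps()
  dt <- data.frame(feature_id = dmps$probe_id, logfc = dmps$logfc,
                   p = dmps$p, p_bh = dmps$p_bh,
                   direction = sign(dmps$logfc), tested = TRUE)
  expect_identical(nrow(call_dmps(dt, 0.05)), 49L)
  expect_identical(nrow(call_dmps(dt, 0.05, direction = 1)), 12L)
  expect_identical(nrow(call_dmps(dt, 0)), 0L)
})
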