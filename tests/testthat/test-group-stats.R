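test_that("the normality gate rejects heavy tails and passes Gaussians", {
  set.seed(101)
  heavy <- rt(100, df = 2)
  expect_equal(normality_gate(heavy), "non_normal")
  set.seed(102)
  expect_equal(normality_gate(rnorm(100)), "normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
  expect_warning(g <- normality_gate(rep(5, 20)), "constant")
  expect_equal(g, "non_normal")
})

test_that("the gate's type-I rate matches its nominal level", {
  set.seed(103)
  rejections <- vapply(1:200, function(i) {
    normality_gate(rnorm(100)) == "non_normal"
  }, logical(1))
  rate <- mean(rejections)
  # binomial sampling band around alpha = 0.05 at n = 200
  expect_lt(abs(rate - 0.05), 0.045)
})

test_that("identical groups give a null comparison", {
  d <- tibble::tibble(group = rep(c("SCA", "control"), each = 20),
                      y = rep(c(1, 2, 3, 4), 10))
  res <- compare_groups(d, "y")
  expect_gt(res$p, 0.9)
  expect_equal(res$cohens_d, 0)
})

test_that("a planted gray-matter-sized effect is overwhelmingly detected", {
  set.seed(104)
  d <- tibble::tibble(
    group = rep(c("SCA", "control"), c(89, 42)),
    y = c(rnorm(89, 54.06, 7.78), rnorm(42, 42.52, 7.13)))
  res <- compare_groups(d, "y")
  expect_lt(res$p, 1e-4)
  expect_gt(res$estimate, 0)          # SCA minus control
  expect_gt(res$cohens_d, 1)
})

test_that("the t branch reproduces the textbook Welch formula by hand", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      y = c(1, 2, 3, 2, 4, 6))
  res <- compare_groups(d, "y")
  # hand arithmetic: means 2 and 4, variances 1 and 4
  se <- sqrt(1 / 3 + 4 / 3)
  t_hand <- (2 - 4) / se
  df_hand <- (1 / 3 + 4 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(t_hand, df_hand), tolerance = 1e-12)
  # pooled form on request
  res_p <- compare_groups(d, "y", var_equal = TRUE)
  sp <- sqrt((2 * 1 + 2 * 4) / 4)
  expect_equal(res_p$statistic, (2 - 4) / (sp * sqrt(1 / 3 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("non-normal features route to Mann-Whitney with rank-biserial effect", {
  set.seed(105)
  d <- tibble::tibble(
    group = rep(c("SCA", "control"), c(60, 40)),
    y = c(rlnorm(60, 4.7, 0.45), rlnorm(40, 4.2, 0.25)))
  res <- compare_groups(d, "y")
  expect_equal(res$test, "mann_whitney_u")
  expect_equal(res$effect_type, "rank_biserial")
  expect_gt(res$effect, 0)
  expect_lt(res$p, 0.01)
  expect_error(compare_groups(
    tibble::tibble(group = c("a", "a", "b", "b"), y = c(1, 1, 1, 1)), "y"),
    "degenerate")
})

test_that("age/sex adjustment preserves scale and removes covariate structure", {
  set.seed(106)
  n <- 60
  d <- tibble::tibble(age = runif(n, 8, 28),
                      sex = sample(c("male", "female"), n, TRUE),
                      y = rnorm(n, 50, 5))
  out <- adjust_age_sex(d, "y", log_if_non_normal = FALSE)
  expect_equal(mean(out$y_adj), mean(d$y), tolerance = 1e-10)
  expect_lt(abs(cor(out$y_adj, d$age)), 1e-10)
  # a feature that is exactly 2*age adjusts to a constant at the grand mean
  d2 <- d; d2$y <- 2 * d2$age
  out2 <- adjust_age_sex(d2, "y", log_if_non_normal = FALSE)
  expect_equal(out2$y_adj, rep(mean(d2$y), n), tolerance = 1e-8)
})

test_that("adjustment equals the hand-rolled normal-equations oracle", {
  set.seed(107)
  n <- 40
  d <- tibble::tibble(age = runif(n, 8, 28),
                      sex = sample(c("male", "female"), n, TRUE),
                      y = rnorm(n, 20, 4))
  out <- adjust_age_sex(d, "y", log_if_non_normal = FALSE)
  X <- cbind(1, d$age, as.numeric(factor(d$sex)) - 1)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  oracle <- d$y - as.vector(X %*% beta) + mean(d$y)
  expect_equal(out$y_adj, oracle, tolerance = 1e-10)
  # single-sex data drop the sex term with a warning
  d3 <- d; d3$sex <- "male"
  expect_warning(adjust_age_sex(d3, "y", log_if_non_normal = FALSE),
                 "single-sex")
})

test_that("correlations behave on exact and monotone-transformed data", {
  x <- seq_len(20)
  expect_equal(correlate(x, -x)$estimate, -1)
  set.seed(108)
  a <- rnorm(30); b <- a + rnorm(30, 0, 0.5)
  s1 <- correlate(a, b, method = "spearman")
  s2 <- correlate(exp(a), b, method = "spearman")   # monotone transform
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-12)
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
  expect_error(correlate(1:3, 3:1), "4 paired")
})

test_that("stratified BH adjustment matches the step-up definition", {
  r <- tibble::tibble(p = c(0.01, 0.02, 0.03, 0.04), family = "one")
  out <- bh_fdr(r, by = "family")
  expect_equal(out$p_adj, rep(0.04, 4))
  single <- bh_fdr(tibble::tibble(p = 0.2))
  expect_equal(single$p_adj, 0.2)
  # strata are adjusted independently of each other
  set.seed(109)
  r2 <- tibble::tibble(p = runif(12),
                       group = rep(c("SCA", "control"), each = 6),
                       family = rep(c("A", "B"), 6))
  out2 <- bh_fdr(r2, by = c("group", "family"))
  for (g in c("SCA", "control")) for (f in c("A", "B")) {
    sel <- r2$group == g & r2$family == f
    expect_equal(out2$p_adj[sel], bh_oracle(r2$p[sel]))
  }
  expect_true(all(out2$p_adj >= out2$p))
  expect_error(bh_fdr(tibble::tibble(p = c(0.5, 1.2))), "0, 1")
})

test_that("BH equals the brute-force oracle on random p-vectors", {
  set.seed(110)
  for (i in 1:50) {
    m <- sample(1:8, 1)
    p <- runif(m)
    out <- bh_fdr(tibble::tibble(p = p))
    expect_equal(out$p_adj, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("cognition regression recovers exact linear structure", {
  set.seed(111)
  n <- 40
  d <- tibble::tibble(
    age = runif(n, 8, 28), sex = sample(c("male", "female"), n, TRUE),
    hydroxycarbamide = runif(n) < 0.4, transfusion = runif(n) < 0.1,
    sci_burden = rpois(n, 30), etiv = rnorm(n, 1.4e6, 1e5),
    education_decile = sample(1:10, n, TRUE),
    x = rnorm(n, 100, 20))
  d$iq <- 80 - 0.5 * d$x + 0.3 * d$age
  fit <- cognition_regression(d, "iq", "x", enforce_gate = FALSE)
  td <- suppressWarnings(tidy(fit))   # lm warns on an essentially perfect fit
  expect_equal(td$b[td$term == "x"], -0.5, tolerance = 1e-8)
  expect_equal(abs(td$partial_r[td$term == "x"]), 1, tolerance = 1e-6)
})

test_that("standardised beta and partial r satisfy their identities", {
  set.seed(112)
  n <- 60
  d <- tibble::tibble(
    age = runif(n, 8, 28), sex = sample(c("male", "female"), n, TRUE),
    hydroxycarbamide = runif(n) < 0.4, transfusion = runif(n) < 0.1,
    sci_burden = rpois(n, 30), etiv = rnorm(n, 1.4e6, 1e5),
    education_decile = sample(1:10, n, TRUE),
    x = rlnorm(n, 5, 0.5))
  d$iq <- 95 - 4 * log(d$x) + rnorm(n, 0, 8)
  fit <- cognition_regression(d, "iq", "x", log_predictors = "x",
                              enforce_gate = FALSE)
  td <- tidy(fit)
  row <- td[td$term == "log_x", ]
  expect_equal(row$beta, row$b * sd(log(d$x)) / sd(d$iq), tolerance = 1e-10)
  sm <- summary(fit$fit)$coefficients
  tval <- sm["log_x", "t value"]
  expect_equal(row$partial_r, tval / sqrt(tval^2 + fit$fit$df.residual),
               tolerance = 1e-12)
  gl <- glance(fit)
  expect_true(gl$r_squared > 0 && gl$r_squared <= 1)
})

test_that("the univariate screen and sample-size guards are enforced", {
  set.seed(113)
  n <- 30
  d <- tibble::tibble(
    age = runif(n, 8, 28), sex = sample(c("male", "female"), n, TRUE),
    hydroxycarbamide = runif(n) < 0.4, transfusion = runif(n) < 0.1,
    sci_burden = rpois(n, 30), etiv = rnorm(n, 1.4e6, 1e5),
    education_decile = sample(1:10, n, TRUE),
    x = rnorm(n), iq = rnorm(n, 100, 10))   # x unrelated to iq
  expect_error(cognition_regression(d, "iq", "x"), "screen")
  expect_s3_class(cognition_regression(d, "iq", "x", enforce_gate = FALSE),
                  "cognition_fit")
  expect_error(cognition_regression(d[1:8, ], "iq", "x",
                                    enforce_gate = FALSE), "complete cases")
})
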