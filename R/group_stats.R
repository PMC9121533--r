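#' Normality gate
#'
#' Shapiro-Wilk screen that routes downstream analyses: `"normal"` when the
#' test does not reject at `alpha`, `"non_normal"` otherwise. Constant
#' vectors are classed non-normal with a warning (the test is undefined).
#'
#' @param x Numeric vector, n >= 3 (finite values only are used).
#' @param alpha Test level (default 0.05).
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    stop("normality_gate: need at least 3 finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    warning("normality_gate: constant vector; classing as non_normal")
    return("non_normal")
  }
  if (stats::shapiro.test(x)$p.value < alpha) "non_normal" else "normal"
}

#' Two-group comparison with a normality-gated test choice
#'
#' Compares one feature between two groups: an independent t-test when both
#' groups pass the normality gate, Mann-Whitney U otherwise. Always
#' two-sided. The t branch defaults to the Welch form (the generator plants
#' unequal venous-BAT variances, and Welch is R's default independent
#' t-test); set `var_equal = TRUE` for the pooled form. Reports Cohen's d
#' (pooled SD) alongside, and the rank-biserial correlation on the U
#' branch, with the mean difference / Hodges-Lehmann estimate and its 95%
#' CI. The first group level (patients, `"SCA"`, when present) minus the
#' second.
#'
#' @param data A data frame.
#' @param feature Name of the feature column (string).
#' @param group Name of the two-level group column (string).
#' @param alpha Normality-gate level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return One-row tibble (`StatResult` layout): comparison, test,
#'   statistic, p, effect size, estimate, CI, group sizes.
#' @export
compare_groups <- function(data, feature, group = "group", alpha = 0.05,
                           var_equal = FALSE) {
  x <- data[[feature]]; g <- data[[group]]
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- as.character(g[keep])
  lev <- unique(g)
  if (length(lev) != 2) {
    stop("compare_groups: need exactly two groups", call. = FALSE)
  }
  # fixed orientation: SCA (or first level alphabetically) minus the other
  lev <- if (setequal(lev, c("SCA", "control"))) c("SCA", "control")
         else sort(lev)
  x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
  if (length(x1) < 2 || length(x2) < 2 || stats::sd(x1) == 0 ||
      stats::sd(x2) == 0) {
    stop("compare_groups: degenerate group", call. = FALSE)
  }
  gate <- c(normality_gate(x1, alpha), normality_gate(x2, alpha))
  sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                (length(x2) - 1) * stats::var(x2)) /
               (length(x1) + length(x2) - 2))
  d <- (mean(x1) - mean(x2)) / sp
  if (all(gate == "normal")) {
    tt <- stats::t.test(x1, x2, var.equal = var_equal, conf.int = TRUE)
    res <- tibble::tibble(test = if (var_equal) "student_t" else "welch_t",
                          statistic = unname(tt$statistic),
                          p = tt$p.value, effect = d,
                          effect_type = "cohens_d",
                          estimate = mean(x1) - mean(x2),
                          conf_low = tt$conf.int[1],
                          conf_high = tt$conf.int[2])
  } else {
    wt <- stats::wilcox.test(x1, x2, conf.int = TRUE, exact = FALSE)
    u <- unname(wt$statistic)
    rb <- 2 * u / (length(x1) * length(x2)) - 1   # rank-biserial
    res <- tibble::tibble(test = "mann_whitney_u", statistic = u,
                          p = wt$p.value, effect = rb,
                          effect_type = "rank_biserial",
                          estimate = unname(wt$estimate),
                          conf_low = wt$conf.int[1],
                          conf_high = wt$conf.int[2])
  }
  dplyr::bind_cols(
    tibble::tibble(comparison = sprintf("%s: %s vs %s", feature,
                                        lev[1], lev[2]),
                   feature = feature, cohens_d = d),
    res,
    tibble::tibble(n1 = length(x1), n2 = length(x2))
  )
}

#' Age- and sex-adjust a feature
#'
#' Regresses the (optionally log-transformed) feature on age and sex by
#' ordinary least squares and returns residuals plus the grand mean, which
#' preserves the feature's units and scale for plotting against covariates.
#' When `log_if_non_normal` is set, the feature is log-transformed first if
#' the normality gate rejects; the returned `.logged` flag records this.
#' Single-sex data drop the sex term with a warning.
#'
#' @param data A data frame with `age` and `sex` columns (no missing
#'   values among rows with a finite feature).
#' @param feature Feature column name (string).
#' @param log_if_non_normal Log-transform non-normal features first.
#' @param alpha Normality-gate level.
#' @return The data with two added columns: `<feature>_adj` (adjusted
#'   values, on the log scale if transformed) and `<feature>_adj_logged`.
#' @export
adjust_age_sex <- function(data, feature, log_if_non_normal = TRUE,
                           alpha = 0.05) {
  y <- data[[feature]]
  keep <- is.finite(y)
  if (any(is.na(data$age[keep])) || any(is.na(data$sex[keep]))) {
    stop("adjust_age_sex: missing age/sex", call. = FALSE)
  }
  logged <- FALSE
  if (log_if_non_normal && normality_gate(y[keep], alpha) == "non_normal") {
    if (any(y[keep] <= 0)) {
      warning("adjust_age_sex: non-positive values; skipping log transform")
    } else {
      y <- log(y); logged <- TRUE
    }
  }
  df <- data.frame(y = y[keep], age = data$age[keep],
                   sex = factor(data$sex[keep]))
  fml <- if (nlevels(df$sex) < 2) {
    warning("adjust_age_sex: single-sex data; dropping sex term")
    y ~ age
  } else y ~ age + sex
  fit <- stats::lm(fml, data = df)
  adj <- rep(NA_real_, nrow(data))
  adj[keep] <- stats::residuals(fit) + mean(df$y)
  data[[paste0(feature, "_adj")]] <- adj
  data[[paste0(feature, "_adj_logged")]] <- logged
  tibble::as_tibble(data)
}

#' Correlation between an adjusted feature and a covariate
#'
#' Pearson or Spearman correlation with a two-sided p-value, on pairwise
#' finite observations.
#'
#' @param x,y Numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param label Optional comparison label.
#' @return One-row tibble: coefficient, statistic, p, n.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      label = NA_character_) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("correlate: need >= 4 paired finite values",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  tibble::tibble(comparison = label, method = method,
                 estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic), p = ct$p.value,
                 n = length(x))
}

#' Stratified Benjamini-Hochberg FDR adjustment
#'
#' Applies the BH step-up adjustment independently within each stratum
#' defined by the grouping keys — in this pipeline, within each
#' participant group and within each parameter-map family (single-TI CBF,
#' multi-TI CBF, multi-TI BAT).
#'
#' @param results A data frame with a raw `p` column.
#' @param by Character vector of stratum key columns (may be empty).
#' @return `results` with a `p_adj` column added.
#' @export
bh_fdr <- function(results, by = character()) {
  stopifnot(is.data.frame(results), "p" %in% names(results))
  if (any(!is.na(results$p) & (results$p < 0 | results$p > 1))) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(results)
  if (length(by) == 0) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    return(out)
  }
  out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
}

#' Covariate-adjusted cognition regression
#'
#' Ordinary least squares of a cognitive outcome on one or more hemodynamic
#' predictors plus the pre-selected covariates (age, sex, hydroxycarbamide
#' use, chronic transfusion, SCI burden, total intracranial volume,
#' education decile), on complete cases within one group. By default the
#' model is only fitted when the primary predictor passes a univariate
#' screen (p < `gate_p`, uncorrected); predictors flagged in
#' `log_predictors` enter on the log scale. Reports, per term: the
#' unstandardised coefficient b, standardised beta (`b * sd(x)/sd(y)`), its
#' 95% CI, p, and the partial correlation `t / sqrt(t^2 + df)`.
#'
#' @param data A data frame (typically one group's rows).
#' @param outcome Outcome column name (string).
#' @param predictors Character vector of hemodynamic predictor columns.
#' @param covariates Character vector of covariate columns.
#' @param log_predictors Subset of `predictors` to log-transform.
#' @param gate_p Univariate screen level (default 0.1).
#' @param enforce_gate Set `FALSE` to fit regardless of the screen.
#' @return Object of class `cognition_fit` (use [tidy()] / [glance()]).
#' @export
cognition_regression <- function(data, outcome, predictors,
                                 covariates = c("age", "sex",
                                                "hydroxycarbamide",
                                                "transfusion", "sci_burden",
                                                "etiv", "education_decile"),
                                 log_predictors = character(),
                                 gate_p = 0.1, enforce_gate = TRUE) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)),
            all(covariates %in% names(data)))
  df <- data[, c(outcome, predictors, covariates)]
  for (pr in intersect(log_predictors, predictors)) {
    if (any(df[[pr]] <= 0, na.rm = TRUE)) {
      stop("cognition_regression: non-positive values in log predictor ",
           pr, call. = FALSE)
    }
    df[[pr]] <- log(df[[pr]])
    names(df)[names(df) == pr] <- paste0("log_", pr)
    predictors[predictors == pr] <- paste0("log_", pr)
  }
  df <- df[stats::complete.cases(df), ]
  n_par <- 1 + length(predictors) + length(covariates)
  if (nrow(df) <= n_par + 2) {
    stop("cognition_regression: too few complete cases for the model size",
         call. = FALSE)
  }
  gate <- purrr::map_dfr(predictors, function(pr) {
    ct <- stats::cor.test(df[[outcome]], df[[pr]])
    tibble::tibble(predictor = pr, r = unname(ct$estimate), p = ct$p.value,
                   pass = ct$p.value < gate_p)
  })
  if (enforce_gate && !any(gate$pass)) {
    stop(sprintf(
      "cognition_regression: no predictor passes the univariate p < %g screen (use enforce_gate = FALSE to override)",
      gate_p), call. = FALSE)
  }
  fml <- stats::reformulate(c(predictors, covariates), response = outcome)
  fit <- stats::lm(fml, data = df)
  structure(list(fit = fit, data = df, outcome = outcome,
                 predictors = predictors, covariates = covariates,
                 gate = gate),
            class = "cognition_fit")
}

#' @export
print.cognition_fit <- function(x, ...) {
  cat(sprintf("<cognition_fit: %s ~ %s + %d covariates, n = %d>\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              length(x$covariates), nrow(x$data)))
  invisible(x)
}

#' Tidy a cognition regression
#'
#' @param x A `cognition_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `b`, `beta`, `conf_low`,
#'   `conf_high`, `p`, `partial_r`.
#' @method tidy cognition_fit
#' @export
tidy.cognition_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit)
  df_res <- x$fit$df.residual
  sdy <- stats::sd(x$data[[x$outcome]])
  terms <- rownames(sm)
  purrr::map_dfr(terms, function(tm) {
    b <- sm[tm, "Estimate"]; tval <- sm[tm, "t value"]
    xcol <- if (tm %in% names(x$data)) x$data[[tm]] else NULL
    beta <- if (tm == "(Intercept)") NA_real_ else {
      mm <- stats::model.matrix(x$fit)
      if (tm %in% colnames(mm)) b * stats::sd(mm[, tm]) / sdy else NA_real_
    }
    tibble::tibble(term = tm, b = b, beta = beta,
                   conf_low = ci[tm, 1], conf_high = ci[tm, 2],
                   p = sm[tm, "Pr(>|t|)"],
                   partial_r = if (tm == "(Intercept)") NA_real_
                     else tval / sqrt(tval^2 + df_res))
  })
}

#' Model-level summary of a cognition regression
#'
#' Includes descriptive assumption checks: Shapiro-Wilk p of the residuals,
#' a Breusch-Pagan-style heteroscedasticity screen (squared residuals on
#' fitted values) and the residual-vs-fitted linearity correlation.
#'
#' @param x A `cognition_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance cognition_fit
#' @export
glance.cognition_fit <- function(x, ...) {
  sm <- summary(x$fit)
  res <- stats::residuals(x$fit); fitted <- stats::fitted(x$fit)
  bp <- summary(stats::lm(res^2 ~ fitted))$coefficients
  tibble::tibble(
    n = nrow(x$data), r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared, sigma = sm$sigma,
    f_statistic = unname(sm$fstatistic[1]),
    p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE),
    resid_normality_p = stats::shapiro.test(res)$p.value,
    heteroscedasticity_p = bp["fitted", "Pr(>|t|)"],
    linearity_r = stats::cor(res, fitted)
  )
}

#' Group-comparison panel over the hemodynamic features
#'
#' Runs [compare_groups()] for each feature, tags each result with its
#' parameter-map family and applies the stratified BH-FDR adjustment across
#' features within each family.
#'
#' @param cohort Cohort table with a `group` column.
#' @param features Feature column names (default: the nine ROI features).
#' @return Tibble of `StatResult` rows with `family` and `p_adj`.
#' @export
group_comparison_table <- function(cohort,
                                   features = intersect(
                                     unique(default_feature_table()$feature),
                                     names(cohort))) {
  res <- purrr::map_dfr(features, function(f) compare_groups(cohort, f))
  res$family <- feature_family(res$feature)
  bh_fdr(res, by = "family")
}

#' Adjusted CaO2 correlations by region
#'
#' Within each participant group, age- and sex-adjusts each feature
#' (log-transforming non-normal ones) and correlates it with arterial
#' oxygen content, then applies the stratified FDR adjustment within
#' (group x parameter-map family).
#'
#' @param cohort Cohort table.
#' @param features Feature columns (default: the nine ROI features).
#' @param method Correlation type (default Pearson, matching parametric
#'   exploration of log-transformed variables).
#' @return Tibble with one row per group x feature, FDR-adjusted.
#' @export
cao2_correlation_table <- function(cohort,
                                   features = intersect(
                                     unique(default_feature_table()$feature),
                                     names(cohort)),
                                   method = "pearson") {
  res <- purrr::map_dfr(c("SCA", "control"), function(gr) {
    sub <- cohort[cohort$group == gr, ]
    purrr::map_dfr(features, function(f) {
      sub2 <- adjust_age_sex(sub, f)
      r <- correlate(sub2[[paste0(f, "_adj")]], sub2$cao2, method = method,
                     label = sprintf("%s ~ CaO2 [%s]", f, gr))
      r$group <- gr; r$feature <- f
      r
    })
  })
  res$family <- feature_family(res$feature)
  bh_fdr(res, by = c("group", "family"))
}

#' Boxplot panel of group differences
#'
#' @param cohort Cohort table.
#' @param features Feature columns to plot.
#' @return A ggplot object (feature facets, group on x).
#' @export
plot_group_comparison <- function(cohort,
                                  features = intersect(
                                    unique(default_feature_table()$feature),
                                    names(cohort))) {
  long <- tidyr::pivot_longer(cohort[, c("group", features)],
                              dplyr::all_of(features),
                              names_to = "feature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
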