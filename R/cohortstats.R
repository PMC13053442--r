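# Subject-level aggregation and group models for repeated-fields designs.

#' Simulate a hierarchical two-group cohort
#'
#' Draws a cohort table emulating a two-group, four-muscle autopsy design
#' with repeated fields of view per subject x muscle: per-subject random
#' intercepts, field-level noise, and subject covariates. Default
#' demographics match an older male cohort: age ~ N(70, 10) in both
#' groups, BMI ~ N(24.8, 2.7) in controls versus N(31.9, 4.7) in the
#' disease group, HbA1c ~ N(5.3, 0.25) in controls versus N(6.9, 1.1) in
#' the disease group.
#'
#' @param n_per_group named c(CTRL, T2DM) subject counts (default 24, 24).
#' @param muscles muscle labels (default SC, EXT, DIA, VL).
#' @param n_fields fields of view per subject x muscle (default 5).
#' @param muscle_means named per-muscle outcome means.
#' @param group_effect additive effect of the T2DM group; scalar or named
#'   per-muscle vector.
#' @param sd_subject SD of the per-subject random intercept.
#' @param sd_field SD of field-level noise.
#' @param age_beta,bmi_beta fixed covariate slopes on the outcome.
#' @param outcome outcome column name.
#' @param seed RNG seed; the table is deterministic given all arguments.
#' @return data.frame with columns subject, group, age, BMI, HbA1c, muscle,
#'   field, outcome, value.
#' @export
simulate_cohort <- function(n_per_group = c(CTRL = 24, T2DM = 24),
                            muscles = c("SC", "EXT", "DIA", "VL"),
                            n_fields = 5,
                            muscle_means = c(SC = 13.6, EXT = 12.6,
                                             DIA = 20.1, VL = 10.1),
                            group_effect = 0,
                            sd_subject = 2, sd_field = 1,
                            age_beta = 0, bmi_beta = 0,
                            outcome = "outcome",
                            seed = 1L) {
  stopifnot(all(n_per_group >= 1), n_fields >= 1,
            all(muscles %in% names(muscle_means)),
            sd_subject >= 0, sd_field >= 0)
  if (length(group_effect) == 1)
    group_effect <- stats::setNames(rep(group_effect, length(muscles)),
                                    muscles)
  with_rng_seed(seed, {
    groups <- rep(names(n_per_group), n_per_group)
    ns <- length(groups)
    subj <- sprintf("S%02d", seq_len(ns))
    age <- stats::rnorm(ns, 70, 10)
    bmi <- ifelse(groups == "T2DM", stats::rnorm(ns, 31.9, 4.7),
                  stats::rnorm(ns, 24.8, 2.7))
    hba1c <- ifelse(groups == "T2DM", stats::rnorm(ns, 6.9, 1.1),
                    stats::rnorm(ns, 5.3, 0.25))
    b_subj <- stats::rnorm(ns, 0, sd_subject)
    rows <- expand.grid(field = seq_len(n_fields), muscle = muscles,
                        si = seq_len(ns), stringsAsFactors = FALSE)
    mu <- muscle_means[rows$muscle] +
      ifelse(groups[rows$si] == "T2DM", group_effect[rows$muscle], 0) +
      age_beta * age[rows$si] + bmi_beta * bmi[rows$si] + b_subj[rows$si]
    val <- mu + stats::rnorm(nrow(rows), 0, sd_field)
    out <- data.frame(subject = subj[rows$si], group = groups[rows$si],
                      age = age[rows$si], BMI = bmi[rows$si],
                      HbA1c = hba1c[rows$si], muscle = rows$muscle,
                      field = rows$field, outcome = outcome,
                      value = val, stringsAsFactors = FALSE)
    out$group <- factor(out$group, levels = names(n_per_group))
    out
  })
}

model_result <- function(beta, ci, p, coefs, converged, singular,
                         model = NULL, note = NULL) {
  structure(list(beta = beta, ci_lower = ci[1], ci_upper = ci[2], p = p,
                 coefficients = coefs, converged = converged,
                 singular = singular, model = model, note = note),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(
    "<model_result> beta = %.4g  95%% CI [%.4g, %.4g]  p = %.4g%s\n",
    x$beta, x$ci_lower, x$ci_upper, x$p,
    if (isTRUE(x$singular)) "  (singular fit)" else ""))
  invisible(x)
}

extract_effect <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!(term %in% rownames(sm))) stop("term not found: ", term)
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  if ("df" %in% colnames(sm)) {              # Satterthwaite (lmerTest)
    df <- sm[term, "df"]
    p <- sm[term, "Pr(>|t|)"]
    tc <- stats::qt(0.975, df)
  } else {                                   # normal approximation fallback
    p <- 2 * stats::pnorm(-abs(est / se))
    tc <- stats::qnorm(0.975)
  }
  list(beta = est, ci = c(est - tc * se, est + tc * se), p = p, coefs = sm)
}

#' Mixed-effects group model for one muscle
#'
#' Linear mixed model of field-level outcomes with a per-subject random
#' intercept (repeated fields of view within individuals), fixed effects
#' for group, age and BMI, REML fitting, and Satterthwaite-type degrees of
#' freedom for the group test (normal approximation as fallback when the
#' Satterthwaite fit fails). Optional sensitivity terms: quadratic age,
#' group-by-age interaction, and a mean fibre diameter covariate.
#' Singular fits (a variance component estimated at zero) are flagged but
#' still returned.
#' @param table cohort data.frame (see [simulate_cohort()]).
#' @param outcome outcome name (rows with `outcome == outcome` are used);
#'   ignored when the table carries a single outcome.
#' @param muscle muscle to subset to, or NULL for all rows.
#' @param extras character subset of
#'   `c("age2", "group_by_age", "fibre_diameter")`; `"fibre_diameter"`
#'   requires a `fibre_diameter` column.
#' @return a `model_result` with the adjusted group effect (beta, 95% CI,
#'   two-sided p).
#' @export
fit_group_model <- function(table, outcome = NULL, muscle = NULL,
                            extras = character(0)) {
  d <- table
  if (!is.null(outcome) && "outcome" %in% names(d))
    d <- d[d$outcome == outcome, , drop = FALSE]
  if (!is.null(muscle)) d <- d[d$muscle == muscle, , drop = FALSE]
  stopifnot(nrow(d) > 0, length(unique(d$subject[d$group == levels(
    factor(d$group))[1]])) >= 2)
  d$group <- factor(d$group)
  rhs <- c("group", "age", "BMI")
  if ("age2" %in% extras) {
    d$age2 <- (d$age - mean(d$age))^2    # centred to limit collinearity
    rhs <- c(rhs, "age2")
  }
  if ("group_by_age" %in% extras) rhs <- c(rhs, "group:age")
  if ("fibre_diameter" %in% extras) {
    stopifnot("fibre_diameter" %in% names(d))
    rhs <- c(rhs, "fibre_diameter")
  }
  fml <- stats::as.formula(paste("value ~", paste(rhs, collapse = " + "),
                                 "+ (1 | subject)"))
  term <- paste0("group", levels(d$group)[2])
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(fml, data = d, REML = TRUE)),
    error = function(e) NULL)
  note <- NULL
  if (is.null(fit)) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    note <- "Satterthwaite fit failed; normal-approximation p-values"
  }
  eff <- extract_effect(fit, term)
  singular <- suppressWarnings(lme4::isSingular(fit, tol = 1e-5))
  if (singular) warning("singular mixed-model fit (variance component at 0)")
  model_result(eff$beta, eff$ci, eff$p, eff$coefs,
               converged = TRUE, singular = singular, model = fit,
               note = note)
}

#' Two-way ANOVA (group x fibre type) with Tukey post hoc tests
#'
#' Fixed-effects two-way analysis of variance on subject-level means with
#' interaction, plus Tukey honestly-significant-difference pairwise
#' comparisons for each factor and the interaction cells.
#' @param data data.frame with the response and both factors.
#' @param response,group,fibre_type column names.
#' @return list with `anova` (the ANOVA table) and `tukey` (TukeyHSD
#'   result). Empty design cells raise an error naming the cell.
#' @export
twoway_anova_tukey <- function(data, response = "value", group = "group",
                               fibre_type = "type") {
  d <- data.frame(y = data[[response]],
                  g = factor(data[[group]]),
                  t = factor(data[[fibre_type]]))
  stopifnot(nlevels(d$g) >= 2, nlevels(d$t) >= 2)
  cells <- table(d$g, d$t)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: group '%s' x fibre type '%s'",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  fit <- stats::aov(y ~ g * t, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  list(anova = tab, tukey = stats::TukeyHSD(fit), fit = fit)
}

#' Within-subject hierarchy across muscles
#'
#' Because every muscle is sampled from the same subjects, the intrinsic
#' ordering of an outcome across muscles can be assessed independently of
#' inter-individual variability: subject-level means per muscle, all
#' pairwise paired t-tests, the rank order of muscle means, and a
#' repeated-measures mixed model
#' `value ~ group * muscle + age + BMI + (1 | subject)`.
#' Subjects lacking any muscle are excluded listwise (and reported).
#' @param table cohort data.frame.
#' @param outcome optional outcome filter.
#' @return list with `order` (muscles, decreasing mean), `means`,
#'   `pairwise` (paired t-tests), `model` (mixed fit), `n_complete`,
#'   `excluded`.
#' @export
within_subject_hierarchy <- function(table, outcome = NULL) {
  d <- table
  if (!is.null(outcome) && "outcome" %in% names(d))
    d <- d[d$outcome == outcome, , drop = FALSE]
  muscles <- unique(d$muscle)
  agg <- stats::aggregate(value ~ subject + muscle + group + age + BMI,
                          data = d, FUN = mean)
  wide <- stats::reshape(agg[, c("subject", "muscle", "value")],
                         idvar = "subject", timevar = "muscle",
                         direction = "wide")
  complete <- stats::complete.cases(wide)
  excluded <- wide$subject[!complete]
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3)
    stop("fewer than 3 subjects with all muscles present")
  vals <- as.matrix(wide[, paste0("value.", muscles), drop = FALSE])
  colnames(vals) <- muscles
  mm <- colMeans(vals)
  ord <- names(sort(mm, decreasing = TRUE))
  pairs <- utils::combn(muscles, 2)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_,
                   p = NA_real_, mean_diff = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- vals[, pairs[1, i]]; b <- vals[, pairs[2, i]]
    if (max(abs(a - b)) < 1e-12) {
      pw$t[i] <- 0; pw$p[i] <- 1; pw$mean_diff[i] <- 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      pw$t[i] <- unname(tt$statistic)
      pw$p[i] <- tt$p.value
      pw$mean_diff[i] <- unname(tt$estimate)
    }
  }
  agg_sub <- agg[agg$subject %in% wide$subject, , drop = FALSE]
  agg_sub$value_field <- agg_sub$value
  fit <- tryCatch(suppressMessages(
    lmerTest::lmer(value ~ group * muscle + age + BMI + (1 | subject),
                   data = agg_sub, REML = TRUE)),
    error = function(e) NULL)
  list(order = ord, means = mm, pairwise = pw, model = fit,
       n_complete = nrow(wide), excluded = excluded)
}

#' Association between HbA1c and a structural outcome (disease subgroup)
#'
#' Linear model of subject-level outcome means on HbA1c, adjusted for age
#' and BMI, within the T2DM subgroup.
#' @param table cohort data.frame (rows outside group `"T2DM"` dropped).
#' @param outcome optional outcome filter.
#' @return a `model_result` for the HbA1c slope, plus `r_squared`.
#' @export
hba1c_association <- function(table, outcome = NULL) {
  d <- table
  if (!is.null(outcome) && "outcome" %in% names(d))
    d <- d[d$outcome == outcome, , drop = FALSE]
  d <- d[d$group == "T2DM", , drop = FALSE]
  stopifnot(nrow(d) > 0, !any(is.na(d$HbA1c)))
  agg <- stats::aggregate(value ~ subject + HbA1c + age + BMI, data = d,
                          FUN = mean)
  if (stats::sd(agg$HbA1c) < 1e-12) stop("HbA1c is constant")
  fit <- stats::lm(value ~ HbA1c + age + BMI, data = agg)
  sm <- summary(fit)
  est <- sm$coefficients["HbA1c", "Estimate"]
  se <- sm$coefficients["HbA1c", "Std. Error"]
  df <- fit$df.residual
  tc <- stats::qt(0.975, df)
  res <- model_result(est, c(est - tc * se, est + tc * se),
                      sm$coefficients["HbA1c", "Pr(>|t|)"],
                      sm$coefficients, converged = TRUE, singular = FALSE,
                      model = fit)
  res$r_squared <- sm$r.squared
  res
}
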