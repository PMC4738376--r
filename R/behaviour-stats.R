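#' @include volumes-io.R
NULL

#' Kendall rank correlation (tau-b) with a two-sided p
#'
#' Tie-corrected tau-b, the natural choice for ordinal rehabilitation scales
#' where ties are guaranteed. The p-value comes from `stats::cor.test`
#' (exact enumeration when feasible, i.e. small n without ties; normal
#' approximation otherwise). Tau is undefined when either variable is
#' constant; that case is flagged rather than returned as 0.
#'
#' @param x,y paired numeric vectors, n >= 3
#' @return list with `tau`, `p` and `flag` (NA or "all_tied")
#' @export
kendallTau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(tau = NA_real_, p = NA_real_, flag = "all_tied"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, flag = NA_character_)
}

#' Wilcoxon signed-rank Z and effect size r
#'
#' Paired baseline/outcome test: zero differences are dropped, absolute
#' differences receive average ranks under ties, and Z is the tie-corrected
#' normal approximation of the signed-rank statistic (no continuity
#' correction). The effect size is r = |Z| / sqrt(N) with N the number of
#' pairs entering the test.
#'
#' @param baseline,outcome paired numeric vectors, n >= 5
#' @return list with `statistic` (W+, the positive-rank sum), `z`,
#'   `effect_r`, `n_used` and `flag`
#' @export
wilcoxonEffect <- function(baseline, outcome) {
  stopifnot(length(baseline) == length(outcome), length(baseline) >= 5)
  d <- outcome - baseline
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, z = NA_real_, effect_r = NA_real_,
                n_used = 0L, flag = "all_differences_zero"))
  n <- length(d)
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (wPlus - mu) / sqrt(sigma2)
  list(statistic = wPlus, z = z, effect_r = abs(z) / sqrt(n),
       n_used = n, flag = NA_character_)
}

#' Multiple linear regression with standardized betas and partial correlations
#'
#' Ordinary least squares of a change score on lesion load and covariates,
#' reported the way rehabilitation regression tables are laid out: per
#' predictor the raw coefficient, its SE, the standardized coefficient
#' `beta * sd(x) / sd(y)`, the two-sided p, the raw Pearson correlation with
#' the response, and the partial correlation derived from the coefficient t,
#' `t / sqrt(t^2 + df)`. Ordinal covariates (Fazekas, FAC baseline) enter as
#' numeric scores. Rows with missing values are dropped listwise with a note.
#'
#' @param change numeric response (change score)
#' @param predictors data.frame of numeric predictors (e.g. wcst_ll, age,
#'   fazekas, baseline, time)
#' @return data.frame with one row per predictor (term, beta, se, std_beta,
#'   t, p, pearson_r, partial_r) plus attributes `n`, `df`, `r_squared`,
#'   `n_dropped`
#' @export
fitLinear <- function(change, predictors) {
  predictors <- as.data.frame(predictors)
  dat <- cbind(.response = change, predictors)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  X <- as.matrix(dat[, -1, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(.response ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  df <- fit$df.residual
  tv <- co[, "t value"]
  out <- data.frame(
    term = rownames(co),
    beta = co[, "Estimate"],
    se = co[, "Std. Error"],
    std_beta = co[, "Estimate"] * apply(X, 2, stats::sd) /
      stats::sd(dat$.response),
    t = tv,
    p = co[, "Pr(>|t|)"],
    pearson_r = apply(X, 2, function(x) stats::cor(x, dat$.response)),
    partial_r = tv / sqrt(tv^2 + df),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(dat)
  attr(out, "df") <- df
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "n_dropped") <- sum(!cc)
  out
}

#' Proportional-odds ordinal regression with odds ratios and Wald tests
#'
#' Cumulative-logit (proportional-odds) model fitted by maximum likelihood
#' via `MASS::polr`. Per predictor: OR = exp(coefficient) (odds of a higher
#' outcome category per unit increase), Wald chi-square = (coef/se)^2 on 1
#' df with its p, the 95% CI exp(coef +/- 1.96 se), and the raw Pearson
#' correlation of the predictor with the (numeric) response. Responses with
#' fewer than 3 observed categories, non-convergence and separation are
#' flagged rather than fitted.
#'
#' @param change ordinal response (integer scores; coerced to ordered factor)
#' @param predictors data.frame of numeric predictors
#' @return data.frame (term, coef, se, odds_ratio, ci_lo, ci_hi, wald_chi2,
#'   p, pearson_r) with attributes `n`, `flag`; or a flagged empty frame when
#'   the fit is impossible
#' @export
fitOrdinal <- function(change, predictors) {
  predictors <- as.data.frame(predictors)
  dat <- cbind(.response = change, predictors)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  flagged <- function(flag) {
    out <- data.frame(term = character(), coef = numeric(), se = numeric(),
                      odds_ratio = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), wald_chi2 = numeric(), p = numeric(),
                      pearson_r = numeric(), stringsAsFactors = FALSE)
    attr(out, "n") <- nrow(dat)
    attr(out, "flag") <- flag
    out
  }
  if (length(unique(dat$.response)) < 3L)
    return(flagged("fewer_than_3_categories"))
  dat$.ord <- factor(dat$.response, ordered = TRUE)
  fml <- stats::as.formula(paste(".ord ~",
                                 paste(names(predictors), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = dat, Hess = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) return(flagged(conditionMessage(fit)))
  if (!is.null(fit$convergence) && fit$convergence != 0)
    return(flagged("non_convergence"))
  co <- summary(fit)$coefficients
  co <- co[names(predictors), , drop = FALSE]
  est <- co[, "Value"]
  se <- co[, "Std. Error"]
  if (any(!is.finite(se)) || any(se > 1e3))
    return(flagged("separation_or_unstable_se"))
  wald <- (est / se)^2
  out <- data.frame(
    term = rownames(co), coef = est, se = se,
    odds_ratio = exp(est),
    ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
    wald_chi2 = wald, p = stats::pchisq(wald, 1, lower.tail = FALSE),
    pearson_r = vapply(names(predictors), function(v)
      stats::cor(dat[[v]], as.numeric(dat$.response)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(dat)
  attr(out, "flag") <- NA_character_
  out
}

#' Descriptive summary of a cohort's behavioural table
#'
#' Median, IQR (linear-interpolation quantiles, R type 7), range, mean and SD
#' per variable, plus Wilcoxon signed-rank effect sizes for the three change
#' scores.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @return list with `variables` (data.frame of descriptives) and `effects`
#'   (data.frame of per-measure Wilcoxon Z and effect r)
#' @export
summarizeCohort <- function(cohort) {
  recs <- records(cohort)
  vars <- c("age", "fazekas", "time_days", "lesion_volume_cm3",
            "walk_baseline", "walk_outcome", "walk_change",
            "fac_baseline", "fac_outcome", "fac_change",
            "mrmi_baseline", "mrmi_outcome", "mrmi_change")
  vars <- intersect(vars, names(recs))
  desc <- do.call(rbind, lapply(vars, function(v) {
    x <- recs[[v]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    data.frame(variable = v, median = q[2], iqr_lo = q[1], iqr_hi = q[3],
               min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
               mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  effects <- do.call(rbind, lapply(c("walk", "fac", "mrmi"), function(m) {
    we <- wilcoxonEffect(recs[[paste0(m, "_baseline")]],
                         recs[[paste0(m, "_outcome")]])
    data.frame(measure = m, z = we$z, effect_r = we$effect_r,
               n_used = we$n_used, stringsAsFactors = FALSE)
  }))
  list(variables = desc, effects = effects)
}

#' The regression battery for one measure given tract loads
#'
#' Joins the cohort's records with the wCST-LL table (subjects flagged
#' `outside_tract_support` are excluded, not zeroed), then fits the multiple
#' regression (walk, mrmi) or the proportional-odds model (fac) of the change
#' score on load, age, Fazekas, baseline and time.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param loads data.frame from [cohortLoads()]
#' @param measure "walk", "fac" or "mrmi"
#' @return the [fitLinear()] or [fitOrdinal()] table
#' @export
loadRegression <- function(cohort, loads, measure = c("walk", "fac", "mrmi")) {
  measure <- match.arg(measure)
  recs <- records(cohort)
  keep <- loads$status == "ok"
  recs <- recs[match(loads$subject_id[keep], recs$subject_id), , drop = FALSE]
  pred <- data.frame(wcst_ll = loads$wcst_ll_cm3[keep],
                     age = recs$age, fazekas = recs$fazekas,
                     baseline = recs[[paste0(measure, "_baseline")]],
                     time_days = recs$time_days)
  y <- recs[[paste0(measure, "_change")]]
  if (measure == "fac") fitOrdinal(y, pred) else fitLinear(y, pred)
}
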