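# Statistics layer: heterogeneity accounting, pathologist concordance,
# correlation/clustering of subtype percentages, Kaplan-Meier/log-rank and
# univariate/multivariate Cox with backward elimination, VIF, AIC and
# Harrell's C.

#' Percentage of a count, as printed in demographic tables
#'
#' `round(100 * k / n, digits)` — the convention used to report category
#' percentages from integer counts.
#'
#' @param k Count (vectorized).
#' @param n Denominator.
#' @param digits Decimal places, default 1 (demographics) — use 0 for
#'   heterogeneity summaries.
#' @return Numeric percentage(s).
#' @export
#' @examples
#' count_percent(46, 117)   # 39.3
count_percent <- function(k, n, digits = 1) {
  round(100 * k / n, digits)
}

#' Intra-tumor heterogeneity accounting for categorical core scores
#'
#' For patients with more than one core, a patient is heterogeneous for a
#' score when not all of their cores carry the same category. Counts are
#' stratified by core number (2 vs 3 cores); three-core patients with all
#' three categories distinct are also counted. Percentages are the integer
#' rounding of `100 k / n` within each stratum, plus the overall
#' heterogeneous fraction among all multi-core patients.
#'
#' @param cores Tibble with `patient_id`, `core_id` and one or more
#'   category columns.
#' @param category Name of the category column (default `"path_immune"`).
#' @return A list of class `heterogeneity_report`: `by_stratum` tibble
#'   (`n_cores`, `n_patients`, `n_same`, `n_heterogeneous`, `n_all_diff`,
#'   `pct_same`, `pct_heterogeneous`, `pct_all_diff`) and `overall`
#'   (`n_patients`, `n_heterogeneous`, `pct_heterogeneous`).
#' @export
#' @examples
#' x <- simulate_category_cohort(99, 44, 62, 13, 5)
#' x$path_immune <- x$category
#' heterogeneity_summary(x, "path_immune")$overall
heterogeneity_summary <- function(cores, category = "path_immune") {
  check_columns(cores, c("patient_id", category), "cores")
  per_pat <- cores |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      n_distinct_cat = dplyr::n_distinct(.data[[category]]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cores >= 2)

  by_stratum <- per_pat |>
    dplyr::group_by(.data$n_cores) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      n_same = sum(.data$n_distinct_cat == 1),
      n_heterogeneous = sum(.data$n_distinct_cat > 1),
      n_all_diff = sum(.data$n_distinct_cat == .data$n_cores & .data$n_cores > 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_same = count_percent(.data$n_same, .data$n_patients, 0),
      pct_heterogeneous = count_percent(.data$n_heterogeneous, .data$n_patients, 0),
      pct_all_diff = count_percent(.data$n_all_diff, .data$n_patients, 0)
    )
  overall <- list(
    n_patients = nrow(per_pat),
    n_heterogeneous = sum(per_pat$n_distinct_cat > 1),
    pct_heterogeneous = count_percent(sum(per_pat$n_distinct_cat > 1),
                                      nrow(per_pat), 0)
  )
  structure(list(by_stratum = by_stratum, overall = overall, score = category),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Heterogeneity of %s: %d/%d multi-core patients heterogeneous (%d%%)\n",
              x$score, x$overall$n_heterogeneous, x$overall$n_patients,
              x$overall$pct_heterogeneous))
  print(x$by_stratum)
  invisible(x)
}

#' @rdname heterogeneity_summary
#' @param x A `heterogeneity_report`.
#' @param ... Unused.
#' @method tidy heterogeneity_report
#' @export
tidy.heterogeneity_report <- function(x, ...) {
  dplyr::bind_rows(
    x$by_stratum,
    tibble::tibble(n_cores = NA_integer_,
                   n_patients = x$overall$n_patients,
                   n_heterogeneous = x$overall$n_heterogeneous,
                   pct_heterogeneous = x$overall$pct_heterogeneous)
  )
}

#' Welch ANOVA with pairwise Welch t-tests
#'
#' Compares a quantitative score across pathologist categories with the
#' unequal-variance (Welch) one-way ANOVA and unadjusted pairwise
#' unequal-variance t-tests.
#'
#' @param values Numeric vector.
#' @param group Factor/character vector of categories.
#' @return List: `overall_p`, `anova` (the `oneway.test` result),
#'   `pairwise` (tibble `group1`, `group2`, `p`).
#' @export
welch_anova_pairwise <- function(values, group) {
  group <- as.character(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  tab <- table(group)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) abort(sprintf("group(s) with < 2 observations: %s",
                                  paste(names(tab)[tab < 2], collapse = ", ")))
  v <- tapply(values, group, var)
  if (any(v == 0)) abort(sprintf("zero-variance group(s): %s",
                                 paste(names(v)[v == 0], collapse = ", ")))
  ow <- oneway.test(values ~ group, var.equal = FALSE)
  pw <- pairwise.t.test(values, group, p.adjust.method = "none", pool.sd = FALSE)
  pm <- pw$p.value
  pairs <- expand.grid(group1 = rownames(pm), group2 = colnames(pm),
                       stringsAsFactors = FALSE)
  pairs$p <- as.vector(pm)
  pairs <- pairs[!is.na(pairs$p), ]
  list(overall_p = ow$p.value, anova = ow, pairwise = tibble::as_tibble(pairs))
}

#' Spearman correlation matrix of subtype percentages
#'
#' @param data Tibble of per-patient quantities (numeric columns only are
#'   used; an id column is ignored).
#' @return Symmetric correlation matrix; constant columns give `NA`
#'   entries with a warning.
#' @export
spearman_matrix <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (nrow(num) < 3) abort("need at least 3 rows")
  const <- vapply(num, function(z) var(z, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(sprintf("constant column(s), correlations undefined: %s",
                 paste(names(num)[const], collapse = ", ")))
  }
  suppressWarnings(cor(as.matrix(num), method = "spearman"))
}

#' Ward clustering of patients by subtype percentages
#'
#' Standardizes the quantity columns, computes Euclidean distances and cuts
#' a Ward ("ward.D") agglomerative tree at `k` clusters. Cluster labels are
#' renumbered by descending cluster mean of the summed T-cell percentage so
#' that cluster 1 is the most immune-infiltrated ("hot").
#'
#' @param data Tibble of per-patient percentages (numeric columns used).
#' @param k Number of clusters (2 or 3 in the standard analysis).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r between patients).
#' @return Integer vector of cluster labels, one per row.
#' @export
cluster_patients <- function(data, k = 2, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  num <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  if (k > nrow(num)) abort("k cannot exceed the number of patients")
  if (k == 1) return(rep(1L, nrow(num)))
  z <- scale(num)
  z[, apply(num, 2, function(col) var(col) == 0)] <- 0
  dd <- if (distance == "euclidean") dist(z) else stats::as.dist(1 - cor(t(z)))
  labels <- cutree(hclust(dd, method = "ward.D"), k = k)
  # order clusters: 1 = highest mean total percentage
  tot <- rowSums(num)
  ord <- order(tapply(tot, labels, mean), decreasing = TRUE)
  match(labels, ord)
}

#' Dichotomize at the sample median
#'
#' Labels values `"low"` when at or below the sample median and `"high"`
#' above it. If median ties empty one side, falls back to a strict split
#' (`"low"` strictly below the median) and records the fallback.
#'
#' @param values Numeric vector with at least 2 values.
#' @return Character vector of `"high"`/`"low"` with attribute `cutoff`
#'   (and `fallback = TRUE` when the strict rule was used).
#' @export
#' @examples
#' dichotomize_median(c(1, 2, 3, 4))
dichotomize_median <- function(values) {
  if (length(values) < 2) abort("need at least 2 values")
  if (length(unique(values)) == 1) abort("all values identical; no median split possible")
  m <- median(values)
  lab <- ifelse(values <= m, "low", "high")
  fallback <- FALSE
  if (all(lab == "low")) {
    lab <- ifelse(values < m, "low", "high")
    fallback <- TRUE
  }
  attr(lab, "cutoff") <- m
  if (fallback) attr(lab, "fallback") <- TRUE
  lab
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with the two-sided log-rank
#' test.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Group labels.
#' @return A list of class `km_result`: `fit` (a `survfit`), `logrank_p`,
#'   `curves` tibble (`group`, `time`, `survival`, `n_risk`).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) abort("times must be positive")
  group <- as.character(group)
  tab <- table(group)
  if (any(tab == 0) || length(tab) < 2) abort("each group needs at least one subject")
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = fit$time,
    survival = fit$surv,
    n_risk = fit$n.risk
  )
  structure(list(fit = fit, logrank_p = p, logrank_chisq = unname(sd_$chisq),
                 curves = curves),
            class = "km_result")
}

#' @rdname km_logrank
#' @param x A `km_result`.
#' @param ... Unused.
#' @method tidy km_result
#' @export
tidy.km_result <- function(x, ...) x$curves

#' @rdname km_logrank
#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p)
}

lr_pvalue <- function(fit_full, fit_reduced, df) {
  lr <- 2 * (fit_full$loglik[2] - fit_reduced)
  pchisq(lr, df, lower.tail = FALSE)
}

#' Univariate Cox proportional hazards fit
#'
#' Fits one covariate against a survival endpoint using the partial
#' likelihood with Efron tie handling, and reports the hazard ratio, Wald
#' 95% CI and likelihood-ratio p-value.
#'
#' @param data Data frame.
#' @param covariate Column name of the covariate (continuous percent or
#'   binary).
#' @param time,event Column names of the endpoint.
#' @return A one-row tibble of class rows: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_events`, `scope = "univariate"`.
#' @export
cox_univariate <- function(data, covariate, time, event) {
  check_columns(data, c(covariate, time, event), "data")
  d <- data[complete.cases(data[, c(covariate, time, event)]), ]
  if (sum(d[[event]]) == 0) abort("no events; Cox model cannot be fit")
  f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, covariate))
  fit <- survival::coxph(f, data = d, ties = "efron")
  if (any(is.na(coef(fit)))) abort("Cox fit did not converge / aliased covariate")
  b <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  p <- pchisq(2 * diff(fit$loglik), 1, lower.tail = FALSE)
  tibble::tibble(
    term = covariate,
    hr = exp(b),
    ci_low = exp(b - qnorm(0.975) * se),
    ci_high = exp(b + qnorm(0.975) * se),
    p = p,
    n = fit$n,
    n_events = fit$nevent,
    scope = "univariate"
  )
}

# Generalized VIF per model term on a dummy-coded design matrix.
# Aliased (linearly dependent) columns get VIF = Inf.
gvif_terms <- function(X, assign, term_labels) {
  X <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(X)
  aliased_cols <- if (qrX$rank < ncol(X)) {
    setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
  } else integer(0)
  R <- cor(X)
  detR <- det(R)
  vif <- vapply(seq_along(term_labels), function(j) {
    cols <- which(assign == j)
    if (length(cols) == 0) return(NA_real_)
    if (any(cols %in% aliased_cols) || detR <= 0) return(Inf)
    others <- setdiff(seq_len(ncol(X)), cols)
    if (length(others) == 0) return(1)
    g <- det(as.matrix(R[cols, cols])) * det(as.matrix(R[others, others])) / detR
    # scale to a per-coefficient VIF for multi-df terms
    g^(1 / length(cols))
  }, numeric(1))
  setNames(vif, term_labels)
}

cox_fit <- function(data, vars, time, event) {
  f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event,
                          paste(vars, collapse = " + ")))
  survival::coxph(f, data = data, ties = "efron")
}

# AIC counting only estimated (non-aliased) coefficients.
cox_aic <- function(fit) {
  k <- sum(!is.na(coef(fit)))
  2 * k - 2 * fit$loglik[2]
}

#' Multivariate Cox model with backward elimination and VIF screen
#'
#' Model selection for a biomarker adjusted for clinical covariates:
#' (1) fit the full Cox model; (2) greedily remove the variable whose
#' removal most decreases AIC, until no removal decreases AIC; (3) compute
#' generalized variance inflation factors on the dummy-coded design and
#' remove variables with VIF > `vif_cutoff` one at a time (largest first),
#' re-running step (2) after each removal; (4) report hazard ratios, Wald
#' CIs and likelihood-ratio p-values for retained variables together with
#' the model AIC and Harrell's C. The biomarker competes for elimination
#' like any other variable. Rows with missing values are dropped
#' (complete-case analysis).
#'
#' @param data Data frame of covariates and endpoint columns.
#' @param covariates Character vector of variable names entering the full
#'   model (clinical variables plus the biomarker).
#' @param time,event Endpoint column names.
#' @param vif_cutoff VIF threshold, default 2.
#' @return A list of class `cox_selection`: `terms` tibble (per retained
#'   variable: `term`, `hr`, `ci_low`, `ci_high`, `p`), `retained`,
#'   `removed_aic`, `removed_vif`, `aic_full`, `aic_final`, `harrell_c`,
#'   `n`, `n_events`, and `fit` (the final `coxph`).
#' @export
cox_multivariate_backward <- function(data, covariates, time, event,
                                      vif_cutoff = 2) {
  check_columns(data, c(covariates, time, event), "data")
  d <- as.data.frame(data)[, c(covariates, time, event)]
  d <- d[complete.cases(d), , drop = FALSE]
  # drop factor levels coding missingness
  for (v in covariates) {
    if (is.character(d[[v]]) || is.factor(d[[v]])) {
      d <- d[as.character(d[[v]]) != "missing", , drop = FALSE]
      d[[v]] <- factor(as.character(d[[v]]))
    }
  }
  if (sum(d[[event]]) < 10) abort("fewer than 10 events; multivariate model not fit")

  full_fit <- cox_fit(d, covariates, time, event)
  aic_full <- cox_aic(full_fit)

  backward <- function(vars) {
    repeat {
      fit <- cox_fit(d, vars, time, event)
      aic <- cox_aic(fit)
      if (length(vars) == 1) return(vars)
      cand <- vapply(vars, function(v) {
        cox_aic(cox_fit(d, setdiff(vars, v), time, event))
      }, numeric(1))
      if (min(cand) < aic) {
        vars <- setdiff(vars, names(which.min(cand)))
      } else {
        return(vars)
      }
    }
  }

  removed_aic <- character(0)
  vars <- backward(covariates)
  removed_aic <- setdiff(covariates, vars)

  removed_vif <- character(0)
  repeat {
    if (length(vars) < 2) break
    mm <- model.matrix(as.formula(paste("~", paste(vars, collapse = " + "))), d)
    assign <- attr(mm, "assign")[-1]
    X <- mm[, -1, drop = FALSE]
    vif <- gvif_terms(X, assign, vars)
    if (all(vif <= vif_cutoff, na.rm = TRUE)) break
    worst <- names(which.max(vif))
    removed_vif <- c(removed_vif, worst)
    vars <- setdiff(vars, worst)
    vars2 <- backward(vars)
    removed_aic <- c(removed_aic, setdiff(vars, vars2))
    vars <- vars2
  }

  fit <- cox_fit(d, vars, time, event)
  aic_final <- cox_aic(fit)
  conc <- survival::concordance(fit)$concordance

  # per-term LR p: final model vs final without the term
  sm <- summary(fit)
  terms_tbl <- tibble::tibble(
    term = rownames(sm$coefficients),
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p = NA_real_
  )
  # map coefficient rows to variables for LR tests
  mm <- model.matrix(fit)
  assign <- attr(mm, "assign")
  var_of_coef <- vars[assign]
  for (v in vars) {
    red_ll <- if (length(vars) == 1) fit$loglik[1] else
      cox_fit(d, setdiff(vars, v), time, event)$loglik[2]
    df <- sum(var_of_coef == v)
    pv <- lr_pvalue(fit, red_ll, df)
    terms_tbl$p[var_of_coef == v] <- pv
  }

  structure(
    list(terms = terms_tbl, retained = vars,
         removed_aic = removed_aic, removed_vif = removed_vif,
         aic_full = aic_full, aic_final = aic_final,
         harrell_c = unname(conc), n = fit$n, n_events = fit$nevent,
         fit = fit),
    class = "cox_selection"
  )
}

#' @rdname cox_multivariate_backward
#' @param x A `cox_selection`.
#' @param ... Unused.
#' @method tidy cox_selection
#' @export
tidy.cox_selection <- function(x, ...) x$terms

#' @rdname cox_multivariate_backward
#' @method glance cox_selection
#' @export
glance.cox_selection <- function(x, ...) {
  tibble::tibble(aic_full = x$aic_full, aic_final = x$aic_final,
                 harrell_c = x$harrell_c, n = x$n, n_events = x$n_events,
                 n_retained = length(x$retained))
}

#' @export
print.cox_selection <- function(x, ...) {
  cat(sprintf("Cox model after backward elimination: %d/%d variables retained\n",
              length(x$retained), length(x$retained) + length(x$removed_aic) +
                length(x$removed_vif)))
  cat(sprintf("AIC %.1f -> %.1f; Harrell's C = %.3f (%d events / %d subjects)\n",
              x$aic_full, x$aic_final, x$harrell_c, x$n_events, x$n))
  print(x$terms)
  invisible(x)
}
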