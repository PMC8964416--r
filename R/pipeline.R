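# End-to-end orchestration: QC -> positivity -> classification -> scores ->
# concordance, clustering and survival models, for both the core-average and
# hot-spot workflows.

#' Run the full TMA immune analysis
#'
#' Single seeded entry point executing the whole pipeline on cell, core and
#' patient tables: cell QC and core assessability, per-marker positivity
#' (two-component mixture by default), rule-table classification (or SVM /
#' probabilistic when requested), per-core scores, pathologist-concordance
#' Welch ANOVA, heterogeneity accounting, Spearman correlations and Ward
#' clusters of per-patient subtype percentages, and — for both the
#' core-average and hot-spot workflows and both endpoints (DFS, OS) —
#' median-dichotomized Kaplan-Meier log-rank tests, univariate Cox fits per
#' quantity and a backward-eliminated multivariate Cox model for each
#' biomarker adjusted for the clinical covariates.
#'
#' @param cells,cores,patients Input tibbles (see [simulate_cohort()] for
#'   the expected columns; `true_class` is not required).
#' @param mode Classification route: `"rule"` (default), `"svm"` (requires
#'   `annotations` with class labels) or `"prob"` (auto-annotation +
#'   probabilistic model).
#' @param annotations Optional annotation tibble for `mode = "svm"`.
#' @param thresholds [qc_thresholds()].
#' @param min_cells Core assessability floor, default 100.
#' @param quantities Biomarker quantities analyzed for survival; default
#'   the five single markers and six T subtypes.
#' @param clinical Clinical covariate names for the multivariate models.
#' @param seed Integer seed.
#' @return A list of class `tma_analysis` with elements `qc_report`,
#'   `cores`, `positivity`, `classes`, `core_scores`, `patient_scores`,
#'   `hotspot` (cores and scores), `concordance`, `heterogeneity`,
#'   `spearman`, `clusters`, `km` (tibble of log-rank results),
#'   `cox_univariate` (forest tibble) and `cox_multivariate` (per
#'   quantity/endpoint/workflow `cox_selection` objects).
#' @export
run_full_analysis <- function(cells, cores, patients,
                              mode = c("rule", "svm", "prob"),
                              annotations = NULL,
                              thresholds = qc_thresholds(),
                              min_cells = 100,
                              quantities = IMT_QUANTITIES,
                              clinical = c("t_stage", "n_stage", "age", "sex",
                                           "lnc", "pln", "differentiation", "lvi"),
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)

  qc <- apply_cell_filters(cells, thresholds, cores)
  kept <- qc$cells
  cores2 <- flag_assessable_cores(cores, kept, min_cells = min_cells)

  positivity <- binarize_panel(kept)
  classes <- switch(mode,
    rule = classify_rule_table(positivity),
    svm = {
      if (is.null(annotations)) abort("mode = 'svm' requires annotations")
      model <- train_multimarker_svm(kept, annotations, seed = seed)
      predict(model, kept)
    },
    prob = {
      ann <- auto_annotate(kept, seed = seed)
      predict_probabilistic(fit_probabilistic_model(ann, kept), kept)
    }
  )

  core_scores <- score_cores(kept, positivity, classes)
  patient_scores <- patient_average(core_scores, cores2)

  # pathologist concordance (assessable cores only)
  assess <- core_scores$core_id %in% cores2$core_id[cores2$assessable]
  cs <- dplyr::left_join(core_scores[assess, ],
                         cores2[, c("core_id", "path_immune", "path_stroma")],
                         by = "core_id")
  # tiny cohorts may lack a category with >= 2 cores; record the reason
  # instead of failing the whole analysis
  safe_welch <- function(values, group) {
    tryCatch(welch_anova_pairwise(values, group),
             error = function(e) list(overall_p = NA_real_,
                                      error = conditionMessage(e)))
  }
  concordance <- list(
    immune = safe_welch(cs$immune_score, cs$path_immune),
    stroma = safe_welch(cs$stroma_score[!cs$stroma_undefined],
                        cs$path_stroma[!cs$stroma_undefined])
  )
  heterogeneity <- list(
    immune = heterogeneity_summary(cores2[cores2$assessable, ], "path_immune"),
    stroma = heterogeneity_summary(cores2[cores2$assessable, ], "path_stroma")
  )

  pct_cols <- paste0("pct_", IMT_T_CLASSES)
  spearman <- spearman_matrix(patient_scores[, pct_cols])
  clusters <- list(
    k2 = cluster_patients(patient_scores[, pct_cols], k = 2),
    k3 = cluster_patients(patient_scores[, pct_cols], k = 3)
  )

  # hot-spot workflow: one core per patient among eligible patients
  hs <- hotspot_select(core_scores[core_scores$patient_id %in%
                                     patient_scores$patient_id, ],
                       mode = "multi", cores = cores2)
  hotspot_scores <- core_scores[match(hs$core_id, core_scores$core_id), ] |>
    dplyr::select("patient_id", dplyr::all_of(paste0("pct_", quantities)))

  surv_tables <- list(
    average = dplyr::inner_join(patient_scores, patients, by = "patient_id"),
    hotspot = dplyr::inner_join(hotspot_scores, patients, by = "patient_id")
  )
  endpoints <- list(dfs = c("dfs_months", "dfs_event"),
                    os = c("os_months", "os_event"))

  km_rows <- list(); uni_rows <- list(); multi <- list()
  for (wf in names(surv_tables)) {
    tb <- surv_tables[[wf]]
    for (ep in names(endpoints)) {
      tm <- endpoints[[ep]][1]; ev <- endpoints[[ep]][2]
      for (q in quantities) {
        colq <- paste0("pct_", q)
        grp <- tryCatch(dichotomize_median(tb[[colq]]), error = function(e) NULL)
        if (!is.null(grp) && length(unique(grp)) == 2) {
          km <- km_logrank(tb[[tm]], tb[[ev]], grp)
          km_rows[[paste(wf, ep, q)]] <- tibble::tibble(
            workflow = wf, endpoint = ep, quantity = q,
            logrank_p = km$logrank_p)
        }
        uni <- cox_univariate(tb, colq, tm, ev)
        uni$workflow <- wf; uni$endpoint <- ep; uni$quantity <- q
        uni_rows[[paste(wf, ep, q)]] <- uni
        multi[[paste(wf, ep, q, sep = "_")]] <- tryCatch(
          cox_multivariate_backward(tb, c(clinical, colq), tm, ev),
          error = function(e) {
            structure(list(error = conditionMessage(e), workflow = wf,
                           endpoint = ep, quantity = q),
                      class = "cox_selection_failure")
          }
        )
      }
    }
  }

  structure(
    list(
      qc_report = qc$report,
      cores = cores2,
      positivity = positivity,
      classes = classes,
      core_scores = core_scores,
      patient_scores = patient_scores,
      hotspot = list(selection = hs, scores = hotspot_scores),
      concordance = concordance,
      heterogeneity = heterogeneity,
      spearman = spearman,
      clusters = clusters,
      km = dplyr::bind_rows(km_rows),
      cox_univariate = dplyr::bind_rows(uni_rows),
      cox_multivariate = multi,
      mode = mode,
      seed = seed
    ),
    class = "tma_analysis"
  )
}

#' @export
print.tma_analysis <- function(x, ...) {
  cat(sprintf("TMA immune analysis (%s classification, seed %d)\n", x$mode, x$seed))
  cat(sprintf("  %d cores scored, %d patients averaged\n",
              nrow(x$core_scores), nrow(x$patient_scores)))
  cat(sprintf("  pathologist concordance: immune p = %.2g, stroma p = %.2g\n",
              x$concordance$immune$overall_p, x$concordance$stroma$overall_p))
  cat(sprintf("  univariate Cox rows: %d; multivariate models: %d\n",
              nrow(x$cox_univariate), length(x$cox_multivariate)))
  invisible(x)
}

#' @rdname run_full_analysis
#' @param x A `tma_analysis`.
#' @param ... Unused.
#' @method tidy tma_analysis
#' @export
tidy.tma_analysis <- function(x, ...) x$cox_univariate

#' @rdname run_full_analysis
#' @method glance tma_analysis
#' @export
glance.tma_analysis <- function(x, ...) {
  tibble::tibble(
    n_cores = nrow(x$core_scores),
    n_patients = nrow(x$patient_scores),
    cells_kept = x$qc_report$cells_out,
    immune_concordance_p = x$concordance$immune$overall_p,
    stroma_concordance_p = x$concordance$stroma$overall_p
  )
}
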