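# Per-core immune and stroma scores, percent-of-total quantification,
# compartment splits, per-patient averaging and hot-spot core selection.

IMT_QUANTITIES <- c(IMT_SINGLE_MARKERS, IMT_T_CLASSES)

#' Per-core immune score
#'
#' Counts segmented cells positive for any immune marker (CD45, CD3, CD4 or
#' CD8) and negative for the epithelial marker AE1.
#'
#' @param positivity Positivity tibble for one core with `pos_CD45`,
#'   `pos_CD3`, `pos_CD4`, `pos_CD8`, `pos_AE1`.
#' @return Integer count.
#' @export
immune_score <- function(positivity) {
  check_columns(positivity, pos_col(c(IMT_IMMUNE_MARKERS, "AE1")), "positivity")
  with(positivity,
       sum((pos_CD45 | pos_CD3 | pos_CD4 | pos_CD8) & !pos_AE1))
}

#' Per-core stroma score
#'
#' Percent, among cells outside the epithelial mask, of cells negative for
#' AE1 and for all immune markers (non-immune stromal cells).
#'
#' @param cells Cell tibble for one core with `in_epithelial_mask`.
#' @param positivity Matching positivity tibble (same cells).
#' @return Percent in \[0, 100\], or `NA` with attribute
#'   `undefined = TRUE` when the core has no non-epithelial cells.
#' @export
stroma_score <- function(cells, positivity) {
  check_columns(cells, c("cell_id", "in_epithelial_mask"), "cells")
  d <- dplyr::inner_join(cells[, c("cell_id", "in_epithelial_mask")],
                         positivity, by = "cell_id")
  outside <- !d$in_epithelial_mask
  if (!any(outside)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  immune <- d$pos_CD45 | d$pos_CD3 | d$pos_CD4 | d$pos_CD8
  100 * sum(outside & !d$pos_AE1 & !immune) / sum(outside)
}

#' Percent of total cells for a quantity
#'
#' `100 * count(quantity) / total cells`, where the quantity is either a
#' single marker (counted from positivity) or a multi-marker class
#' (counted from class calls).
#'
#' @param n_quantity,n_total Counts.
#' @return Percent.
#' @export
percent_of_total <- function(n_quantity, n_total) {
  if (any(n_total <= 0)) abort("percent_of_total is undefined for empty cores")
  100 * n_quantity / n_total
}

#' Score all cores
#'
#' Computes, per core: total QC-kept cells, the immune score, the stroma
#' score, counts and percent-of-total for the five single markers and the
#' six T-cell subtype classes, and the total T-cell count.
#'
#' @param cells QC-kept cell tibble.
#' @param positivity Positivity tibble from [binarize_panel()] including
#'   CD45.
#' @param classes Class-call tibble (e.g. from [classify_rule_table()]).
#' @return Tibble, one row per core: `core_id`, `patient_id`, `n_cells`,
#'   `immune_score`, `stroma_score`, `stroma_undefined`, `n_<q>` and
#'   `pct_<q>` per quantity, `n_T` (sum over the six T classes).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, cells_per_core = 150, seed = 5))
#' pv <- binarize_panel(cohort$cells, method = "fixed", threshold = 220)
#' cls <- classify_rule_table(pv)
#' score_cores(cohort$cells, pv, cls)
score_cores <- function(cells, positivity, classes) {
  check_columns(cells, c("cell_id", "core_id", "patient_id", "in_epithelial_mask"),
                "cells")
  d <- cells |>
    dplyr::select("cell_id", "core_id", "patient_id", "in_epithelial_mask") |>
    dplyr::inner_join(positivity, by = "cell_id") |>
    dplyr::inner_join(classes[, c("cell_id", "class")], by = "cell_id")

  out <- d |>
    dplyr::group_by(.data$core_id, .data$patient_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      immune_score = sum((.data$pos_CD45 | .data$pos_CD3 | .data$pos_CD4 |
                            .data$pos_CD8) & !.data$pos_AE1),
      n_outside = sum(!.data$in_epithelial_mask),
      n_stromal_cells = sum(!.data$in_epithelial_mask & !.data$pos_AE1 &
                              !(.data$pos_CD45 | .data$pos_CD3 |
                                  .data$pos_CD4 | .data$pos_CD8)),
      dplyr::across(dplyr::all_of(pos_col(IMT_SINGLE_MARKERS)), sum,
                    .names = "n_{sub('pos_', '', .col)}"),
      .groups = "drop"
    )
  # subtype counts
  cls_counts <- d |>
    dplyr::count(.data$core_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (cl in IMT_CLASSES) {
    nm <- paste0("n_", cl)
    if (!nm %in% names(cls_counts)) cls_counts[[nm]] <- 0L
  }
  out <- dplyr::left_join(out, cls_counts, by = "core_id")

  out$stroma_score <- ifelse(out$n_outside > 0,
                             100 * out$n_stromal_cells / out$n_outside,
                             NA_real_)
  out$stroma_undefined <- out$n_outside == 0
  out$n_T <- rowSums(as.matrix(out[, paste0("n_", IMT_T_CLASSES)]))
  for (q in IMT_QUANTITIES) {
    out[[paste0("pct_", q)]] <- percent_of_total(out[[paste0("n_", q)]], out$n_cells)
  }
  dplyr::select(out, -"n_outside", -"n_stromal_cells") |>
    dplyr::arrange(.data$core_id)
}

#' Per-patient average scores
#'
#' Unweighted arithmetic mean, per quantity, over a patient's assessable
#' cores. Only patients with at least two assessable cores are returned;
#' excluded patients are recorded in the `excluded` attribute.
#'
#' @param core_scores Output of [score_cores()].
#' @param cores Core tibble carrying `assessable` (see
#'   [flag_assessable_cores()]); if `NULL`, all scored cores count as
#'   assessable.
#' @return Tibble, one row per eligible patient: `patient_id`, `n_cores`
#'   and mean `pct_<q>` per quantity.
#' @export
patient_average <- function(core_scores, cores = NULL) {
  d <- core_scores
  if (!is.null(cores)) {
    keep <- cores$core_id[cores$assessable]
    d <- d[d$core_id %in% keep, ]
  }
  pct_cols <- grep("^pct_", names(d), value = TRUE)
  out <- d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      dplyr::across(dplyr::all_of(pct_cols), mean),
      .groups = "drop"
    )
  excluded <- out$patient_id[out$n_cores < 2]
  out <- out[out$n_cores >= 2, ]
  attr(out, "excluded") <- excluded
  out
}

#' Select the immune hot-spot core per patient
#'
#' For each patient, picks the assessable core with the highest T-cell
#' count: the CD3-positive cell count in `"single"` mode, or the summed
#' count of the six T-cell subtype classes in `"multi"` mode. Ties are
#' broken by the lexicographically smallest `core_id`.
#'
#' @param core_scores Output of [score_cores()].
#' @param mode `"multi"` (default) or `"single"`.
#' @param cores Optional core tibble with `assessable`.
#' @return Tibble `patient_id`, `core_id`, `hotspot_count`.
#' @export
hotspot_select <- function(core_scores, mode = c("multi", "single"),
                           cores = NULL) {
  mode <- match.arg(mode)
  d <- core_scores
  if (!is.null(cores)) d <- d[d$core_id %in% cores$core_id[cores$assessable], ]
  if (nrow(d) == 0) abort("no assessable cores to select a hot-spot from")
  d$hotspot_count <- if (mode == "single") d$n_CD3 else d$n_T
  d |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$hotspot_count),
                   .data$core_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "core_id", "hotspot_count")
}

#' Split subtype counts by tissue compartment
#'
#' Partitions each class's cells within each core into epithelial-associated
#' (inside the epithelial segmentation mask) and stromal cells.
#'
#' @param cells Cell tibble with `in_epithelial_mask`.
#' @param classes Class-call tibble.
#' @return Tibble `core_id`, `class`, `n_epithelial_assoc`, `n_stromal`,
#'   `n_total`.
#' @export
compartment_split <- function(cells, classes) {
  check_columns(cells, c("cell_id", "core_id", "in_epithelial_mask"), "cells")
  cells |>
    dplyr::select("cell_id", "core_id", "in_epithelial_mask") |>
    dplyr::inner_join(classes[, c("cell_id", "class")], by = "cell_id") |>
    dplyr::group_by(.data$core_id, .data$class) |>
    dplyr::summarise(
      n_epithelial_assoc = sum(.data$in_epithelial_mask),
      n_stromal = sum(!.data$in_epithelial_mask),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}
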