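# Post-segmentation cell filtering and core assessability.

#' Quality-control thresholds for segmented cells
#'
#' The six post-segmentation filter criteria, in the order they are
#' reported: (1) epithelial-mask cells must have a nucleus count inside
#' `nuclei_range_epithelial`; (2) every subcellular compartment area
#' (nucleus, membrane, cytoplasm) must lie strictly inside
#' `compartment_area_px`; (3) the cell must be aligned with the first
#' staining round; (4) the cell must sit strictly more than `margin_min_px`
#' pixels from every image edge (Chebyshev distance); (5) the nuclear
#' segmentation mask area must lie strictly inside `nuclear_area_px`;
#' (6) duplicated cells (same core and identical rounded coordinates) are
#' dropped, keeping the first occurrence.
#'
#' @param nuclei_range_epithelial Inclusive integer interval, default
#'   `c(1, 2)`.
#' @param compartment_area_px Open interval in pixels, default
#'   `c(10, 1500)`.
#' @param margin_min_px Minimum edge distance (strict), default 25.
#' @param nuclear_area_px Open interval in pixels, default `c(100, 3000)`.
#' @param require_round0_alignment Drop cells not aligned to round 0?
#' @param drop_duplicates Drop coordinate duplicates within a core?
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(nuclei_range_epithelial = c(1L, 2L),
                          compartment_area_px = c(10, 1500),
                          nuclear_area_px = c(100, 3000),
                          margin_min_px = 25,
                          require_round0_alignment = TRUE,
                          drop_duplicates = TRUE) {
  for (iv in list(nuclei_range_epithelial, compartment_area_px, nuclear_area_px)) {
    if (length(iv) != 2 || iv[1] >= iv[2]) abort("interval bounds must satisfy lower < upper")
  }
  if (margin_min_px < 0) abort("margin_min_px must be >= 0")
  structure(
    list(
      nuclei_range_epithelial = nuclei_range_epithelial,
      compartment_area_px = compartment_area_px,
      nuclear_area_px = nuclear_area_px,
      margin_min_px = margin_min_px,
      require_round0_alignment = require_round0_alignment,
      drop_duplicates = drop_duplicates
    ),
    class = "qc_thresholds"
  )
}

#' Apply post-segmentation cell filters
#'
#' Keeps a cell iff it passes all six criteria of [qc_thresholds()]. The
#' kept set is criterion-order independent; for reporting, each excluded
#' cell is attributed to its lowest-numbered failing criterion.
#'
#' @param cells Cell tibble with `cell_id`, `core_id`, `x`, `y`,
#'   `nucleus_count`, `area_nucleus`, `area_membrane`, `area_cytoplasm`,
#'   `in_epithelial_mask`, `aligned_round0`.
#' @param thresholds A [qc_thresholds()] object.
#' @param core_dims Tibble with `core_id`, `width_px`, `height_px` (a
#'   `cores` table works).
#' @return A list of class `qc_result`: `cells` (the kept tibble) and
#'   `report` (class `qc_report`) with per-criterion exclusion counts,
#'   `cells_in` and `cells_out`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, cells_per_core = 100, seed = 3))
#' qc <- apply_cell_filters(cohort$cells, qc_thresholds(), cohort$cores)
#' tidy(qc$report)
apply_cell_filters <- function(cells, thresholds = qc_thresholds(),
                               core_dims = NULL) {
  required <- c("cell_id", "core_id", "x", "y", "nucleus_count",
                "area_nucleus", "area_membrane", "area_cytoplasm",
                "in_epithelial_mask", "aligned_round0")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    abort(sprintf("cells table is missing required field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(core_dims)) abort("core_dims (core_id, width_px, height_px) is required")
  check_columns(core_dims, c("core_id", "width_px", "height_px"), "core_dims")
  for (fld in required) {
    bad <- is.na(cells[[fld]])
    if (any(bad)) {
      abort(sprintf("missing value in field '%s' for cell_id %s",
                    fld, cells$cell_id[which(bad)[1]]))
    }
  }

  th <- thresholds
  d <- dplyr::left_join(
    cells,
    dplyr::select(core_dims, "core_id", "width_px", "height_px"),
    by = "core_id"
  )
  if (anyNA(d$width_px)) abort("some cells reference cores absent from core_dims")

  in_open <- function(x, iv) x > iv[1] & x < iv[2]

  fail1 <- d$in_epithelial_mask &
    !(d$nucleus_count >= th$nuclei_range_epithelial[1] &
        d$nucleus_count <= th$nuclei_range_epithelial[2])
  fail2 <- !(in_open(d$area_nucleus, th$compartment_area_px) &
               in_open(d$area_membrane, th$compartment_area_px) &
               in_open(d$area_cytoplasm, th$compartment_area_px))
  fail3 <- if (th$require_round0_alignment) !d$aligned_round0 else rep(FALSE, nrow(d))
  edge_dist <- pmin(d$x, d$y, d$width_px - 1 - d$x, d$height_px - 1 - d$y)
  fail4 <- !(edge_dist > th$margin_min_px)
  fail5 <- !in_open(d$area_nucleus, th$nuclear_area_px)
  fail6 <- if (th$drop_duplicates) {
    duplicated(data.frame(d$core_id, round(d$x), round(d$y)))
  } else rep(FALSE, nrow(d))

  fails <- cbind(fail1, fail2, fail3, fail4, fail5, fail6)
  keep <- rowSums(fails) == 0
  # first failing criterion per excluded cell
  first_fail <- apply(fails[!keep, , drop = FALSE], 1, function(z) which(z)[1])

  report <- structure(
    list(
      cells_in = nrow(cells),
      cells_out = sum(keep),
      exclusions = tibble::tibble(
        criterion = 1:6,
        description = c(
          "epithelial nucleus count outside range",
          "compartment area outside bounds",
          "not aligned to staining round 0",
          "too close to image margin",
          "nuclear mask area outside bounds",
          "duplicate coordinates within core"
        ),
        n_excluded = vapply(1:6, function(k) sum(first_fail == k), integer(1))
      )
    ),
    class = "qc_report"
  )
  kept <- cells[keep, , drop = FALSE]
  structure(list(cells = kept, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Cell QC: %d cells in, %d kept, %d excluded\n",
              x$cells_in, x$cells_out, x$cells_in - x$cells_out))
  print(x$exclusions)
  invisible(x)
}

#' @rdname apply_cell_filters
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::mutate(x$exclusions, cells_in = x$cells_in, cells_out = x$cells_out)
}

#' Flag assessable cores and averaging-eligible patients
#'
#' A core is assessable when it retains at least `min_cells` QC-kept cells.
#' Patients with fewer than two assessable cores are flagged: per-patient
#' averaging uses multi-core patients only.
#'
#' @param cores Core tibble with `core_id` and `patient_id`.
#' @param kept_cells QC-kept cell tibble.
#' @param min_cells Minimum kept cells for assessability (default 100).
#' @return `cores` with columns `n_cells_kept`, `assessable` and
#'   `patient_eligible` (>= 2 assessable cores for the patient).
#' @export
flag_assessable_cores <- function(cores, kept_cells, min_cells = 100) {
  check_columns(cores, c("core_id", "patient_id"), "cores")
  counts <- dplyr::count(kept_cells, .data$core_id, name = "n_cells_kept")
  out <- cores |>
    dplyr::left_join(counts, by = "core_id") |>
    dplyr::mutate(
      n_cells_kept = dplyr::coalesce(.data$n_cells_kept, 0L),
      assessable = .data$n_cells_kept >= min_cells
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(patient_eligible = sum(.data$assessable) >= 2) |>
    dplyr::ungroup()
  out
}
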