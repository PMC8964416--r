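# Marker panel and cell-class vocabulary shared across the pipeline.

IMT_MARKERS <- c("DAPI", "AE1", "panCK", "NaKATPase", "S6",
                 "CD45", "CD3", "CD4", "CD8", "FOXP3", "PD1")

# Markers entering the multi-marker class table.
IMT_CLASS_MARKERS <- c("AE1", "CD3", "CD4", "CD8", "FOXP3", "PD1")

# Markers defining the per-core immune score (union positivity, AE1-negative).
IMT_IMMUNE_MARKERS <- c("CD45", "CD3", "CD4", "CD8")

IMT_CLASSES <- c("Th", "ThPD1", "Tc", "TcPD1", "Treg", "TregPD1",
                 "Epithelial", "Other")
IMT_T_CLASSES <- c("Tc", "TcPD1", "Th", "ThPD1", "Treg", "TregPD1")

IMT_SINGLE_MARKERS <- c("CD3", "CD4", "CD8", "FOXP3", "PD1")

#' Marker panel description
#'
#' The ten-plus-one marker panel the pipeline expects in per-cell tables:
#' the epithelial marker AE1, the T-cell lineage markers
#' (CD45, CD3, CD4, CD8, FOXP3, PD1) and structural markers used for
#' segmentation and subcellular analysis (DAPI, pan-cytokeratin, NaKATPase,
#' S6). Cell tables carry `mean_<marker>` and `sd_<marker>` columns.
#'
#' @return A tibble with columns `marker` and `role`
#'   (`epithelial`, `lineage` or `structural`).
#' @export
#' @examples
#' marker_panel()
marker_panel <- function() {
  tibble::tibble(
    marker = IMT_MARKERS,
    role = dplyr::case_when(
      IMT_MARKERS == "AE1" ~ "epithelial",
      IMT_MARKERS %in% c("CD45", "CD3", "CD4", "CD8", "FOXP3", "PD1") ~ "lineage",
      TRUE ~ "structural"
    )
  )
}

# Which panel markers are drawn from the positive intensity component for
# each ground-truth class; used by the cohort generator.  DAPI is positive
# in every nucleated cell.
class_marker_profile <- function() {
  list(
    Th         = c("DAPI", "CD45", "CD3", "CD4"),
    ThPD1      = c("DAPI", "CD45", "CD3", "CD4", "PD1"),
    Tc         = c("DAPI", "CD45", "CD3", "CD8"),
    TcPD1      = c("DAPI", "CD45", "CD3", "CD8", "PD1"),
    Treg       = c("DAPI", "CD45", "CD3", "CD4", "FOXP3"),
    TregPD1    = c("DAPI", "CD45", "CD3", "CD4", "FOXP3", "PD1"),
    Epithelial = c("DAPI", "AE1", "panCK", "NaKATPase", "S6"),
    Other      = "DAPI"
  )
}

mean_col <- function(marker) paste0("mean_", marker)
sd_col <- function(marker) paste0("sd_", marker)
pos_col <- function(marker) paste0("pos_", marker)

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
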