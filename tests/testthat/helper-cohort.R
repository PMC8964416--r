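# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small default cohort reused by several test files.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_cohort(
      sim_config(n_patients = 12, cells_per_core = 300, seed = 42)
    )
  }
  .fixtures$small
}

# Random positivity table over the score markers.
random_positivity <- function(n, seed = 1, p = 0.3) {
  set.seed(seed)
  out <- tibble::tibble(cell_id = sprintf("c%04d", seq_len(n)))
  for (mk in c("AE1", "CD45", "CD3", "CD4", "CD8", "FOXP3", "PD1")) {
    out[[paste0("pos_", mk)]] <- runif(n) < p
  }
  out
}

# Minimal valid cell row for QC tests; override fields as needed.
qc_cell <- function(..., core_id = "K1") {
  base <- tibble::tibble(
    cell_id = "c1", core_id = core_id, x = 500, y = 500,
    nucleus_count = 1L, area_nucleus = 500, area_membrane = 500,
    area_cytoplasm = 500, in_epithelial_mask = FALSE, aligned_round0 = TRUE
  )
  dplyr::mutate(base, ...)
}

qc_core_dims <- function(core_id = "K1", w = 1000, h = 1000) {
  tibble::tibble(core_id = core_id, width_px = w, height_px = h)
}

# Independent brute-force class mapping used as the rule-table oracle.
oracle_class <- function(ae1, cd3, cd4, cd8, foxp3, pd1) {
  if (ae1) return("Epithelial")
  if (cd3 && cd8 && !cd4) return(if (pd1) "TcPD1" else "Tc")
  if (cd3 && cd4 && !cd8) {
    if (foxp3) return(if (pd1) "TregPD1" else "Treg")
    return(if (pd1) "ThPD1" else "Th")
  }
  "Other"
}

# All 64 positivity patterns over the six classification markers.
all_patterns <- function() {
  g <- expand.grid(pos_AE1 = c(FALSE, TRUE), pos_CD3 = c(FALSE, TRUE),
                   pos_CD4 = c(FALSE, TRUE), pos_CD8 = c(FALSE, TRUE),
                   pos_FOXP3 = c(FALSE, TRUE), pos_PD1 = c(FALSE, TRUE))
  tibble::as_tibble(g) |>
    dplyr::mutate(cell_id = sprintf("p%02d", dplyr::row_number()),
                  .before = 1)
}
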