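# Seeded synthetic TMA cohort generator: patients -> cores -> segmented cells
# with known ground-truth classes, pathologist-style categorical scores and
# proportional-hazards survival outcomes.

#' Simulation configuration for a synthetic TMA cohort
#'
#' Parameters of the synthetic multiplexed-immunofluorescence cohort.
#' Defaults emulate a stage III colorectal TMA study: 117 patients with up
#' to three 1 mm cores each, a few thousand segmented cells per core, a
#' strongly skewed class mixture in which T-cell subtypes are each well
#' under 1 % of cells, and exponential survival whose hazard depends on the
#' patient's regulatory T-cell (Treg) fraction dichotomized at the cohort
#' median.
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Either a single integer in 1:3 giving the core
#'   count for every patient, or `NULL` (default) to sample 1/2/3 cores per
#'   patient with probabilities 7:99:62 (the assessable-core split of a
#'   typical TMA design).
#' @param cells_per_core Expected cells per core; realized counts are
#'   lognormal around this mean (sdlog 0.25) with a floor of 50.
#'   Values below 50 are rejected: per-core percent-of-total scores become
#'   degenerate for smaller cores.
#' @param class_mixture Named 8-vector of expected class fractions over
#'   the classes Th, ThPD1, Tc, TcPD1, Treg, TregPD1, Epithelial, Other;
#'   must sum to 1.
#' @param separation Multiplicative separation between the negative and
#'   positive intensity components (applied on the log scale).
#' @param base_meanlog,sdlog Location (log scale) of the negative intensity
#'   component and common log-scale spread of both components.
#' @param heterogeneity_sd Within-patient (core-to-core) dispersion of the
#'   class-fraction perturbation on the log-fraction scale.
#' @param patient_sd Between-patient dispersion of class fractions on the
#'   log-fraction scale; gives patients genuinely different Treg levels so
#'   that median dichotomization is meaningful.
#' @param beta_treg Log hazard ratio of the Treg-high versus Treg-low group
#'   (Treg fraction above vs below the cohort median).
#' @param baseline_hazard Baseline event hazard, events per month.
#' @param censor_rate Hazard of independent exponential censoring, per month.
#' @param os_gap_rate Rate of the exponential gap between relapse and death
#'   used to construct overall survival from disease-free survival.
#' @param core_px Width and height of the (square) core image, pixels.
#' @param path_noise Probability that a simulated pathologist category is
#'   flipped to an adjacent category (inter-observer noise).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 10, cells_per_core = 200, seed = 1)
#' cfg$class_mixture
sim_config <- function(n_patients = 117,
                       cores_per_patient = NULL,
                       cells_per_core = 2000,
                       class_mixture = c(
                         Th = 0.0015, ThPD1 = 0.006, Tc = 0.007,
                         TcPD1 = 0.005, Treg = 0.006, TregPD1 = 0.003,
                         Epithelial = 0.50, Other = 0.4715
                       ),
                       separation = 5,
                       base_meanlog = log(100),
                       sdlog = 0.35,
                       heterogeneity_sd = 0.35,
                       patient_sd = 0.5,
                       beta_treg = log(0.5),
                       baseline_hazard = 0.01,
                       censor_rate = 0.012,
                       os_gap_rate = 1 / 18,
                       core_px = 1400,
                       path_noise = 0.1,
                       seed = 1L) {
  if (n_patients < 1) abort("n_patients must be a positive integer")
  if (!is.null(cores_per_patient) &&
      (length(cores_per_patient) != 1 || !cores_per_patient %in% 1:3)) {
    abort("cores_per_patient must be NULL or a single integer in {1, 2, 3}")
  }
  if (cells_per_core < 50) {
    abort("cells_per_core must be >= 50: per-core scores are degenerate for smaller cores")
  }
  class_mixture <- class_mixture[IMT_CLASSES]
  if (anyNA(class_mixture)) {
    abort(sprintf("class_mixture must be named with the 8 classes: %s",
                  paste(IMT_CLASSES, collapse = ", ")))
  }
  if (abs(sum(class_mixture) - 1) > 1e-9) abort("class_mixture must sum to 1")
  if (any(class_mixture < 0)) abort("class_mixture fractions must be >= 0")
  if (separation <= 0 || sdlog <= 0) abort("intensity scales must be > 0")
  if (baseline_hazard <= 0) abort("baseline_hazard must be > 0")
  if (censor_rate < 0 || os_gap_rate <= 0) abort("censoring/gap rates invalid")

  intensity_params <- tibble::tibble(
    marker = IMT_MARKERS,
    meanlog_neg = base_meanlog,
    meanlog_pos = base_meanlog + log(separation),
    sdlog = sdlog
  )

  structure(
    list(
      n_patients = as.integer(n_patients),
      cores_per_patient = cores_per_patient,
      cells_per_core = cells_per_core,
      class_mixture = class_mixture,
      separation = separation,
      intensity_params = intensity_params,
      heterogeneity_sd = heterogeneity_sd,
      patient_sd = patient_sd,
      beta_treg = beta_treg,
      baseline_hazard = baseline_hazard,
      censor_rate = censor_rate,
      os_gap_rate = os_gap_rate,
      core_px = as.integer(core_px),
      path_noise = path_noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Perturb a fraction vector on the log scale and renormalize
# (logistic-normal); sd = 0 returns the input unchanged.
perturb_fractions <- function(p, sd) {
  if (sd == 0) return(p)
  lp <- log(pmax(p, 1e-12)) + rnorm(length(p), 0, sd)
  q <- exp(lp - max(lp))
  q[p == 0] <- 0          # structural zeros stay zero
  q / sum(q)
}

#' Generate a synthetic multiplexed-TMA cohort
#'
#' Draws a full synthetic cohort: clinical covariates per patient, one to
#' three cores per patient, and per-core segmented-cell tables with known
#' ground-truth classes. Per-core class fractions are the patient-level
#' mixture perturbed on the log-fraction scale by `heterogeneity_sd` and
#' renormalized; each cell's marker intensities are lognormal draws from
#' the positive component for the markers its true class expresses and the
#' negative component otherwise. Patient Treg fractions feed
#' [simulate_survival()] and true class compositions feed
#' [simulate_pathologist_scores()].
#'
#' @param config A [sim_config()] object.
#' @return A list of class `tma_cohort` with tibbles `patients`, `cores`
#'   and `cells`. Cells carry `true_class` (ground truth, absent in real
#'   data), coordinates, per-compartment areas, nucleus counts, an
#'   epithelial-mask flag, a staining-round alignment flag and
#'   `mean_`/`sd_` intensities for all panel markers.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 4, cells_per_core = 100, seed = 7))
#' dplyr::count(cohort$cells, true_class)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))

  patients <- tibble::tibble(
    patient_id = pid,
    t_stage = sample(c(2L, 3L, 4L), n, replace = TRUE,
                     prob = c(0.085, 0.598, 0.316)),
    n_stage = sample(c(1L, 2L), n, replace = TRUE, prob = c(0.709, 0.291)),
    age = pmin(pmax(round(rnorm(n, 59.2, 11.2)), 26), 85),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.393, 0.607)),
    lnc = pmax(5L, as.integer(round(rlnorm(n, log(19), 0.45)))),
    lvi = runif(n) < 0.581,
    differentiation = sample(c("moderate-to-well", "poor", "missing"),
                             n, replace = TRUE, prob = c(0.846, 0.137, 0.017))
  )
  patients$pln <- pmin(1L + rpois(n, 2), patients$lnc)

  n_cores <- if (is.null(config$cores_per_patient)) {
    sample(1:3, n, replace = TRUE, prob = c(7, 99, 62) / 168)
  } else {
    rep(config$cores_per_patient, n)
  }

  # patient-level mixtures: cohort mixture perturbed between patients
  patient_mix <- lapply(seq_len(n), function(i) {
    perturb_fractions(config$class_mixture, config$patient_sd)
  })

  profile <- class_marker_profile()
  ip <- config$intensity_params

  core_rows <- list()
  cell_rows <- list()
  r <- config$core_px / 2

  for (i in seq_len(n)) {
    for (j in seq_len(n_cores[i])) {
      core_id <- sprintf("%s_C%d", pid[i], j)
      m <- max(round(rlnorm(1, log(config$cells_per_core), 0.25)), 50L)
      frac <- perturb_fractions(patient_mix[[i]], config$heterogeneity_sd)
      counts <- as.vector(rmultinom(1, m, frac))
      true_class <- rep(IMT_CLASSES, counts)

      # uniform positions in the core disc
      theta <- runif(m, 0, 2 * pi)
      rad <- r * sqrt(runif(m))
      x <- round(r + rad * cos(theta), 1)
      y <- round(r + rad * sin(theta), 1)

      is_epi <- true_class == "Epithelial"
      in_mask <- ifelse(is_epi, runif(m) < 0.95, runif(m) < 0.10)
      nuc <- ifelse(is_epi,
                    sample(1:2, m, replace = TRUE, prob = c(0.9, 0.1)),
                    ifelse(runif(m) < 0.02, 0L, 1L))

      cell <- tibble::tibble(
        cell_id = sprintf("%s_%05d", core_id, seq_len(m)),
        core_id = core_id,
        patient_id = pid[i],
        x = x, y = y,
        nucleus_count = as.integer(nuc),
        area_nucleus = round(runif(m, 120, 1400)),
        area_membrane = round(runif(m, 50, 1400)),
        area_cytoplasm = round(runif(m, 50, 1400)),
        in_epithelial_mask = in_mask,
        aligned_round0 = runif(m) < 0.98,
        true_class = true_class
      )
      for (k in seq_len(nrow(ip))) {
        mk <- ip$marker[k]
        pos <- true_class %in% names(which(vapply(
          profile, function(p) mk %in% p, logical(1))))
        mu <- ifelse(pos, ip$meanlog_pos[k], ip$meanlog_neg[k])
        mean_i <- rlnorm(m, mu, ip$sdlog[k])
        cell[[mean_col(mk)]] <- mean_i
        cell[[sd_col(mk)]] <- mean_i * runif(m, 0.05, 0.25)
      }
      cell_rows[[core_id]] <- cell
      core_rows[[core_id]] <- tibble::tibble(
        core_id = core_id, patient_id = pid[i],
        tma_id = sprintf("TMA%d", ((i - 1) %% 5) + 1),
        width_px = config$core_px, height_px = config$core_px,
        assessable = TRUE
      )
    }
  }

  cores <- dplyr::bind_rows(core_rows)
  cells <- dplyr::bind_rows(cell_rows)

  treg_frac <- cells |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(treg = mean(.data$true_class == "Treg"), .groups = "drop")
  treg <- treg_frac$treg[match(pid, treg_frac$patient_id)]

  patients <- simulate_survival(patients, treg, config)
  cores <- simulate_pathologist_scores(cores, cells, noise = config$path_noise)

  structure(list(patients = patients, cores = cores, cells = cells),
            class = "tma_cohort")
}

#' Simulate survival outcomes from patient Treg fractions
#'
#' Fills DFS/OS times and event indicators. Disease-free survival times are
#' exponential with hazard `baseline_hazard * exp(beta_treg * I[Treg above
#' the cohort median])`; censoring is independent exponential with rate
#' `censor_rate`. Overall survival stochastically dominates DFS by
#' construction: the death time is the relapse time plus an independent
#' exponential gap, and both endpoints share one censoring time.
#'
#' @param patients Patient tibble (one row per patient).
#' @param treg_fraction Numeric vector, the Treg fraction per patient, in
#'   the order of `patients`.
#' @param config A [sim_config()]; only the hazard fields are used.
#' @return `patients` with columns `treg_fraction`, `dfs_months`,
#'   `dfs_event`, `os_months`, `os_event` added or replaced.
#' @export
simulate_survival <- function(patients, treg_fraction, config) {
  n <- nrow(patients)
  stopifnot(length(treg_fraction) == n)
  if (config$baseline_hazard <= 0) abort("baseline_hazard must be > 0")

  high <- treg_fraction > median(treg_fraction)
  hazard <- config$baseline_hazard * exp(config$beta_treg * high)
  t_dfs <- rexp(n, hazard)
  t_os <- t_dfs + rexp(n, config$os_gap_rate)
  cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else rep(Inf, n)

  patients$treg_fraction <- treg_fraction
  patients$dfs_months <- pmax(pmin(t_dfs, cens), 1e-6)
  patients$dfs_event <- as.integer(t_dfs <= cens)
  patients$os_months <- pmax(pmin(t_os, cens), 1e-6)
  patients$os_event <- as.integer(t_os <= cens)
  patients
}

#' Simulate pathologist immune and stroma categories per core
#'
#' Emulates a pathologist's three-level (`low`/`moderate`/`high`) visual
#' scoring from the ground-truth composition. The stroma category compares
#' true stromal-cell count against epithelial-cell count (higher / within a
#' +-10 % band / lower); the immune category is assigned by tertiles of the
#' true immune-cell fraction across all cores. With probability `noise`
#' a category is flipped to an adjacent level, emulating inter-observer
#' variability.
#'
#' @param cores Core tibble.
#' @param cells Cell tibble carrying `true_class`.
#' @param noise Adjacent-category flip probability in \[0, 1\].
#' @return `cores` with `path_immune` and `path_stroma` columns filled.
#' @export
simulate_pathologist_scores <- function(cores, cells, noise = 0.1) {
  check_columns(cells, c("core_id", "true_class"), "cells")
  comp <- cells |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(
      n_epi = sum(.data$true_class == "Epithelial"),
      n_stroma = sum(.data$true_class == "Other"),
      immune_frac = mean(.data$true_class %in% IMT_T_CLASSES),
      .groups = "drop"
    )
  comp <- dplyr::left_join(cores["core_id"], comp, by = "core_id")

  stroma <- dplyr::case_when(
    comp$n_stroma > 1.1 * comp$n_epi ~ "high",
    comp$n_stroma < 0.9 * comp$n_epi ~ "low",
    TRUE ~ "moderate"
  )
  cuts <- quantile(comp$immune_frac, c(1 / 3, 2 / 3), na.rm = TRUE)
  immune <- dplyr::case_when(
    comp$immune_frac <= cuts[1] ~ "low",
    comp$immune_frac <= cuts[2] ~ "moderate",
    TRUE ~ "high"
  )

  flip_adjacent <- function(cat, p) {
    flip <- runif(length(cat)) < p
    up <- runif(length(cat)) < 0.5
    dplyr::case_when(
      !flip ~ cat,
      cat == "low" ~ "moderate",
      cat == "high" ~ "moderate",
      up ~ "high",
      TRUE ~ "low"
    )
  }
  cores$path_stroma <- flip_adjacent(stroma, noise)
  cores$path_immune <- flip_adjacent(immune, noise)
  cores
}

#' Build a categorical-score cohort from marginal concordance counts
#'
#' Deterministically constructs one categorical score column (e.g. a
#' pathologist immune or stroma score) for a cohort of two- and three-core
#' patients matching stated marginal counts: how many two-core patients
#' have both cores identical, how many three-core patients have all three
#' identical, and how many have all three different. Used to reproduce
#' published heterogeneity accounting from printed summary counts.
#'
#' @param n_two,n_two_same Number of two-core patients and how many of them
#'   have the same category in both cores.
#' @param n_three,n_three_same,n_three_alldiff Number of three-core
#'   patients, how many have all three identical and how many have all
#'   three different; the remainder have exactly two distinct categories.
#' @param prefix Prefix for generated patient IDs.
#' @return A tibble with `patient_id`, `core_id` and `category`.
#' @export
#' @examples
#' x <- simulate_category_cohort(99, 44, 62, 13, 5)
#' nrow(dplyr::distinct(x, patient_id))
simulate_category_cohort <- function(n_two, n_two_same,
                                     n_three, n_three_same, n_three_alldiff,
                                     prefix = "F") {
  stopifnot(n_two_same <= n_two,
            n_three_same + n_three_alldiff <= n_three)
  pat_two <- function(same) if (same) c("moderate", "moderate") else c("low", "high")
  pat_three <- function(kind) switch(kind,
    same = c("moderate", "moderate", "moderate"),
    alldiff = c("low", "moderate", "high"),
    partial = c("low", "low", "high")
  )
  rows <- list()
  k <- 0
  for (i in seq_len(n_two)) {
    k <- k + 1
    rows[[k]] <- tibble::tibble(
      patient_id = sprintf("%s2_%03d", prefix, i),
      core_id = sprintf("%s2_%03d_C%d", prefix, i, 1:2),
      category = pat_two(i <= n_two_same)
    )
  }
  kinds <- rep(c("same", "alldiff", "partial"),
               c(n_three_same, n_three_alldiff,
                 n_three - n_three_same - n_three_alldiff))
  for (i in seq_len(n_three)) {
    k <- k + 1
    rows[[k]] <- tibble::tibble(
      patient_id = sprintf("%s3_%03d", prefix, i),
      core_id = sprintf("%s3_%03d_C%d", prefix, i, 1:3),
      category = pat_three(kinds[i])
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a cohort to delimited text files
#'
#' Writes `cells.csv`, `cores.csv` and `patients.csv` into a directory.
#'
#' @param cohort A `tma_cohort` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(cohort$cores, file.path(dir, "cores.csv"), row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  invisible(dir)
}
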