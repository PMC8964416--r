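# Positivity calling (fixed, mixture, Otsu), SVM classifiers, automatic
# annotation and the probabilistic model.

# Two-component lognormal marker with known truth.
mixture_cells <- function(n = 2000, p_pos = 0.1, sep = 10, sdlog = 0.35,
                          marker = "CD3", seed = 11) {
  set.seed(seed)
  pos <- runif(n) < p_pos
  mu <- log(100) + ifelse(pos, log(sep), 0)
  m <- rlnorm(n, mu, sdlog)
  out <- tibble::tibble(cell_id = sprintf("m%04d", seq_len(n)), truth = pos)
  out[[paste0("mean_", marker)]] <- m
  out[[paste0("sd_", marker)]] <- m * runif(n, 0.05, 0.25)
  out
}

test_that("fixed threshold is strict: 4.9 negative, 5.1 positive at cutoff 5", {
  cells <- tibble::tibble(mean_CD3 = c(4.9, 5.1, 5.0))
  got <- binarize_marker(cells, "CD3", method = "fixed", threshold = 5)
  expect_equal(as.logical(got), c(FALSE, TRUE, FALSE))
  expect_equal(attr(got, "threshold"), 5)
  expect_error(binarize_marker(cells, "CD3", method = "fixed"), "threshold")
  expect_error(binarize_marker(tibble::tibble(mean_CD3 = -1), "CD3",
                               method = "fixed", threshold = 5), "nonnegative")
})

test_that("mixture binarization recovers a rare, well-separated positive mode", {
  cells <- mixture_cells(sep = 10)
  got <- binarize_marker(cells, "CD3", method = "gmm2")
  expect_gte(mean(got == cells$truth), 0.99)
  thr <- attr(got, "threshold")[["all"]]
  # cutoff sits between the component medians
  expect_gt(thr, 100)
  expect_lt(thr, 1000)
  # calling is a monotone threshold on intensity
  expect_gt(min(cells$mean_CD3[got]), max(cells$mean_CD3[!got]))
})

test_that("Otsu binarization also separates a clear mixture", {
  cells <- mixture_cells(p_pos = 0.3, sep = 10, seed = 12)
  got <- binarize_marker(cells, "CD3", method = "otsu")
  expect_gte(mean(got == cells$truth), 0.98)
})

test_that("constant intensities give an all-negative call with a warning", {
  cells <- tibble::tibble(mean_CD3 = rep(7, 50))
  expect_warning(got <- binarize_marker(cells, "CD3", method = "gmm2"),
                 "constant")
  expect_false(any(got))
})

test_that("grouped thresholding adapts to per-slide intensity scales", {
  a <- mixture_cells(n = 1500, sep = 10, seed = 13)
  b <- mixture_cells(n = 1500, sep = 10, seed = 14)
  b$mean_CD3 <- b$mean_CD3 * 50   # slide with much brighter staining
  a$slide <- "s1"; b$slide <- "s2"
  cells <- dplyr::bind_rows(a, b)
  got <- binarize_marker(cells, "CD3", method = "gmm2", group = "slide")
  expect_gte(mean(got == cells$truth), 0.99)
  thr <- attr(got, "threshold")
  expect_gt(thr[["s2"]] / thr[["s1"]], 10)
})

test_that("panel binarization returns one column per marker plus thresholds", {
  co <- small_cohort()
  cells <- co$cells[1:800, ]
  pv <- binarize_panel(cells, markers = c("AE1", "CD3"))
  expect_equal(names(pv), c("cell_id", "pos_AE1", "pos_CD3"))
  expect_equal(nrow(pv), 800)
  expect_named(attr(pv, "thresholds"), c("AE1", "CD3"))
})

test_that("single-marker SVM separates a clean mixture and rejects one-class input", {
  cells <- mixture_cells(n = 600, p_pos = 0.4, sep = 10, seed = 15)
  ann <- tibble::tibble(cell_id = cells$cell_id,
                        label = ifelse(cells$truth, "positive", "negative"))
  tr <- ann[1:400, ]; te_cells <- cells[401:600, ]
  m <- train_marker_svm(cells, tr, "CD3")
  pred <- predict(m, te_cells)
  expect_gte(mean(pred == te_cells$truth), 0.99)
  expect_error(train_marker_svm(cells, dplyr::filter(ann, label == "positive"),
                                "CD3"), "single class")
  expect_error(train_marker_svm(cells, tibble::tibble(cell_id = "nope",
                                                      label = "positive"),
                                "CD3"), "no annotated")
})

test_that("marker SVM with permuted labels scores at chance level", {
  cells <- mixture_cells(n = 400, p_pos = 0.5, sep = 10, seed = 16)
  set.seed(99)
  ann <- tibble::tibble(cell_id = cells$cell_id,
                        label = sample(ifelse(cells$truth, "positive", "negative")))
  cv <- crossval_accuracy(cells, ann, type = "marker", marker = "CD3",
                          k = 3, seed = 5)
  expect_gt(cv$mean, 0.35)
  expect_lt(cv$mean, 0.65)
})

test_that("multi-marker SVM learns the ground-truth classes and agrees with the rule table", {
  co <- small_cohort()
  set.seed(20)
  # stratified annotation sample so rare subtypes are represented
  ann_all <- tibble::tibble(cell_id = co$cells$cell_id,
                            label = co$cells$true_class)
  ann <- ann_all |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_sample(n = 200) |>
    dplyr::ungroup()
  cv <- suppressWarnings(
    crossval_accuracy(co$cells, ann, type = "multimarker", k = 3, seed = 2))
  expect_gte(cv$mean, 0.90)

  model <- suppressWarnings(train_multimarker_svm(co$cells, ann, seed = 2))
  expect_gte(model$training_accuracy, 0.90)
  test_cells <- co$cells[1:2000, ]
  svm_calls <- predict(model, test_cells)
  rule_calls <- classify_rule_table(binarize_panel(test_cells))
  expect_gte(mean(svm_calls$class == rule_calls$class), 0.95)
})

test_that("multi-marker SVM drops tiny classes with a warning and rejects unknown labels", {
  co <- small_cohort()
  ann <- tibble::tibble(
    cell_id = co$cells$cell_id[1:103],
    label = c(rep("Epithelial", 50), rep("Other", 50), rep("Tc", 2), "Th")
  )
  expect_warning(m <- train_multimarker_svm(co$cells, ann), "< 3 annotations")
  expect_error(train_multimarker_svm(
    co$cells, tibble::tibble(cell_id = co$cells$cell_id[1:2],
                             label = c("Epithelial", "Blastoid"))),
    "unknown class")
})

test_that("cross-validated accuracy of permuted eight-class labels is near chance", {
  co <- small_cohort()
  set.seed(30)
  idx <- sample(nrow(co$cells), 1200)
  ann <- tibble::tibble(cell_id = co$cells$cell_id[idx],
                        label = sample(co$cells$true_class[idx]))
  cv <- suppressWarnings(
    crossval_accuracy(co$cells, ann, type = "multimarker", k = 3, seed = 3))
  # chance = accuracy of always guessing the majority class at best
  p_major <- max(table(ann$label)) / nrow(ann)
  se <- sqrt(p_major * (1 - p_major) / (nrow(ann) / 3))
  expect_lt(cv$mean, p_major + 4 * se)
})

test_that("cross-validation is deterministic given the seed", {
  cells <- mixture_cells(n = 300, p_pos = 0.5, sep = 10, seed = 17)
  ann <- tibble::tibble(cell_id = cells$cell_id,
                        label = ifelse(cells$truth, "positive", "negative"))
  a <- crossval_accuracy(cells, ann, type = "marker", marker = "CD3", seed = 8)
  b <- crossval_accuracy(cells, ann, type = "marker", marker = "CD3", seed = 8)
  expect_identical(a, b)
})

# --- automatic annotation ---------------------------------------------------

auto_cells <- function(n = 500, n_cd4 = 50, n_cd8 = 50, seed = 40) {
  set.seed(seed)
  hi <- rep(c("CD4", "CD8", "none"), c(n_cd4, n_cd8, n - n_cd4 - n_cd8))
  out <- tibble::tibble(
    cell_id = sprintf("a%04d", seq_len(n)),
    truth = hi,
    nucleus_count = 1L,
    area_nucleus = 500
  )
  for (mk in c("CD4", "CD8")) {
    out[[paste0("mean_", mk)]] <- rlnorm(n, log(100) + log(10) * (hi == mk), 0.3)
  }
  out
}

test_that("automatic annotation picks true high-expressors as positives", {
  cells <- auto_cells()
  ann <- auto_annotate(cells, markers = c("CD4", "CD8"), q = 0.9, seed = 1)
  pos_cd4 <- ann$cell_id[ann$marker == "CD4" & ann$label == "positive"]
  truth <- cells$truth[match(pos_cd4, cells$cell_id)]
  expect_gte(mean(truth == "CD4"), 0.95)
  expect_gte(length(pos_cd4), 20)
  # each marker gets negatives too
  expect_true(all(c("positive", "negative") %in%
                    ann$label[ann$marker == "CD8"]))
  expect_true(all(ann$annotator == "automatic"))
})

test_that("cells without a segmented nucleus are never annotated positive", {
  cells <- auto_cells()
  # knock out nuclei of the brightest CD4 cells
  top <- order(cells$mean_CD4, decreasing = TRUE)[1:10]
  cells$nucleus_count[top] <- 0L
  ann <- auto_annotate(cells, markers = c("CD4", "CD8"), q = 0.9, seed = 1)
  pos <- ann$cell_id[ann$label == "positive"]
  expect_false(any(cells$cell_id[top] %in% pos))
})

test_that("markers with too few candidates are skipped with a warning", {
  cells <- auto_cells()
  cells$mean_FOXP3 <- rep(100, nrow(cells))  # constant: no cell above its q95
  expect_warning(
    ann <- auto_annotate(cells, markers = c("CD4", "CD8", "FOXP3"),
                         q = 0.9, seed = 1),
    "FOXP3.*skipped")
  expect_false("FOXP3" %in% ann$marker)
  cells2 <- auto_cells()
  cells2$area_nucleus <- 50   # below the nuclear bounds: no candidates anywhere
  expect_error(suppressWarnings(
    auto_annotate(cells2, markers = c("CD4", "CD8"), q = 0.9, seed = 1)),
    "no marker")
})

# --- probabilistic model ----------------------------------------------------

test_that("probabilistic marker model agrees with linear discriminant analysis", {
  cells <- mixture_cells(n = 800, p_pos = 0.5, sep = 8, seed = 50)
  ann <- tibble::tibble(cell_id = cells$cell_id[1:400],
                        marker = "CD3",
                        label = ifelse(cells$truth[1:400], "positive", "negative"))
  model <- fit_probabilistic_model(ann, cells)
  test_cells <- cells[401:800, ]
  got <- predict_probabilistic(model, test_cells)

  train <- cells[1:400, ]
  f_tr <- cbind(log(train$mean_CD3 + 1e-9), log(train$sd_CD3 + 1e-9))
  f_te <- cbind(log(test_cells$mean_CD3 + 1e-9), log(test_cells$sd_CD3 + 1e-9))
  lda_fit <- MASS::lda(f_tr, grouping = ifelse(train$truth, "positive", "negative"),
                       prior = c(0.5, 0.5))
  lda_pos <- as.character(predict(lda_fit, f_te)$class) == "positive"

  # compare the per-marker positivity decision, not the final class (a
  # CD3-only model maps everything to Other through the rule table)
  m <- model$markers$CD3
  lp <- immunotma:::ldmvnorm2(f_te, m$mu_pos, m$sigma)
  ln <- immunotma:::ldmvnorm2(f_te, m$mu_neg, m$sigma)
  called_pos <- lp > ln
  expect_gte(mean(called_pos == lda_pos), 0.99)
  expect_gte(mean(called_pos == test_cells$truth), 0.97)
})

test_that("probabilistic classification recovers ground-truth classes on a cohort", {
  co <- small_cohort()
  cells <- co$cells
  ann <- suppressWarnings(auto_annotate(cells, seed = 3))
  model <- fit_probabilistic_model(ann, cells)
  got <- predict_probabilistic(model, cells)
  expect_equal(nrow(got), nrow(cells))
  expect_true(all(got$confidence >= 0 & got$confidence <= 1))
  expect_true(all(got$source == "probabilistic"))
  # epithelial vs non-epithelial separation is the dominant, easy signal
  epi_acc <- mean((got$class == "Epithelial") == (cells$true_class == "Epithelial"))
  expect_gte(epi_acc, 0.95)
})

test_that("probabilistic model rejects empty or single-class annotation sets", {
  co <- small_cohort()
  expect_error(fit_probabilistic_model(NULL, co$cells), "empty")
  expect_error(fit_probabilistic_model(
    tibble::tibble(cell_id = character(), marker = character(),
                   label = character())[0, ], co$cells), "empty")
  ann <- tibble::tibble(cell_id = co$cells$cell_id[1:10], marker = "CD3",
                        label = "positive")
  expect_error(fit_probabilistic_model(ann, co$cells), "single class")
})
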