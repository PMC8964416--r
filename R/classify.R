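# Per-marker positivity calling and multi-marker immune cell classification:
# explicit gating rule table, linear SVMs trained from annotations, and the
# automated-annotation probabilistic workflow.

#' Call per-cell positivity for one marker
#'
#' Binarizes a marker's mean intensity. The default `gmm2` method fits a
#' two-component, equal-variance Gaussian mixture to log intensities and
#' calls a cell positive when the posterior probability of the
#' higher-mean component exceeds 0.5; with equal variances this is a
#' monotone threshold in intensity. `otsu` minimizes intra-class variance
#' of the log-intensity histogram; `fixed` applies a raw-intensity cutoff.
#'
#' @param cells Cell tibble with a `mean_<marker>` column.
#' @param marker Marker name, e.g. `"CD3"`.
#' @param method One of `"gmm2"` (default), `"otsu"`, `"fixed"`.
#' @param threshold Raw-intensity cutoff for `method = "fixed"`
#'   (positive strictly above).
#' @param group Optional name of a column to fit within (e.g. a TMA slide
#'   id) so thresholds adapt per slide; default fits all cells together.
#' @return Logical vector of positivity, one element per row of `cells`,
#'   with attribute `threshold` (raw-intensity scale, per group).
#' @export
#' @examples
#' cells <- tibble::tibble(mean_CD3 = c(4.9, 5.1))
#' binarize_marker(cells, "CD3", method = "fixed", threshold = 5)
binarize_marker <- function(cells, marker,
                            method = c("gmm2", "otsu", "fixed"),
                            threshold = NULL, group = NULL) {
  method <- match.arg(method)
  col <- mean_col(marker)
  check_columns(cells, col, "cells")
  x <- cells[[col]]
  if (any(x < 0, na.rm = TRUE)) abort("intensities must be nonnegative")

  if (method == "fixed") {
    if (is.null(threshold)) abort("method = 'fixed' needs a threshold")
    out <- x > threshold
    attr(out, "threshold") <- threshold
    return(out)
  }

  groups <- if (is.null(group)) rep("all", length(x)) else as.character(cells[[group]])
  out <- logical(length(x))
  thr <- c()
  for (g in unique(groups)) {
    idx <- groups == g
    xg <- log(x[idx] + 1e-9)
    if (length(unique(xg)) < 3 || sd(xg) < 1e-10) {
      warn(sprintf("marker %s has (nearly) constant intensity in group %s; all cells called negative",
                   marker, g))
      out[idx] <- FALSE
      thr[g] <- Inf
      next
    }
    t_log <- if (method == "gmm2") gmm2_threshold(xg) else otsu_threshold(xg)
    out[idx] <- xg > t_log
    thr[g] <- exp(t_log)
  }
  attr(out, "threshold") <- thr
  out
}

# Equal-variance two-component Gaussian mixture on log intensities;
# returns the log-intensity value where the component posteriors cross.
gmm2_threshold <- function(xg) {
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller's scope
  fit <- mclust::Mclust(xg, G = 2, modelNames = "E", verbose = FALSE)
  mu <- fit$parameters$mean
  pro <- fit$parameters$pro
  s2 <- fit$parameters$variance$sigmasq
  hi <- which.max(mu); lo <- which.min(mu)
  # posterior crossing for equal variances
  (mu[hi] + mu[lo]) / 2 + s2 * log(pro[lo] / pro[hi]) / (mu[hi] - mu[lo])
}

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(xg, nbins = 256) {
  brk <- seq(min(xg), max(xg), length.out = nbins + 1)
  h <- tabulate(findInterval(xg, brk, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  brk[which.max(sigma_b) + 1]
}

#' Call positivity for a set of markers
#'
#' Runs [binarize_marker()] per marker and assembles a positivity table.
#'
#' @inheritParams binarize_marker
#' @param markers Character vector of markers; defaults to the six
#'   classification markers plus CD45 (needed by the immune score).
#' @return Tibble with `cell_id` and one logical `pos_<marker>` column per
#'   marker; attribute `thresholds` records the cutoffs used.
#' @export
binarize_panel <- function(cells,
                           markers = c(IMT_CLASS_MARKERS, "CD45"),
                           method = "gmm2", threshold = NULL, group = NULL) {
  check_columns(cells, "cell_id", "cells")
  out <- tibble::tibble(cell_id = cells$cell_id)
  thr <- list()
  for (mk in markers) {
    p <- binarize_marker(cells, mk, method = method,
                         threshold = threshold, group = group)
    thr[[mk]] <- attr(p, "threshold")
    out[[pos_col(mk)]] <- as.logical(p)
  }
  attr(out, "thresholds") <- thr
  out
}

#' Classify cells by the multi-marker gating rule table
#'
#' Maps each cell's positivity pattern over AE1, CD3, CD4, CD8, FOXP3 and
#' PD1 to one of the eight classes. Decision order: AE1+ cells are
#' Epithelial; CD3+CD8+CD4- cells are cytotoxic T (Tc, or TcPD1 when
#' PD1+); CD3+CD4+CD8-FOXP3- cells are helper T (Th/ThPD1);
#' CD3+CD4+CD8-FOXP3+ cells are regulatory T (Treg/TregPD1); every other
#' pattern — including CD4+CD8+ double positives — is Other. The mapping is
#' total: all 64 patterns receive exactly one class.
#'
#' @param positivity Tibble with `cell_id` and `pos_AE1`, `pos_CD3`,
#'   `pos_CD4`, `pos_CD8`, `pos_FOXP3`, `pos_PD1` (from
#'   [binarize_panel()]).
#' @return Tibble `cell_id`, `class`, `source = "rule"`,
#'   `confidence = NA`.
#' @export
#' @examples
#' pv <- tibble::tibble(cell_id = "c1", pos_AE1 = FALSE, pos_CD3 = TRUE,
#'   pos_CD4 = TRUE, pos_CD8 = FALSE, pos_FOXP3 = TRUE, pos_PD1 = FALSE)
#' classify_rule_table(pv)$class  # "Treg"
classify_rule_table <- function(positivity) {
  need <- pos_col(IMT_CLASS_MARKERS)
  missing <- setdiff(need, names(positivity))
  if (length(missing) > 0) {
    abort(sprintf("positivity table is missing marker column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ae1 <- positivity$pos_AE1; cd3 <- positivity$pos_CD3
  cd4 <- positivity$pos_CD4; cd8 <- positivity$pos_CD8
  foxp3 <- positivity$pos_FOXP3; pd1 <- positivity$pos_PD1

  class <- dplyr::case_when(
    ae1 ~ "Epithelial",
    cd3 & cd8 & !cd4 & !pd1 ~ "Tc",
    cd3 & cd8 & !cd4 & pd1 ~ "TcPD1",
    cd3 & cd4 & !cd8 & !foxp3 & !pd1 ~ "Th",
    cd3 & cd4 & !cd8 & !foxp3 & pd1 ~ "ThPD1",
    cd3 & cd4 & !cd8 & foxp3 & !pd1 ~ "Treg",
    cd3 & cd4 & !cd8 & foxp3 & pd1 ~ "TregPD1",
    TRUE ~ "Other"
  )
  tibble::tibble(
    cell_id = positivity$cell_id,
    class = class,
    source = "rule",
    confidence = NA_real_
  )
}

svm_features <- function(cells, markers) {
  cols <- c(vapply(markers, mean_col, ""), vapply(markers, sd_col, ""))
  check_columns(cells, cols, "cells")
  f <- log(as.matrix(cells[, cols]) + 1e-9)
  colnames(f) <- cols
  f
}

#' Train a single-marker linear SVM
#'
#' Fits a linear-kernel support vector machine separating marker-positive
#' from marker-negative cells, using the cell's mean and standard deviation
#' of that marker's intensity (log scale) as the two features.
#'
#' @param cells Cell tibble.
#' @param annotations Tibble with `cell_id` and `label`
#'   (`"positive"`/`"negative"`) for this marker.
#' @param marker Marker name.
#' @param cost SVM regularization constant, default 1.
#' @param seed Integer seed (training is deterministic given data; the seed
#'   fixes any tie-breaking).
#' @return An object of class `marker_svm`; use [predict()] with a cell
#'   tibble to obtain logical positivity.
#' @export
train_marker_svm <- function(cells, annotations, marker, cost = 1, seed = 1L) {
  check_columns(annotations, c("cell_id", "label"), "annotations")
  d <- dplyr::inner_join(annotations, cells, by = "cell_id")
  if (nrow(d) == 0) abort("no annotated cells found in the cell table")
  if (length(unique(d$label)) < 2) {
    abort(sprintf("annotations for %s contain a single class; annotate both positive and negative cells",
                  marker))
  }
  set.seed(seed)
  f <- svm_features(d, marker)
  fit <- e1071::svm(x = f, y = factor(d$label, levels = c("negative", "positive")),
                    kernel = "linear", cost = cost, scale = TRUE)
  structure(list(fit = fit, marker = marker), class = "marker_svm")
}

#' @export
predict.marker_svm <- function(object, newdata, ...) {
  f <- svm_features(newdata, object$marker)
  as.character(predict(object$fit, f)) == "positive"
}

#' Train the eight-class multi-marker linear SVM
#'
#' Fits one linear-kernel SVM over all eight classes using 12 features:
#' log mean and log SD intensity of AE1, CD3, CD4, CD8, FOXP3 and PD1.
#' Classes with fewer than three annotated cells are dropped with a
#' warning.
#'
#' @param cells Cell tibble.
#' @param annotations Tibble with `cell_id` and `label` (one of the eight
#'   classes).
#' @param cost SVM regularization constant, default 1.
#' @param seed Integer seed.
#' @return An object of class `multimarker_svm`; `predict()` returns a
#'   class-call tibble.
#' @export
train_multimarker_svm <- function(cells, annotations, cost = 1, seed = 1L) {
  check_columns(annotations, c("cell_id", "label"), "annotations")
  bad <- setdiff(unique(annotations$label), IMT_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")))
  }
  counts <- table(annotations$label)
  drop <- names(counts)[counts < 3]
  if (length(drop) > 0) {
    warn(sprintf("dropping class(es) with < 3 annotations: %s",
                 paste(drop, collapse = ", ")))
    annotations <- annotations[!annotations$label %in% drop, ]
  }
  if (length(unique(annotations$label)) < 2) {
    abort("need annotations from at least 2 classes")
  }
  d <- dplyr::inner_join(annotations, cells, by = "cell_id")
  set.seed(seed)
  f <- svm_features(d, IMT_CLASS_MARKERS)
  fit <- e1071::svm(x = f, y = factor(d$label, levels = IMT_CLASSES),
                    kernel = "linear", cost = cost, scale = TRUE)
  train_acc <- mean(as.character(predict(fit, f)) == d$label)
  structure(list(fit = fit, training_accuracy = train_acc),
            class = "multimarker_svm")
}

#' @export
predict.multimarker_svm <- function(object, newdata, ...) {
  f <- svm_features(newdata, IMT_CLASS_MARKERS)
  tibble::tibble(
    cell_id = newdata$cell_id,
    class = as.character(predict(object$fit, f)),
    source = "svm",
    confidence = NA_real_
  )
}

#' Automatically generate a marker annotation set
#'
#' Builds a training set without manual annotation: for each lineage
#' marker, candidate positives are cells whose mean intensity exceeds the
#' `q`-th intensity quantile and whose nuclear area lies within QC bounds;
#' candidates without a segmented nucleus (`nucleus_count == 0`) are
#' discarded. A cell that is a candidate for several mutually exclusive
#' lineage markers is asserted only for the marker with its highest
#' intensity z-score. Negative examples per marker are the positives of
#' other exclusive markers plus an equal-size sample of sub-median
#' intensity cells.
#'
#' @param cells Cell tibble.
#' @param markers Markers to annotate (default the five single lineage
#'   markers plus AE1).
#' @param q Intensity quantile defining candidates, default 0.95.
#' @param nuclear_bounds Open interval on nuclear area, default
#'   `c(100, 3000)`.
#' @param min_candidates Markers with fewer surviving candidates are
#'   skipped with a warning (default 20).
#' @param seed Integer seed for the negative-example sample.
#' @return Tibble with `cell_id`, `marker`, `label`
#'   (`"positive"`/`"negative"`), `annotator = "automatic"`.
#' @export
auto_annotate <- function(cells,
                          markers = c("AE1", IMT_SINGLE_MARKERS),
                          q = 0.95, nuclear_bounds = c(100, 3000),
                          min_candidates = 20, seed = 1L) {
  check_columns(cells, c("cell_id", "nucleus_count", "area_nucleus"), "cells")
  set.seed(seed)
  # mutually exclusive lineage groups: a cell has one dominant lineage marker
  exclusive <- intersect(markers, c("CD4", "CD8", "FOXP3", "AE1"))

  zscores <- sapply(markers, function(mk) {
    x <- log(cells[[mean_col(mk)]] + 1e-9)
    (x - mean(x)) / sd(x)
  })
  candidates <- lapply(markers, function(mk) {
    x <- cells[[mean_col(mk)]]
    ok <- x > quantile(x, q) &
      cells$area_nucleus > nuclear_bounds[1] &
      cells$area_nucleus < nuclear_bounds[2] &
      cells$nucleus_count >= 1
    which(ok)
  })
  names(candidates) <- markers

  # resolve multi-marker candidates among exclusive markers by top z-score
  if (length(exclusive) > 1) {
    multi <- Reduce(union, candidates[exclusive])
    for (i in multi) {
      in_mk <- exclusive[vapply(exclusive, function(mk) i %in% candidates[[mk]], logical(1))]
      if (length(in_mk) > 1) {
        winner <- in_mk[which.max(zscores[i, in_mk])]
        for (mk in setdiff(in_mk, winner)) {
          candidates[[mk]] <- setdiff(candidates[[mk]], i)
        }
      }
    }
  }

  rows <- list()
  for (mk in markers) {
    pos_idx <- candidates[[mk]]
    if (length(pos_idx) < min_candidates) {
      warn(sprintf("marker %s: only %d candidate positives; marker skipped",
                   mk, length(pos_idx)))
      next
    }
    x <- cells[[mean_col(mk)]]
    other_pos <- setdiff(Reduce(union, candidates[setdiff(exclusive, mk)]), pos_idx)
    # a negative example must also look negative for this marker, or cells
    # bright for two lineages would corrupt the negative component
    other_pos <- other_pos[x[other_pos] < median(x)]
    low_pool <- setdiff(which(x < median(x)), pos_idx)
    low_idx <- sample(low_pool, min(length(pos_idx), length(low_pool)))
    neg_idx <- union(other_pos, low_idx)
    rows[[mk]] <- tibble::tibble(
      cell_id = c(cells$cell_id[pos_idx], cells$cell_id[neg_idx]),
      marker = mk,
      label = rep(c("positive", "negative"), c(length(pos_idx), length(neg_idx))),
      annotator = "automatic"
    )
  }
  if (length(rows) == 0) abort("no marker produced enough candidates")
  dplyr::bind_rows(rows)
}

# 2-d Gaussian log density with given mean and covariance.
ldmvnorm2 <- function(x, mu, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warn("singular covariance; falling back to diagonal")
    sigma <- diag(pmax(diag(sigma), 1e-8))
    ch <- chol(sigma)
  }
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Fit per-marker probabilistic positivity models
#'
#' For each annotated marker, fits class-conditional Gaussians with a
#' pooled covariance on the (log mean, log SD) intensity features of the
#' positive and negative annotations, with equal class priors. Posterior
#' positivity probabilities are produced per cell and combined into the
#' eight classes through the gating rule table by
#' [predict_probabilistic()].
#'
#' @param annotations Tibble with `cell_id`, `marker`, `label` (from
#'   [auto_annotate()] or manual annotation).
#' @param cells Cell tibble supplying the features.
#' @return An object of class `prob_model`.
#' @export
fit_probabilistic_model <- function(annotations, cells) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    abort("annotation set is empty; annotate or auto-annotate cells first")
  }
  check_columns(annotations, c("cell_id", "marker", "label"), "annotations")
  models <- list()
  for (mk in unique(annotations$marker)) {
    a <- annotations[annotations$marker == mk, ]
    d <- dplyr::inner_join(a, cells, by = "cell_id")
    if (length(unique(d$label)) < 2) {
      abort(sprintf("marker %s annotations contain a single class", mk))
    }
    f <- cbind(log(d[[mean_col(mk)]] + 1e-9), log(d[[sd_col(mk)]] + 1e-9))
    pos <- d$label == "positive"
    mu_p <- colMeans(f[pos, , drop = FALSE])
    mu_n <- colMeans(f[!pos, , drop = FALSE])
    cp <- f[pos, , drop = FALSE] - matrix(mu_p, sum(pos), 2, byrow = TRUE)
    cn <- f[!pos, , drop = FALSE] - matrix(mu_n, sum(!pos), 2, byrow = TRUE)
    sigma <- (crossprod(cp) + crossprod(cn)) / (nrow(f) - 2)
    models[[mk]] <- list(mu_pos = mu_p, mu_neg = mu_n, sigma = sigma)
  }
  structure(list(markers = models), class = "prob_model")
}

#' Predict cell classes from the probabilistic model
#'
#' Computes each marker's posterior positivity per cell, calls a marker
#' positive when its posterior exceeds 0.5, maps the pattern through the
#' gating rule table, and reports confidence as the product over the
#' classification markers of the posterior of the called state.
#' Markers without a fitted model are treated as negative with posterior 1.
#'
#' @param model A `prob_model` from [fit_probabilistic_model()].
#' @param cells Cell tibble.
#' @return Class-call tibble: `cell_id`, `class`,
#'   `source = "probabilistic"`, `confidence` in \[0, 1\].
#' @export
predict_probabilistic <- function(model, cells) {
  stopifnot(inherits(model, "prob_model"))
  n <- nrow(cells)
  post <- matrix(0, n, length(IMT_CLASS_MARKERS),
                 dimnames = list(NULL, IMT_CLASS_MARKERS))
  for (mk in IMT_CLASS_MARKERS) {
    m <- model$markers[[mk]]
    if (is.null(m)) next
    f <- cbind(log(cells[[mean_col(mk)]] + 1e-9), log(cells[[sd_col(mk)]] + 1e-9))
    lp <- ldmvnorm2(f, m$mu_pos, m$sigma)
    ln <- ldmvnorm2(f, m$mu_neg, m$sigma)
    post[, mk] <- 1 / (1 + exp(ln - lp))
  }
  pv <- tibble::as_tibble(post > 0.5)
  names(pv) <- pos_col(IMT_CLASS_MARKERS)
  pv$cell_id <- cells$cell_id
  calls <- classify_rule_table(pv)
  conf <- apply(ifelse(post > 0.5, post, 1 - post), 1, prod)
  calls$source <- "probabilistic"
  calls$confidence <- pmin(pmax(conf, 0), 1)
  calls
}

#' Stratified cross-validated classification accuracy
#'
#' Splits annotations into `k` stratified folds, retrains the requested
#' model on each training fold and measures held-out accuracy.
#'
#' @param cells Cell tibble.
#' @param annotations Annotation tibble: `cell_id`, `label` (class labels
#'   for `type = "multimarker"`, positive/negative for `type = "marker"`).
#' @param type `"multimarker"` (default) or `"marker"`.
#' @param marker Marker name when `type = "marker"`.
#' @param k Number of folds, default 3.
#' @param seed Integer seed fixing the fold split.
#' @return A list: `fold_accuracy`, `mean`, `sd`, `k`.
#' @export
crossval_accuracy <- function(cells, annotations,
                              type = c("multimarker", "marker"),
                              marker = NULL, k = 3, seed = 1L) {
  type <- match.arg(type)
  if (k < 2) abort("k must be >= 2")
  set.seed(seed)
  min_class <- min(table(annotations$label))
  if (min_class < k) {
    k <- max(2, min_class)
    warn(sprintf("smallest class has %d annotations; reducing to %d folds",
                 min_class, k))
  }
  # stratified fold assignment
  fold <- integer(nrow(annotations))
  for (lb in unique(annotations$label)) {
    idx <- sample(which(annotations$label == lb))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- annotations[fold != f, ]
    te <- annotations[fold == f, ]
    pred <- if (type == "multimarker") {
      m <- suppressWarnings(train_multimarker_svm(cells, tr, seed = seed))
      predict(m, dplyr::semi_join(cells, te, by = "cell_id"))
    } else {
      m <- train_marker_svm(cells, tr, marker = marker, seed = seed)
      d <- dplyr::semi_join(cells, te, by = "cell_id")
      tibble::tibble(cell_id = d$cell_id,
                     class = ifelse(predict(m, d), "positive", "negative"))
    }
    truth <- te$label[match(pred$cell_id, te$cell_id)]
    mean(pred$class == truth)
  }, numeric(1))
  list(fold_accuracy = acc, mean = mean(acc), sd = sd(acc), k = k)
}
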