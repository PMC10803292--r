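# Evaluation metrics and the multi-group feasibility protocol.
#
# Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2/(1/P + 1/R) per class
# over the fixed six-class order, with 0/0 cases defined as 0; macro means
# are unweighted averages. Generation quality is scored by mean squared
# error and the discrete Frechet distance between the (t, amplitude)
# polylines of real and generated leads.

#' Confusion matrix over the six classes
#'
#' Rows are true classes, columns predicted classes, in `ecg_classes()`
#' order.
#'
#' @param true,predicted Equal-length character vectors over the six
#'   classes.
#' @return 6 x 6 integer matrix.
#' @export
confusion <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("confusion: label vectors differ in length")
  classes <- ecg_classes()
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(true, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(true = tf, predicted = pf)
  matrix(as.integer(cm), 6, 6, dimnames = list(true = classes,
                                               predicted = classes))
}

#' Per-class and macro precision, recall and F1 from a confusion matrix
#'
#' For each class c: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2/(1/precision + 1/recall). A 0/0 ratio is defined as 0 and flagged
#' in the `undefined` column. Macro values are unweighted means over the six
#' classes.
#'
#' @param cm 6 x 6 confusion matrix from [confusion()].
#' @return An object of class `class_metrics`: list with `per_class`
#'   (data.frame: class, precision, recall, f1, undefined), and
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
metrics_from_confusion <- function(cm) {
  if (!is.matrix(cm) || !identical(dim(cm), c(6L, 6L)) || any(cm < 0))
    stop("cm must be a 6 x 6 nonnegative count matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  undefined <- (tp + fp == 0) | (tp + fn == 0) | (precision + recall == 0)
  per_class <- data.frame(class = ecg_classes(), precision = precision,
                          recall = recall, f1 = f1, undefined = undefined,
                          row.names = NULL, stringsAsFactors = FALSE)
  out <- list(per_class = per_class,
              macro_precision = mean(precision),
              macro_recall = mean(recall),
              macro_f1 = mean(f1))
  class(out) <- "class_metrics"
  out
}

#' @export
print.class_metrics <- function(x, ...) {
  print(x$per_class, digits = 3)
  cat(sprintf("macro: precision %.3f  recall %.3f  f1 %.3f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Discrete Frechet distance between two signals
#'
#' The signals are treated as planar polylines (t, amplitude) with t in
#' sample-index units, and the standard O(n m) dynamic programme is applied.
#'
#' @param a,b Numeric vectors (signals) or two-column coordinate matrices.
#' @return Scalar distance.
#' @export
frechet_distance <- function(a, b) {
  as_poly <- function(v) {
    if (is.matrix(v)) {
      if (ncol(v) != 2) stop("polyline matrices must have 2 columns")
      v
    } else cbind(seq_along(v) - 1, as.numeric(v))
  }
  .frechet_dp(as_poly(a), as_poly(b))
}

#' Generation-quality scores for one real/generated lead pair
#'
#' @param real,generated Equal-length numeric vectors (mV).
#' @return List with `mse` (mean squared sample-wise difference) and `fd`
#'   (discrete Frechet distance on the (t, amplitude) polylines).
#' @export
generation_quality <- function(real, generated) {
  if (length(real) != length(generated))
    stop("generation_quality: signal lengths differ")
  list(mse = mean((real - generated)^2),
       fd = frechet_distance(real, generated))
}

# ---- the multi-group comparison protocol -----------------------------------

#' Run the lead-group classification feasibility protocol
#'
#' For each requested lead group, assembles that group's channel set for
#' every segment (via [assemble_group()]), trains a fresh classifier with an
#' identical configuration and seed (only the input channel count differs
#' between 12-lead and single-lead groups), evaluates it on a
#' patient-disjoint test split, and reports per-class precision/recall/F1
#' plus the confusion matrix.
#'
#' @param groups Character vector of [lead_groups()] ids.
#' @param classifier_config A [classifier_config()]; its seed also fixes the
#'   train/test split.
#' @param cohort List of `ecg_record` objects (will be filtered through
#'   [apply_exclusions()] and segmented).
#' @param gan_models Named list of trained generators (required for groups
#'   containing GAN leads).
#' @param window_s Segmentation window, seconds.
#' @param test_frac Patient fraction held out for the final evaluation.
#' @param use_dropout Dropout mode during generation.
#' @param verbose Print progress.
#' @return List with `report` (data.frame: group, class, precision, recall,
#'   f1), `metrics` (named list of `class_metrics`), `confusions` (named
#'   list of matrices), `macro` (data.frame: group, macro_precision,
#'   macro_recall, macro_f1) and `exclusions` (the exclusion report).
#' @export
run_protocol <- function(groups, classifier_config, cohort,
                         gan_models = NULL, window_s = 2.5,
                         test_frac = 0.25, use_dropout = FALSE,
                         verbose = FALSE) {
  groups <- match.arg(groups, lead_groups(), several.ok = TRUE)
  filt <- apply_exclusions(cohort_manifest(cohort))
  keep_ids <- filt$manifest$record_id
  cohort <- Filter(function(r) r$record_id %in% keep_ids, cohort)
  sc <- segment_cohort(cohort, window_s)
  n_seg <- nrow(sc$meta)
  L <- classifier_config$input_len
  set.seed(classifier_config$seed)
  split <- split_by_patient(sc$meta$patient_id, test_frac)
  gan_groups <- setdiff(groups, c("real12", "realI"))
  gan_cache <- NULL
  if (length(gan_groups)) {
    if (is.null(gan_models))
      stop("gan_models required for group(s): ",
           paste(gan_groups, collapse = ", "))
    xs <- t(vapply(sc$segments, function(s) s$signals["I", ], numeric(L)))
    need <- unique(unlist(lapply(gan_groups, function(g) switch(g,
      gen12 = setdiff(ecg_leads(), "I"),
      einthoven_II = c("II", paste0("V", 1:6)),
      einthoven_III = c("III", paste0("V", 1:6)),
      einthoven_II_III = c("II", "III", paste0("V", 1:6))))))
    missing <- setdiff(need, names(gan_models))
    if (length(missing))
      stop("missing GAN model(s) for lead(s): ",
           paste(missing, collapse = ", "))
    gan_cache <- lapply(setNames(need, need), function(lead) {
      g <- generator_forward(gan_models[[lead]], xs, use_dropout = use_dropout)
      matrix(g[, 1L, ], nrow = n_seg)
    })
  }
  metrics <- list(); confusions <- list(); report <- list(); macro <- list()
  for (g in groups) {
    if (verbose) message("protocol group: ", g)
    ch <- if (g == "realI") 1L else 12L
    X <- array(0, c(n_seg, ch, L))
    for (i in seq_len(n_seg)) {
      gan_leads <- if (is.null(gan_cache)) list()
                   else lapply(gan_cache, function(m) m[i, ])
      X[i, , ] <- assemble_group(g, sc$segments[[i]]$signals, gan_leads)
    }
    cfg <- classifier_config
    cfg$channels <- ch
    tr <- split == "train"
    fit <- train_classifier(cfg, X[tr, , , drop = FALSE],
                            sc$meta$label[tr], sc$meta$patient_id[tr])
    pred <- predict_labels(fit$model, X[!tr, , , drop = FALSE])
    cm <- confusion(sc$meta$label[!tr], pred)
    mt <- metrics_from_confusion(cm)
    confusions[[g]] <- cm
    metrics[[g]] <- mt
    report[[g]] <- cbind(group = g, mt$per_class[c("class", "precision",
                                                   "recall", "f1")])
    macro[[g]] <- data.frame(group = g,
                             macro_precision = mt$macro_precision,
                             macro_recall = mt$macro_recall,
                             macro_f1 = mt$macro_f1)
  }
  list(report = do.call(rbind, c(report, make.row.names = FALSE)),
       metrics = metrics, confusions = confusions,
       macro = do.call(rbind, c(macro, make.row.names = FALSE)),
       exclusions = filt$report)
}
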