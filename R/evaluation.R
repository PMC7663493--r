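#' Temporally match predicted events to ground-truth events
#'
#' Each truth event is matched to the predicted event (same body) with
#' maximal temporal overlap, assigned greedily in descending overlap so each
#' prediction matches at most once. Truth events with no overlapping
#' prediction may still match an unused prediction whose midpoint lies
#' within `tolerance_s`; otherwise they are scored `no_detection` (missed).
#' Predictions left unmatched are returned separately as spurious -- they
#' have no truth counterpart and stay out of the confusion matrix, whose
#' columns are truth events only.
#'
#' @param predicted,truth [event_records] tables.
#' @param tolerance_s Midpoint tolerance for zero-overlap matches (default 0.5).
#' @return List of class `event_matching`: `matched` (one row per truth
#'   event: `truth_event_id, body_id, truth_label, pred_label,
#'   pred_event_id, overlap_s`) and `spurious` (unmatched predictions).
#' @export
match_events <- function(predicted, truth, tolerance_s = 0.5) {
  predicted <- event_records(predicted)
  truth <- event_records(truth)
  nt <- nrow(truth); np <- nrow(predicted)
  pred_label <- rep("no_detection", nt)
  pred_id <- rep(NA_integer_, nt)
  overlap_s <- rep(0, nt)
  pred_used <- rep(FALSE, np)
  truth_done <- rep(FALSE, nt)

  if (nt && np) {
    # pass 1: positive overlap, greedy by descending overlap
    cand <- expand.grid(ti = seq_len(nt), pi = seq_len(np))
    cand <- cand[truth$body_id[cand$ti] == predicted$body_id[cand$pi], , drop = FALSE]
    cand$ov <- pmax(0, pmin(truth$end_s[cand$ti], predicted$end_s[cand$pi]) -
                       pmax(truth$start_s[cand$ti], predicted$start_s[cand$pi]))
    pos <- cand[cand$ov > 0, , drop = FALSE]
    pos <- pos[order(-pos$ov, truth$start_s[pos$ti], predicted$start_s[pos$pi]), ,
               drop = FALSE]
    for (k in seq_len(nrow(pos))) {
      ti <- pos$ti[k]; pi <- pos$pi[k]
      if (truth_done[ti] || pred_used[pi]) next
      truth_done[ti] <- TRUE
      pred_used[pi] <- TRUE
      pred_label[ti] <- predicted$label[pi]
      pred_id[ti] <- predicted$event_id[pi]
      overlap_s[ti] <- pos$ov[k]
    }
    # pass 2: no overlap -- nearest midpoints within tolerance
    rest <- cand[!truth_done[cand$ti] & !pred_used[cand$pi], , drop = FALSE]
    if (nrow(rest)) {
      tm <- (truth$start_s + truth$end_s) / 2
      pm <- (predicted$start_s + predicted$end_s) / 2
      rest$gap <- abs(tm[rest$ti] - pm[rest$pi])
      rest <- rest[rest$gap <= tolerance_s, , drop = FALSE]
      rest <- rest[order(rest$gap), , drop = FALSE]
      for (k in seq_len(nrow(rest))) {
        ti <- rest$ti[k]; pi <- rest$pi[k]
        if (truth_done[ti] || pred_used[pi]) next
        truth_done[ti] <- TRUE
        pred_used[pi] <- TRUE
        pred_label[ti] <- predicted$label[pi]
        pred_id[ti] <- predicted$event_id[pi]
      }
    }
  }
  matched <- data.frame(
    truth_event_id = truth$event_id, body_id = truth$body_id,
    truth_label = truth$label, pred_label = pred_label,
    pred_event_id = pred_id, overlap_s = overlap_s, stringsAsFactors = FALSE
  )
  structure(list(matched = matched,
                 spurious = predicted[!pred_used, , drop = FALSE]),
            class = "event_matching")
}

#' @export
print.event_matching <- function(x, ...) {
  cat(sprintf("<event_matching> %d truth events (%d missed), %d spurious predictions\n",
              nrow(x$matched), sum(x$matched$pred_label == "no_detection"),
              nrow(x$spurious)))
  invisible(x)
}

EVAL_CLASSES_7 <- c("mouth_nose", "right_eye", "left_eye", "right_ear",
                    "left_ear", "low_risk", "occlusion")

#' Build a confusion matrix from matched event labels
#'
#' Orientation: columns are the truth classes, rows the classifier classes.
#' The classifier never emits an occlusion label, so its `occlusion` row
#' holds the events for which it emitted nothing (`no_detection`): a missed
#' contact event lands in (occlusion row, its truth column), and a truth
#' occlusion event that the classifier -- correctly -- did not report lands
#' on the (occlusion, occlusion) diagonal.
#'
#' @param matched An `event_matching` (or its `matched` data frame).
#' @param classes Class ordering (default the 7-class layout).
#' @return Integer matrix of class `confusion_matrix`, rows = classifier,
#'   columns = truth.
#' @export
build_confusion <- function(matched, classes = EVAL_CLASSES_7) {
  if (inherits(matched, "event_matching")) matched <- matched$matched
  truth <- matched$truth_label
  pred <- matched$pred_label
  pred[pred == "no_detection"] <- "occlusion"
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) {
    stop("label(s) outside the class vocabulary: ", paste(bad, collapse = ", "))
  }
  cm <- table(factor(pred, levels = classes), factor(truth, levels = classes))
  confusion_matrix(unclass(matrix(as.integer(cm), nrow = length(classes),
                                  dimnames = list(classifier = classes,
                                                  truth = classes))))
}

#' Construct/validate a confusion matrix object
#'
#' @param m Square non-negative integer matrix with identical row and column
#'   names; rows = classifier classes, columns = truth classes.
#' @return `m` with class `confusion_matrix`.
#' @export
confusion_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("confusion matrix needs identical row (classifier) and column (truth) names")
  }
  if (any(m < 0L)) stop("confusion matrix counts must be non-negative")
  names(dimnames(m)) <- c("classifier", "truth")
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d events (rows = classifier, columns = truth)\n",
              nrow(x), sum(x)))
  y <- x; class(y) <- NULL
  print(y)
  invisible(x)
}

#' Per-class reliability metrics
#'
#' For class i, TP is the diagonal cell, FP the rest of its classifier row,
#' FN the rest of its truth column and TN the remainder. The derived metrics
#' are accuracy = (TP+TN)/(TP+TN+FP+FN) x 100, precision = TP/(TP+FP) x 100
#' and sensitivity = TP/(TP+FN) x 100; 0/0 cases are reported as `NaN` and
#' flagged in the `undefined` column rather than coerced to 0 or 100.
#'
#' @param cm A [confusion_matrix].
#' @return Data frame with one row per class: `class, tp, tn, fp, fn,
#'   accuracy_pct, precision_pct, sensitivity_pct, undefined`.
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  tn <- total - tp - fp - fn
  ratio <- function(num, den) ifelse(den > 0, 100 * num / den, NaN)
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  undef <- paste0(ifelse(is.nan(prec), "precision", ""),
                  ifelse(is.nan(prec) & is.nan(sens), ",", ""),
                  ifelse(is.nan(sens), "sensitivity", ""))
  data.frame(class = rownames(cm), tp = as.integer(tp), tn = as.integer(tn),
             fp = as.integer(fp), fn = as.integer(fn),
             accuracy_pct = 100 * (tp + tn) / total,
             precision_pct = prec, sensitivity_pct = sens,
             undefined = undef, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A [confusion_matrix].
#' @return Percentage: 100 x trace / total.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Cohen's Kappa with Landis-Koch band
#'
#' Chance-corrected agreement between classifier and ground truth:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o =
#' trace/total and chance agreement p_e = sum of (row margin x column
#' margin) / total^2. The qualitative Landis-Koch band of the value is
#' attached as a label.
#'
#' @param cm A [confusion_matrix].
#' @return List of class `cohens_kappa`: `kappa`, `p_o`, `p_e`, `band`.
#'   `kappa` is `NaN` (flagged via `band = "undefined"`) when p_e = 1.
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (p_e >= 1) NaN else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e,
                 band = landis_koch(kappa)), class = "cohens_kappa")
}

#' @export
print.cohens_kappa <- function(x, ...) {
  cat(sprintf("Cohen's Kappa = %.3f (p_o = %.4f, p_e = %.4f): %s agreement\n",
              x$kappa, x$p_o, x$p_e, x$band))
  invisible(x)
}

#' Landis-Koch qualitative band for a kappa value
#'
#' @param kappa Numeric kappa value(s).
#' @return Character: `poor` (< 0), `slight` (0--0.20), `fair` (0.21--0.40),
#'   `moderate` (0.41--0.60), `substantial` (0.61--0.80), `almost_perfect`
#'   (0.81--1), or `undefined` for `NaN`.
#' @export
landis_koch <- function(kappa) {
  ifelse(is.nan(kappa), "undefined",
    ifelse(kappa < 0, "poor",
      as.character(cut(kappa, c(-1e-9, 0.2, 0.4, 0.6, 0.8, 1),
                       labels = c("slight", "fair", "moderate", "substantial",
                                  "almost_perfect")))))
}

#' Cluster confusion-matrix classes
#'
#' Aggregates fine classes into coarse ones by summing cells; the event
#' total is preserved. The default clustering separates risk contacts
#' (mouth-nose and both eyes, i.e. mucous-membrane exposure) from no-risk
#' contacts (ears and the low-risk area), keeping occlusions apart.
#'
#' @param cm A [confusion_matrix] (fine classes).
#' @param clustering Named character vector mapping every fine class to its
#'   coarse class.
#' @return A coarse [confusion_matrix].
#' @export
cluster_matrix <- function(cm, clustering = default_clustering()) {
  fine <- rownames(cm)
  if (!all(fine %in% names(clustering))) {
    stop("clustering does not cover class(es): ",
         paste(setdiff(fine, names(clustering)), collapse = ", "))
  }
  coarse <- unique(unname(clustering[fine]))
  out <- matrix(0L, length(coarse), length(coarse),
                dimnames = list(classifier = coarse, truth = coarse))
  for (i in fine) for (j in fine) {
    out[clustering[[i]], clustering[[j]]] <- out[clustering[[i]], clustering[[j]]] + cm[i, j]
  }
  confusion_matrix(out)
}

#' @rdname cluster_matrix
#' @export
default_clustering <- function() {
  c(mouth_nose = "risk_contacts", right_eye = "risk_contacts",
    left_eye = "risk_contacts", right_ear = "no_risk_contacts",
    left_ear = "no_risk_contacts", low_risk = "no_risk_contacts",
    occlusion = "occlusion")
}

#' Read / write a confusion matrix CSV
#'
#' Layout follows the evaluation orientation: truth classes as column
#' headers (first header field `classifier`), classifier classes as row
#' labels.
#'
#' @param path CSV path.
#' @return `read_confusion()`: a [confusion_matrix].
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  confusion_matrix(m)
}

#' @rdname read_confusion
#' @param cm A [confusion_matrix].
#' @export
write_confusion <- function(cm, path) {
  lines <- c(paste(c("classifier", colnames(cm)), collapse = ","),
             vapply(seq_len(nrow(cm)), function(i) {
               paste(c(rownames(cm)[i], cm[i, ]), collapse = ",")
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Event counts from a published 575-event laboratory validation
#'
#' The package ships, as reference data, the 7-class event-level confusion
#' matrix observed when the detector was validated against a human observer
#' annotating RGB recordings of scripted face-touch sessions: 575 events
#' across the six contact classes plus face occlusions.
#'
#' @return The 7x7 [confusion_matrix] (rows = classifier, columns = truth).
#' @export
#' @examples
#' cm <- validation_confusion()
#' overall_accuracy(cm)
validation_confusion <- function() {
  read_confusion(system.file("extdata", "validation_confusion_7class.csv",
                             package = "facetouch", mustWork = TRUE))
}

#' One-call event-level evaluation
#'
#' Matches predictions to truth, builds the 7-class confusion matrix and
#' computes per-class metrics, overall accuracy and Cohen's Kappa;
#' optionally also the clustered coarse matrix and its statistics.
#'
#' @inheritParams match_events
#' @param cluster Also compute the risk/no-risk clustered results.
#' @return List of class `evaluation_result` with `matching`, `matrix`,
#'   `metrics`, `overall_accuracy`, `kappa`, and (if `cluster`)
#'   `matrix_clustered`, `metrics_clustered`, `overall_accuracy_clustered`,
#'   `kappa_clustered`.
#' @export
evaluate_events <- function(predicted, truth, tolerance_s = 0.5, cluster = TRUE) {
  matching <- match_events(predicted, truth, tolerance_s)
  cm <- build_confusion(matching)
  out <- list(matching = matching, matrix = cm,
              metrics = per_class_metrics(cm),
              overall_accuracy = overall_accuracy(cm),
              kappa = cohens_kappa(cm))
  if (cluster) {
    cc <- cluster_matrix(cm)
    out$matrix_clustered <- cc
    out$metrics_clustered <- per_class_metrics(cc)
    out$overall_accuracy_clustered <- overall_accuracy(cc)
    out$kappa_clustered <- cohens_kappa(cc)
  }
  structure(out, class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %d truth events | overall accuracy %.2f%% | kappa %.3f (%s)\n",
              sum(x$matrix), x$overall_accuracy, x$kappa$kappa, x$kappa$band))
  if (!is.null(x$matrix_clustered)) {
    cat(sprintf("  clustered (risk/no-risk/occlusion): accuracy %.2f%% | kappa %.3f (%s)\n",
                x$overall_accuracy_clustered, x$kappa_clustered$kappa,
                x$kappa_clustered$band))
  }
  invisible(x)
}
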