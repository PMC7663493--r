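ev_tab <- function(labels, starts, ends = starts + 0.5, body = 0L) {
  event_records(data.frame(event_id = seq_along(labels), body_id = body,
                           start_s = starts, end_s = ends, label = labels,
                           n_frames = 15L))
}

test_that("identical event lists match perfectly with no spurious predictions", {
  tr <- ev_tab(c("mouth_nose", "left_eye", "low_risk"), c(1, 3, 5))
  m <- match_events(tr, tr)
  expect_equal(m$matched$pred_label, m$matched$truth_label)
  expect_equal(nrow(m$spurious), 0L)
})

test_that("truth events without predictions in tolerance are missed (no_detection)", {
  tr <- ev_tab(c("mouth_nose", "right_ear"), c(1, 10))
  pr <- ev_tab("mouth_nose", 1)
  m <- match_events(pr, tr, tolerance_s = 0.5)
  expect_equal(m$matched$pred_label, c("mouth_nose", "no_detection"))
  # nearby-but-disjoint prediction within tolerance still matches
  pr2 <- ev_tab("right_ear", 10.6)
  m2 <- match_events(pr2, ev_tab("right_ear", 10), tolerance_s = 0.7)
  expect_equal(m2$matched$pred_label, "right_ear")
  m3 <- match_events(pr2, ev_tab("right_ear", 10), tolerance_s = 0.2)
  expect_equal(m3$matched$pred_label, "no_detection")
})

test_that("greedy matching maximizes overlap and flags the loser as spurious", {
  tr <- ev_tab("mouth_nose", 1, 2)
  # two predictions over one truth event: 0.8 s and 0.3 s of overlap
  pr <- event_records(data.frame(event_id = 1:2, body_id = 0L,
                                 start_s = c(1.0, 1.6), end_s = c(1.8, 1.9),
                                 label = c("mouth_nose", "left_eye"),
                                 n_frames = 10L))
  m <- match_events(pr, tr)
  expect_equal(m$matched$pred_label, "mouth_nose")
  expect_equal(m$matched$pred_event_id, 1L)
  expect_equal(m$spurious$label, "left_eye")

  # 3-event toy case against brute-force assignment maximizing total overlap
  tr3 <- ev_tab(c("mouth_nose", "left_eye", "low_risk"), c(0, 1, 2),
                c(0.9, 1.9, 2.9))
  pr3 <- event_records(data.frame(
    event_id = 1:3, body_id = 0L,
    start_s = c(0.1, 0.95, 2.05), end_s = c(0.8, 1.8, 2.8),
    label = c("mouth_nose", "left_eye", "mouth_nose"), n_frames = 10L))
  # explicit overlap matrix
  O <- outer(1:3, 1:3, Vectorize(function(i, j) {
    max(0, min(tr3$end_s[i], pr3$end_s[j]) - max(tr3$start_s[i], pr3$start_s[j]))
  }))
  best <- -Inf; best_perm <- NULL
  for (p in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    tot <- sum(O[cbind(1:3, p)])
    if (tot > best) { best <- tot; best_perm <- p }
  }
  m3 <- match_events(pr3, tr3)
  expect_equal(m3$matched$pred_event_id, pr3$event_id[best_perm])
  # matching respects body identity
  pr_other_body <- ev_tab("mouth_nose", 1, 2, body = 5L)
  mb <- match_events(pr_other_body, tr)
  expect_equal(mb$matched$pred_label, "no_detection")
})

test_that("confusion matrix uses truth columns, classifier rows and occlusion semantics", {
  tr <- ev_tab(c("mouth_nose", "occlusion", "occlusion", "low_risk"),
               c(1, 3, 5, 7))
  # classifier: correct mouth_nose; silent on first occlusion (correct);
  # low_risk on the second occlusion (false contact); misses the low_risk
  pr <- ev_tab(c("mouth_nose", "low_risk"), c(1, 5))
  cm <- build_confusion(match_events(pr, tr))
  expect_equal(sum(cm), 4L)
  expect_equal(cm["mouth_nose", "mouth_nose"], 1L)
  expect_equal(cm["occlusion", "occlusion"], 1L)   # undetected occlusion = correct
  expect_equal(cm["low_risk", "occlusion"], 1L)    # occlusion called a contact
  expect_equal(cm["occlusion", "low_risk"], 1L)    # missed contact event
  expect_identical(names(dimnames(cm)), c("classifier", "truth"))

  perfect <- build_confusion(match_events(ev_tab(contact_areas(), 1:6),
                                          ev_tab(contact_areas(), 1:6)))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0L))
  expect_error(build_confusion(data.frame(truth_label = "forehead",
                                          pred_label = "mouth_nose")),
               "vocabulary")
})

test_that("per-class base metrics satisfy the margin identities", {
  cm <- validation_confusion()
  m <- per_class_metrics(cm)
  mn <- m[m$class == "mouth_nose", ]
  expect_equal(mn$tp, 74L)
  expect_equal(mn$fp, 22L)
  expect_equal(mn$fn, 19L)
  expect_equal(mn$tn, 460L)
  expect_equal(mn$precision_pct, 100 * 74 / 96, tolerance = 1e-9)
  expect_equal(mn$sensitivity_pct, 100 * 74 / 93, tolerance = 1e-9)
  expect_equal(mn$accuracy_pct, 100 * 534 / 575, tolerance = 1e-9)
  expect_equal(round(c(mn$precision_pct, mn$sensitivity_pct, mn$accuracy_pct), 2),
               c(77.08, 79.57, 92.87))
  # identities on random matrices
  for (seed in 1:20) {
    rcm <- random_confusion(5, seed)
    rm <- per_class_metrics(rcm)
    expect_equal(sum(rm$tp), sum(diag(rcm)))
    expect_equal(rm$tp + rm$fp, unname(rowSums(rcm)))
    expect_equal(rm$tp + rm$fn, unname(colSums(rcm)))
    expect_equal(rm$tp + rm$tn + rm$fp + rm$fn, rep(sum(rcm), 5))
  }
  # diagonal matrix: all metrics 100%
  d <- confusion_matrix(matrix(diag(3) * 7, 3,
                               dimnames = list(letters[1:3], letters[1:3])))
  md <- per_class_metrics(d)
  expect_true(all(md$accuracy_pct == 100 & md$precision_pct == 100 &
                    md$sensitivity_pct == 100))
  # empty row and column -> undefined, flagged
  z <- matrix(c(5L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mz <- per_class_metrics(confusion_matrix(z))
  expect_true(is.nan(mz$precision_pct[2]))
  expect_true(is.nan(mz$sensitivity_pct[2]))
  expect_match(mz$undefined[2], "precision")
  expect_match(mz$undefined[2], "sensitivity")
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(validation_confusion()), 100 * 459 / 575)
  d <- confusion_matrix(matrix(diag(4L) * 3L, 4,
                               dimnames = list(letters[1:4], letters[1:4])))
  expect_equal(overall_accuracy(d), 100)
})

test_that("Cohen's kappa matches theory and an independent implementation", {
  # balanced chance agreement -> kappa 0
  even <- confusion_matrix(matrix(c(25L, 25L, 25L, 25L), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(cohens_kappa(even)$kappa, 0)
  # independent margins (outer product) -> exactly 0
  ab <- outer(c(3L, 7L, 2L), c(4L, 1L, 5L))
  dimnames(ab) <- list(letters[1:3], letters[1:3])
  expect_equal(cohens_kappa(confusion_matrix(ab))$kappa, 0, tolerance = 1e-12)
  # kappa = 1 iff all mass on the diagonal (>= 2 nonempty classes)
  d <- confusion_matrix(matrix(diag(3L) * 5L, 3,
                               dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(cohens_kappa(d)$kappa, 1)
  offd <- d; offd[1, 2] <- 1L
  expect_lt(cohens_kappa(confusion_matrix(offd))$kappa, 1)
  # degenerate: all mass in one cell -> p_e = 1, undefined
  one <- matrix(c(9L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  kd <- cohens_kappa(confusion_matrix(one))
  expect_true(is.nan(kd$kappa))
  expect_equal(kd$band, "undefined")
  # cross-check against e1071 on 100 random matrices
  skip_if_not_installed("e1071")
  for (seed in 1:100) {
    rcm <- random_confusion(4, seed, lambda = 6)
    expect_equal(cohens_kappa(rcm)$kappa,
                 e1071::classAgreement(unclass(rcm))$kappa, tolerance = 1e-10)
  }
})

test_that("Landis-Koch bands are assigned correctly", {
  expect_equal(landis_koch(c(-0.2, 0.1, 0.3, 0.5, 0.764, 0.851, 1)),
               c("poor", "slight", "fair", "moderate", "substantial",
                 "almost_perfect", "almost_perfect"))
})

test_that("class clustering aggregates cells and preserves totals", {
  cm <- validation_confusion()
  cc <- cluster_matrix(cm)
  expect_equal(unname(unclass(cc)),
               matrix(c(234L, 10L, 0L, 17L, 224L, 20L, 0L, 5L, 65L), 3))
  expect_equal(sum(cc), sum(cm))
  expect_equal(rownames(cc), c("risk_contacts", "no_risk_contacts", "occlusion"))

  ident <- stats::setNames(rownames(cm), rownames(cm))
  expect_equal(unclass(cluster_matrix(cm, ident)), unclass(cm))

  allone <- stats::setNames(rep("all", 7), rownames(cm))
  c1 <- cluster_matrix(cm, allone)
  expect_equal(dim(c1), c(1L, 1L))
  expect_equal(sum(c1), 575L)

  expect_error(cluster_matrix(cm, allone[-1]), "does not cover")

  for (seed in 1:10) {
    rcm <- random_confusion(6, seed)
    map <- stats::setNames(sample(c("x", "y"), 6, TRUE), rownames(rcm))
    expect_equal(sum(cluster_matrix(rcm, map)), sum(rcm))
  }
})

test_that("confusion CSV round-trips in the truth-columns orientation", {
  cm <- validation_confusion()
  p <- tempfile(fileext = ".csv")
  write_confusion(cm, p)
  expect_equal(readLines(p)[1],
               "classifier,mouth_nose,right_eye,left_eye,right_ear,left_ear,low_risk,occlusion")
  expect_equal(unclass(read_confusion(p)), unclass(cm))
})
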