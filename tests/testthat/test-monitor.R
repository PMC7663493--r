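lab_row <- function(t, state, area = NA_character_, body = 0L) {
  out <- data.frame(timestamp_s = t, body_id = body, state = state,
                    area = area, hand = NA_character_, degraded = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("frame_labels", "data.frame")
  out
}

lab_seq <- function(areas, body = 0L) {
  # areas: character vector, NA = no_contact
  if (!length(areas)) {
    out <- data.frame(timestamp_s = numeric(), body_id = integer(),
                      state = character(), area = character(),
                      hand = character(), degraded = logical())
    class(out) <- c("frame_labels", "data.frame")
    return(out)
  }
  do.call(rbind, lapply(seq_along(areas), function(i) {
    lab_row(i / 30, if (is.na(areas[i])) "no_contact" else "contact",
            areas[i], body)
  }))
}

test_that("monitor_step signals exactly on state or area transitions", {
  n <- lab_row(1 / 30, "no_contact")
  c1 <- lab_row(2 / 30, "contact", "mouth_nose")
  c2 <- lab_row(3 / 30, "contact", "mouth_nose")
  c3 <- lab_row(4 / 30, "contact", "left_eye")
  n2 <- lab_row(5 / 30, "no_contact")

  expect_equal(monitor_step(n, c1)$signal, "contact_started")
  expect_equal(monitor_step(n, c1)$area, "mouth_nose")
  expect_null(monitor_step(c1, c2))
  s <- monitor_step(c2, c3)
  expect_equal(s$signal, "area_changed")
  expect_equal(s$area, "left_eye")
  expect_equal(monitor_step(c3, n2)$signal, "contact_ended")
  expect_null(monitor_step(n, lab_row(2 / 30, "no_contact")))
  # stream start: a contact first frame opens an event
  expect_equal(monitor_step(NULL, c1)$signal, "contact_started")
  expect_error(monitor_step(c1, n), "increase")
})

test_that("group_events run-length-encodes contact runs", {
  labs <- lab_seq(c(NA, NA, "mouth_nose", "mouth_nose", "left_eye", NA))
  ev <- group_events(labs)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$label, c("mouth_nose", "left_eye"))
  expect_equal(ev$n_frames, c(2L, 1L))
  expect_equal(ev$start_s, c(3 / 30, 5 / 30))
  expect_equal(ev$end_s, c(4 / 30, 5 / 30))

  expect_equal(nrow(group_events(lab_seq(rep(NA_character_, 6)))), 0L)
  one <- group_events(lab_seq(c(NA, "right_ear", NA)))
  expect_equal(one$start_s, one$end_s)
  expect_equal(one$n_frames, 1L)
})

test_that("group_events matches an independent RLE oracle on random sequences", {
  for (seed in 1:25) {
    labs <- random_labels(80, seed, bodies = 2L)
    ev <- group_events(labs)
    # oracle: explicit scan per body
    expected <- 0L
    for (b in 0:1) {
      sub <- labs[labs$body_id == b, ]
      key <- ifelse(sub$state == "contact", sub$area, NA)
      runs <- rle(paste(key))
      expected <- expected + sum(runs$values != "NA")
    }
    expect_equal(nrow(ev), expected)
    expect_true(all(ev$n_frames >= 1L))
    # non-overlap per body, time-ordered
    for (b in unique(ev$body_id)) {
      e <- ev[ev$body_id == b, ]
      if (nrow(e) > 1L) expect_true(all(e$start_s[-1] > e$end_s[-nrow(e)]))
    }
  }
})

test_that("streaming signals and batch grouping agree on event boundaries", {
  for (seed in 26:40) {
    labs <- random_labels(60, seed)
    sig <- monitor_signals(labs)
    ev <- group_events(labs)
    starts <- sig$timestamp_s[sig$signal %in% c("contact_started", "area_changed")]
    expect_equal(sort(starts), sort(ev$start_s))
    areas <- sig$area[sig$signal %in% c("contact_started", "area_changed")]
    expect_equal(areas[order(starts)], ev$label[order(ev$start_s)])
  }
})

test_that("events expand back to the contact frames that formed them", {
  labs <- random_labels(120, 99)
  ev <- group_events(labs)
  expanded <- rep(NA_character_, nrow(labs))
  for (i in seq_len(nrow(ev))) {
    in_ev <- labs$timestamp_s >= ev$start_s[i] & labs$timestamp_s <= ev$end_s[i]
    expanded[in_ev] <- ev$label[i]
  }
  expect_identical(expanded, ifelse(labs$state == "contact", labs$area,
                                    NA_character_))
  expect_equal(sum(ev$n_frames), sum(labs$state == "contact"))
})

test_that("optional smoothing merges short gaps and drops short events", {
  labs <- lab_seq(c("mouth_nose", "mouth_nose", NA, "mouth_nose", NA, "left_eye"))
  expect_equal(nrow(group_events(labs)), 3L)
  merged <- group_events(labs, merge_gap_s = 2 / 30)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$n_frames[1], 3L)
  expect_equal(nrow(group_events(labs, min_frames = 2L)), 1L)
})

test_that("check_distance alerts on pelvis pairs below 1 m only", {
  two_at <- function(sep) {
    rbind(make_head_frame(cc = c(-sep / 2, 0, 2000), body = 0L),
          make_head_frame(cc = c(sep / 2, 0, 2000), body = 1L))
  }
  expect_equal(nrow(check_distance(make_head_frame())), 0L)     # single body
  expect_equal(nrow(check_distance(two_at(2000))), 0L)
  expect_equal(nrow(check_distance(two_at(1000))), 0L)          # boundary: compliant
  a <- check_distance(two_at(500))
  expect_equal(nrow(a), 1L)
  expect_equal(a$distance_mm, 500)
  expect_lt(a$distance_mm, a$threshold_mm)

  # three bodies pairwise 800 mm -> all three pairs alert
  tri <- do.call(rbind, lapply(0:2, function(b) {
    ang <- 2 * pi * b / 3
    make_head_frame(cc = 800 / sqrt(3) * c(cos(ang), 0, sin(ang)) + c(0, 0, 3000),
                    body = b)
  }))
  a3 <- check_distance(tri)
  expect_equal(nrow(a3), 3L)
  expect_equal(a3$distance_mm, rep(800, 3), tolerance = 1e-9)

  # invariance under body relabeling
  swapped <- tri
  swapped$body_id <- c(2L, 1L, 0L)[swapped$body_id + 1L]
  a3s <- check_distance(swapped)
  expect_equal(sort(a3s$distance_mm), sort(a3$distance_mm))
  expect_equal(nrow(a3s), 3L)

  # a body without pelvis is skipped and tallied
  nopelvis <- rbind(make_head_frame(cc = c(0, 0, 2000), body = 0L),
                    make_head_frame(cc = c(300, 0, 2000), body = 1L,
                                    drop = "pelvis"))
  an <- check_distance(nopelvis)
  expect_equal(nrow(an), 0L)
  expect_equal(attr(an, "n_skipped"), 1L)
})

test_that("reports count and time events per area and add over streams", {
  labs <- lab_seq(c(NA, NA, "mouth_nose", "mouth_nose", "left_eye", NA))
  rep1 <- build_report(labs, group_events(labs))
  a <- rep1$areas
  expect_equal(a$count[a$area == "mouth_nose"], 1L)
  expect_equal(a$total_duration_s[a$area == "mouth_nose"], 2 / 30)
  expect_equal(a$count[a$area == "left_eye"], 1L)
  expect_equal(a$total_duration_s[a$area == "left_eye"], 1 / 30)
  expect_equal(sum(a$count), rep1$events_total)
  expect_equal(sum(a$count), nrow(rep1$events))
  expect_equal(sum(a$total_duration_s),
               sum(rep1$events$end_s - rep1$events$start_s) +
                 nrow(rep1$events) / 30)

  # empty buffer
  rep0 <- build_report(lab_seq(character(0)), group_events(lab_seq(character(0))))
  expect_equal(rep0$span_s, 0)
  expect_equal(rep0$events_total, 0L)
  expect_equal(rep0$events_per_hour, 0)

  # additivity over disjoint streams at the same frame rate
  labs2 <- lab_seq(c(NA, "right_ear", "right_ear", NA))
  labs2$timestamp_s <- labs2$timestamp_s + 10
  both <- rbind(labs, labs2)
  repb <- build_report(both, group_events(both))
  rep2 <- build_report(labs2, group_events(labs2))
  expect_equal(repb$areas$count, rep1$areas$count + rep2$areas$count)
  expect_equal(repb$areas$total_duration_s,
               rep1$areas$total_duration_s + rep2$areas$total_duration_s)

  p <- tempfile(fileext = ".csv")
  write_report(repb, p)
  lines <- readLines(p)
  expect_equal(lines[1], "metric,value")
  expect_true("area,count,total_duration_s" %in% lines)
  expect_true("event_id,body_id,start_s,end_s,label,n_frames" %in% lines)
})
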