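test_that("keypoint CSV reading completes the frame x joint grid", {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(mini_track_df(), f)
  tr <- read_keypoint_csv(f, fps = 30)
  expect_s3_class(tr, "keypoint_track")
  expect_equal(nrow(tr), 4)
  expect_false(any(tr$missing))
  expect_equal(tr$time_s, tr$frame / 30)

  # a dropped row becomes a missing (frame, joint) pair
  df <- mini_track_df()[-3, ] # left_knee at frame 1 absent
  readr::write_csv(df, f)
  tr2 <- read_keypoint_csv(f, fps = 30)
  row <- tr2[tr2$frame == 1 & tr2$joint == "left_knee", ]
  expect_true(row$missing)
  expect_equal(row$confidence, 0)

  # schema and parse errors
  readr::write_csv(mini_track_df()[, -3], f)
  expect_error(read_keypoint_csv(f, 30), "missing column")
  bad <- mini_track_df()
  bad$x <- as.character(bad$x)
  bad$x[1] <- "oops"
  readr::write_csv(bad, f)
  expect_error(read_keypoint_csv(f, 30), "not numeric")
})

test_that("OpenPose JSON frames read back with person-0 policy", {
  d <- tempfile()
  dir.create(d)
  # three frames in BODY_25 order, one person each; second person ignored
  kp <- rep(0, 75)
  set_joint <- function(kp, idx, x, y, c) {
    kp[idx * 3 + 1:3] <- c(x, y, c)
    kp
  }
  for (i in 0:2) {
    k <- kp
    for (idx in c(9, 10, 11, 12, 13, 14)) {
      k <- set_joint(k, idx, 100 + idx + i, 200 + idx, 0.9)
    }
    people <- list(list(pose_keypoints_2d = k),
                   list(pose_keypoints_2d = rep(1, 75)))
    jsonlite::write_json(list(people = people),
                         file.path(d, sprintf("f_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  tr <- read_openpose_json(d, fps = 30, model = "body25")
  expect_equal(sort(unique(tr$joint)),
               sort(c("left_hip", "left_knee", "left_ankle",
                      "right_hip", "right_knee", "right_ankle")))
  expect_equal(nrow(tr), 18)
  lk <- tr[tr$joint == "left_knee", ]
  expect_equal(lk$x, 100 + 13 + 0:2) # body25 left knee is index 13
  expect_false(any(tr$missing))

  # empty people -> frame marked missing at confidence 0
  jsonlite::write_json(list(people = list()),
                       file.path(d, "f_003.json"), auto_unbox = TRUE)
  tr2 <- read_openpose_json(d, fps = 30)
  f3 <- tr2[tr2$frame == 3, ]
  expect_true(all(f3$missing))
  expect_true(all(f3$confidence == 0))

  # malformed JSON names the file; unknown model flag rejected; empty dir
  writeLines("{not json", file.path(d, "f_004.json"))
  expect_error(read_openpose_json(d, 30), "f_004")
  expect_error(read_openpose_json(d, 30, model = "mpi15"), "body25")
  empty <- tempfile()
  dir.create(empty)
  expect_error(read_openpose_json(empty, 30), "No JSON")
})

test_that("confidence filtering is idempotent and reports survival", {
  tr <- new_keypoint_track(
    data.frame(frame = 0:2, joint = "left_knee", x = 1:3, y = 1:3,
               confidence = c(0.9, 0.3, 0.8)),
    fps = 30
  )
  f1 <- filter_by_confidence(tr, 0.5)
  expect_equal(f1$missing, c(FALSE, TRUE, FALSE))
  expect_equal(attr(f1, "survival")$survival, 2 / 3)
  f2 <- filter_by_confidence(f1, 0.5)
  expect_identical(f1$missing, f2$missing)

  # nothing removed when all confidences clear the bar
  hi <- new_keypoint_track(
    data.frame(frame = 0:2, joint = "j", x = 1:3, y = 1:3, confidence = 0.9),
    fps = 30
  )
  expect_false(any(filter_by_confidence(hi, 0.5)$missing))

  # threshold 1.0 wipes a track whose max confidence is below it, and the
  # downstream stage refuses it
  gone <- filter_by_confidence(hi, 1.0)
  expect_true(all(gone$missing))
  expect_error(interpolate_gaps(gone, 0.5), class = "gaithht_unusable_joint")

  expect_error(filter_by_confidence(tr, 1.5), "\\[0, 1\\]")
})

test_that("gap interpolation fills short runs and reports long ones", {
  n <- 31
  df <- data.frame(frame = 0:(n - 1), joint = "left_knee",
                   x = seq(10, 10 + 2 * (n - 1), by = 2),
                   y = 5, confidence = 0.9)
  tr <- new_keypoint_track(df, fps = 10)
  tr$missing[tr$frame == 5] <- TRUE
  tr$x[tr$frame == 5] <- NA
  filled <- interpolate_gaps(tr, max_gap_s = 0.5)
  expect_equal(filled$x[filled$frame == 5], (18 + 22) / 2) # midpoint of 10+2f
  expect_false(any(filled$missing))

  # 1 s gap with a 0.5 s cap stays missing and is reported
  tr2 <- new_keypoint_track(df, fps = 10)
  gap <- tr2$frame >= 10 & tr2$frame < 20
  tr2$missing[gap] <- TRUE
  out <- interpolate_gaps(tr2, max_gap_s = 0.5)
  expect_true(all(out$missing[gap]))
  rep <- attr(out, "gap_report")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$duration_s, 1)

  # non-missing samples are never altered
  expect_identical(out$x[!gap], tr2$x[!gap])
})

test_that("random sparse missingness interpolates close to generator truth", {
  sc <- gait_scenario_preset("normal", seed = 9, duration_s = 10,
                             noise_sd_deg = 0)
  tk <- generate_keypoint_track(sc)
  set.seed(99)
  # knock out 5% of single frames for one joint
  idx <- which(tk$joint == "left_knee")
  drop <- sort(sample(idx[5:(length(idx) - 5)], length(idx) %/% 20))
  drop <- drop[c(TRUE, diff(drop) > 1)] # isolated single-frame gaps
  truth_x <- tk$x[drop]
  tk$missing[drop] <- TRUE
  filled <- interpolate_gaps(tk, max_gap_s = 0.5)
  # per-frame hip translation plus knee swing bounds the error of a
  # single-step linear fill
  step <- max(abs(diff(tk$x[idx])))
  expect_lt(max(abs(filled$x[drop] - truth_x)), step)
})

test_that("confidence summary gives per-track means and a unit-mass density", {
  mk <- function(conf, id) {
    tr <- new_keypoint_track(
      data.frame(frame = 0:9, joint = "left_knee", x = 1, y = 1,
                 confidence = conf),
      fps = 30, subject_id = id
    )
  }
  out <- confidence_summary(list(mk(0.90, "a"), mk(0.98, "b")))
  expect_equal(sort(out$summary$mean), c(0.90, 0.98))
  # density integrates to 1
  width <- diff(out$density$mid[1:2])
  expect_lt(abs(sum(out$density$density) * width - 1), 1e-6)

  # degenerate density concentrates at the constant
  one <- confidence_summary(mk(0.95, "c"))
  peak <- one$density$mid[which.max(one$density$density)]
  expect_lt(abs(peak - 0.95), 0.02)

  # law of large numbers on uniform confidences
  set.seed(123)
  big <- new_keypoint_track(
    data.frame(frame = 0:9999, joint = "j", x = 1, y = 1,
               confidence = runif(10000)),
    fps = 30
  )
  expect_lt(abs(confidence_summary(big)$summary$mean - 0.5), 0.01)

  expect_error(confidence_summary(list()), "at least one")
})
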