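test_that("orientation traces are unit-norm with bounded per-step rotation", {
  tr <- make_orientation_trace(50, wobble_deg_s = 0, seed = 1)
  expect_true(all(abs(rowSums(tr^2) - 1) < 1e-9))
  expect_true(all(apply(tr, 1, function(q) all(q == tr[1, ]))))  # constant

  tr5 <- make_orientation_trace(200, base = random_quaternion(3),
                                wobble_deg_s = 5, seed = 2)
  expect_true(all(abs(rowSums(tr5^2) - 1) < 1e-9))
  # consecutive-sample rotation angle ~ wobble / fs = 0.5 degrees
  angles <- vapply(2:200, function(i) {
    dq <- quat_multiply(c(tr5[i - 1, 1], -tr5[i - 1, 2:4]), tr5[i, ])
    2 * acos(min(1, abs(dq[1]))) * 180 / pi
  }, numeric(1))
  expect_equal(mean(angles), 0.5, tolerance = 0.02)
  expect_lt(max(angles), 0.5 + 1e-6)
})

test_that("generated frames are exactly consistent under rotation", {
  for (b in behaviors) {
    rec <- generate_event(b, seed = 31)
    bf <- as.matrix(rec$data[c("ax_body", "ay_body", "az_body")])
    wf <- as.matrix(rec$data[c("ax_world", "ay_world", "az_world")])
    q <- as.matrix(rec$data[c("q1", "q2", "q3", "q4")])
    expect_equal(sqrt(rowSums(wf^2)), sqrt(rowSums(bf^2)), tolerance = 1e-9)
    expect_equal(rotate_to_world(bf, q), wf, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("resting events pin world-frame z at gravity", {
  for (s in 1:5) {
    rec <- generate_event("resting", seed = 40 + s)
    expect_equal(mean(rec$data$az_world), 9.807, tolerance = 0.1)
    expect_lt(abs(mean(rec$data$ax_world)), 0.1)
    expect_lt(abs(mean(rec$data$ay_world)), 0.1)
  }
})

test_that("mount events carry a high-quiet-high energy envelope", {
  for (s in 1:5) {
    rec <- generate_event("active_mounting", seed = 50 + s)
    amag <- sqrt(rec$data$ax_body^2 + rec$data$ay_body^2 + rec$data$az_body^2)
    dev <- (amag - 9.807)^2
    n <- length(dev)
    third <- n %/% 3
    e1 <- mean(dev[1:third])
    e2 <- mean(dev[(third + 1):(2 * third)])
    e3 <- mean(dev[(2 * third + 1):n])
    expect_gt(e1, 2 * e2)
    expect_gt(e3, 2 * e2)
  }
})

test_that("generation is deterministic under a fixed seed", {
  r1 <- generate_event("walking", seed = 77)
  r2 <- generate_event("walking", seed = 77)
  expect_identical(r1$data, r2$data)

  root1 <- withr::local_tempdir(); root2 <- withr::local_tempdir()
  counts <- c(active_mounting = 2, walking = 1, resting = 1)
  generate_database(root1, counts, seed = 9)
  generate_database(root2, counts, seed = 9)
  f1 <- list.files(root1, recursive = TRUE)
  expect_identical(f1, list.files(root2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(root1, f)),
                     readLines(file.path(root2, f)))
  }
})

test_that("per-class mean durations stay near their configured averages", {
  recs <- generate_recordings(c(active_mounting = 15, walking = 15,
                                resting = 15, head_nodding = 15,
                                grazing = 15), seed = 13)
  beh <- vapply(recs, function(r) r$behavior, character(1))
  durs <- vapply(recs, event_duration, numeric(1))
  target <- c(active_mounting = 9, walking = 14, resting = 20,
              head_nodding = 8, grazing = 71)
  for (b in names(target)) {
    expect_lt(abs(mean(durs[beh == b]) - target[[b]]) / target[[b]], 0.2)
  }
})

test_that("profile interpolation is linear in every numeric field", {
  p <- default_profiles()
  mid <- interpolate_profiles(p$active_mounting, p$head_nodding, 0.5)
  expect_equal(mid$peak_amp, (8 + 0) / 2)
  expect_equal(mid$osc_amp, (c(0, 0, 0) + c(0.3, 0.3, 3)) / 2)
  expect_identical(interpolate_profiles(p$active_mounting, p$head_nodding, 0)[
    setdiff(names(mid), "name")],
    p$active_mounting[setdiff(names(mid), "name")])
})
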