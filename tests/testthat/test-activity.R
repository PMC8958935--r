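t0 <- as.POSIXct("2019-11-05 01:00:00", tz = "UTC")

test_that("haul overlay labels fixes on closed intervals", {
  traj <- straight_trajectory(100, 2.5)
  tm <- traj$records$time
  hauls <- data.frame(trip_id = traj$trip_id,
                      start = c(tm[10], tm[60]), end = c(tm[30], tm[80]))
  lab <- label_from_hauls(traj, hauls, source = "observer")
  expect_equal(nrow(lab), 100)
  expect_equal(as.character(lab$state[10]), "trawling")     # at the start instant
  expect_equal(as.character(lab$state[30]), "trawling")     # at the end instant
  expect_equal(as.character(lab$state[31]), "not_trawling") # just after the end
  expect_equal(sum(lab$state == "trawling"), 21 + 21)

  # one second past the end is not trawling
  hauls2 <- data.frame(trip_id = traj$trip_id, start = tm[10], end = tm[30] - 1)
  lab2 <- label_from_hauls(traj, hauls2)
  expect_equal(as.character(lab2$state[30]), "not_trawling")

  # overlapping hauls are physically impossible
  bad <- data.frame(trip_id = traj$trip_id,
                    start = c(tm[10], tm[20]), end = c(tm[30], tm[40]))
  expect_error(label_from_hauls(traj, bad), "overlap")
})

test_that("a multi-haul trip yields the expected trawling fix count", {
  # 4 hauls of 2.5 h at 180 s cadence: 51 fixes per closed interval
  cfg <- tiny_fleet_config(hauls_per_trip_range = c(4, 4),
                           haul_duration_range_h = c(2.5, 2.5), seed = 17L)
  tr <- simulate_trip(cfg, "V01", "2019-11-20")
  expect_equal(sum(tr$truth$trawling), 4 * 50, tolerance = 0.05)
})

test_that("step features encode distance, turning angle and cyclic clock time", {
  # collinear, equally spaced: turning angle zero; step = 2.5 kn x 180 s
  traj <- straight_trajectory(10, 2.5)
  f <- compute_features(traj)
  expect_equal(f$step_distance_m[-1], rep(2.5 * 0.5144 * 180, 9), tolerance = 1e-3)
  expect_equal(f$turning_angle_deg[3:10], rep(0, 8), tolerance = 1e-6)
  expect_true(all(is.na(f$step_distance_m[1]), is.na(f$turning_angle_deg[2])))
  expect_false(any(f$eligible[1:2]))
  expect_equal(f$tod_sin^2 + f$tod_cos^2, rep(1, 10))

  # exact double-back: turning angle 180
  xy <- rbind(c(0, 0), c(-500, 0), c(0, 0), c(-500, 0))
  tr <- track_from_xy(xy, (0:3) * 180)
  traj2 <- trawlwatch:::new_trajectory("VX_d", "VX", as.Date("2019-11-04"),
                                       data.frame(time = tr$time, lon = tr$lon, lat = tr$lat))
  f2 <- compute_features(traj2)
  expect_equal(abs(f2$turning_angle_deg[3]), 180, tolerance = 1e-4)

  expect_warning(f3 <- compute_features(straight_trajectory(2, 2)), "3 fixes")
  expect_null(f3)
})

test_that("vessel-level splits are disjoint and reproducible", {
  ds <- data.frame(vessel_id = rep(sprintf("V%02d", 1:14), each = 5), x = 1)
  sp <- split_by_vessel(ds, 7, seed = 4L)
  expect_length(sp$train_vessels, 7)
  expect_length(sp$test_vessels, 7)
  expect_length(intersect(sp$train_vessels, sp$test_vessels), 0)
  expect_setequal(c(sp$train_vessels, sp$test_vessels), unique(ds$vessel_id))
  sp2 <- split_by_vessel(ds, 7, seed = 4L)
  expect_identical(sp$train_vessels, sp2$train_vessels)
  expect_error(split_by_vessel(ds, 14, seed = 1L), "below")
  two <- data.frame(vessel_id = c("A", "A", "B"), x = 1)
  spt <- split_by_vessel(two, 1, seed = 1L)
  expect_length(spt$train_vessels, 1)
  expect_length(spt$test_vessels, 1)
})

make_separable_dataset <- function(n = 300, seed = 8L) {
  # trawl steps ~231 m, transit steps ~510 m: separable on distance alone
  set.seed(seed)
  state <- factor(rep(c("trawling", "not_trawling"), each = n / 2),
                  levels = c("not_trawling", "trawling"))
  data.frame(
    vessel_id = rep(sprintf("V%02d", 1:6), length.out = n),
    step_distance_m = ifelse(state == "trawling", rnorm(n, 231, 15), rnorm(n, 510, 25)),
    turning_angle_deg = ifelse(state == "trawling", rnorm(n, 0, 25), rnorm(n, 0, 50)),
    tod_sin = sin(2 * pi * runif(n)), tod_cos = cos(2 * pi * runif(n)),
    state = state)
}

test_that("the forest separates well-separated kinematics and is seed-stable", {
  ds <- make_separable_dataset()
  m <- train_classifier(ds, seed = 2L)
  ev <- evaluate_classifier(m, ds)
  expect_gte(ev$accuracy, 0.99)
  m2 <- train_classifier(ds, seed = 2L)
  expect_identical(m$forest$err.rate, m2$forest$err.rate)
  only_one <- ds[ds$state == "trawling", ]
  expect_error(train_classifier(only_one), "not_trawling")
})

test_that("permuted labels learn nothing beyond the majority rate", {
  ds <- make_separable_dataset(n = 400, seed = 10L)
  set.seed(44)
  ds$state <- ds$state[sample(seq_len(nrow(ds)))]  # permute labels
  sp <- split_by_vessel(ds, 3, seed = 5L)
  m <- train_classifier(sp$train, ntree = 300, seed = 6L)
  ev <- evaluate_classifier(m, sp$test)
  maj <- max(table(sp$test$state)) / nrow(sp$test)
  expect_lt(abs(ev$accuracy - maj), 0.05 + 0.05)
})

test_that("per-trip prediction covers every fix and honours the endpoint buffer", {
  ds <- make_separable_dataset()
  m <- train_classifier(ds, seed = 2L)

  # pure transit at 6 kn: nearly all fixes not trawling
  transit <- straight_trajectory(40, 6.0)
  p <- predict_activity(m, transit)
  expect_equal(nrow(p), 40)                       # label completeness
  expect_gte(mean(p$state == "not_trawling"), 0.95)

  # trawl-speed leg: majority trawling, and leading fixes inherit a state
  trawl <- straight_trajectory(40, 2.5)
  p2 <- predict_activity(m, trawl)
  expect_gt(mean(p2$state == "trawling"), 0.5)
  expect_equal(as.character(p2$state[1]), as.character(p2$state[3]))

  # flagged fixes are forced to not_trawling
  trawl$records$flagged[5:10] <- TRUE
  p3 <- predict_activity(m, trawl)
  expect_true(all(p3$state[5:10] == "not_trawling"))
})

test_that("accuracy reports satisfy the confusion-matrix identity", {
  ds <- make_separable_dataset(n = 200, seed = 3L)
  m <- train_classifier(ds, seed = 1L)
  ev <- evaluate_classifier(m, ds)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / ev$n_fixes)
  expect_equal(sum(ev$confusion), ev$n_fixes)

  # degenerate evaluations
  expect_error(evaluate_classifier(m, ds[0, ]), "empty")
  flipped <- ds
  flipped$state <- factor(ifelse(ds$state == "trawling", "not_trawling", "trawling"),
                          levels = levels(ds$state))
  ev2 <- evaluate_classifier(m, flipped)
  expect_lte(ev2$accuracy, 0.01)
})

test_that("run-length smoothing drops sub-threshold trawling bursts", {
  lab <- data.frame(state = factor(
    c("not_trawling", "trawling", "not_trawling", rep("trawling", 5), "not_trawling"),
    levels = c("not_trawling", "trawling")))
  sm <- smooth_states(lab, min_run = 3)
  expect_equal(as.character(sm$state[2]), "not_trawling")
  expect_true(all(sm$state[4:8] == "trawling"))
})
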