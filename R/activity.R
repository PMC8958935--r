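# Trawling-activity inference: observer haul overlay, step features, a random
# forest on step distance / turning angle / time of day, vessel-level splits
# and the accuracy bookkeeping used to judge the classifier.

ACTIVITY_LEVELS <- c("not_trawling", "trawling")

#' Label fixes from observer haul intervals
#'
#' A fix is trawling iff its timestamp falls inside any haul's closed
#' `[start, end]` interval. Overlapping haul intervals within a trip are a
#' data error (one net cannot be in the water twice).
#'
#' @param traj a regularized `trajectory`.
#' @param hauls data.frame with `start`, `end` (POSIXct) for this trip
#'   (optionally a `trip_id` column to subset on).
#' @param source label provenance: `"observer"` or `"truth"`.
#' @return data.frame `trip_id`, `time`, `state` (factor), `source`.
#' @export
label_from_hauls <- function(traj, hauls, source = c("observer", "truth")) {
  source <- match.arg(source)
  if ("trip_id" %in% names(hauls))
    hauls <- hauls[hauls$trip_id == traj$trip_id, , drop = FALSE]
  if (nrow(hauls) == 0) stop("no haul intervals for trip ", traj$trip_id)
  if (any(hauls$start >= hauls$end)) stop("haul with start >= end in trip ", traj$trip_id)
  o <- order(hauls$start)
  if (nrow(hauls) > 1 && any(hauls$start[o][-1] <= hauls$end[o][-nrow(hauls)]))
    stop("overlapping haul intervals in trip ", traj$trip_id)
  tm <- traj$records$time[retained(traj)]
  st <- rep(FALSE, length(tm))
  for (i in seq_len(nrow(hauls)))
    st <- st | (tm >= hauls$start[i] & tm <= hauls$end[i])
  data.frame(trip_id = traj$trip_id, time = tm,
             state = factor(ifelse(st, "trawling", "not_trawling"),
                            levels = ACTIVITY_LEVELS),
             source = source)
}

#' Step features for activity classification
#'
#' Per regularized fix: distance to the previous fix (m), turning angle
#' between consecutive steps (degrees in (-180, 180]), and the local time of
#' day encoded cyclically as sin/cos of the fractional hour (a raw hour would
#' fracture midnight, when this fleet fishes). The first two fixes of a trip
#' lack a turning angle and are marked ineligible; endpoint-buffer-flagged
#' fixes are ineligible too.
#'
#' @param traj a regularized `trajectory`.
#' @param local_utc_offset_h local clock offset for the time-of-day feature.
#' @return data.frame with `trip_id`, `vessel_id`, `time`, `step_distance_m`,
#'   `turning_angle_deg`, `tod_sin`, `tod_cos`, `eligible`.
#' @export
compute_features <- function(traj, local_utc_offset_h = -5) {
  r <- which(retained(traj))
  n <- length(r)
  if (n < 3) {
    warning("trajectory ", traj$trip_id, " has < 3 fixes; no features computable")
    return(NULL)
  }
  lon <- traj$records$lon[r]; lat <- traj$records$lat[r]
  tm <- traj$records$time[r]
  d <- c(NA, step_distances_m(lon, lat))
  brg <- c(NA, geosphere::bearing(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1])))
  turn <- c(NA, wrap_angle(diff(brg)))
  turn[is.na(turn) & seq_len(n) >= 3] <- 0  # zero-length steps have no bearing
  hr <- local_seconds_of_day(tm, local_utc_offset_h) / 3600
  data.frame(trip_id = traj$trip_id, vessel_id = traj$vessel_id, time = tm,
             step_distance_m = d, turning_angle_deg = turn,
             tod_sin = sin(2 * pi * hr / 24), tod_cos = cos(2 * pi * hr / 24),
             eligible = seq_len(n) >= 3 & !traj$records$flagged[r])
}

#' Assemble a classification dataset from trajectories and labels
#'
#' Joins per-fix features with states by trip and timestamp, keeping eligible
#' fixes only.
#'
#' @param trajs list of regularized trajectories.
#' @param labels data.frame as from [label_from_hauls()] (rbind over trips).
#' @param local_utc_offset_h passed to [compute_features()].
#' @return data.frame of features plus `state`.
#' @export
build_activity_dataset <- function(trajs, labels, local_utc_offset_h = -5) {
  feats <- do.call(rbind, lapply(trajs, compute_features,
                                 local_utc_offset_h = local_utc_offset_h))
  feats <- feats[feats$eligible, , drop = FALSE]
  key_f <- paste(feats$trip_id, as.numeric(feats$time))
  key_l <- paste(labels$trip_id, as.numeric(labels$time))
  idx <- match(key_f, key_l)
  feats$state <- factor(as.character(labels$state[idx]), levels = ACTIVITY_LEVELS)
  feats <- feats[!is.na(feats$state), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Vessel-level train/test split
#'
#' Partitions a dataset by vessel so no vessel contributes fixes to both
#' sides, avoiding leakage of within-vessel autocorrelation.
#'
#' @param dataset data.frame with a `vessel_id` column.
#' @param n_train number of vessels assigned to the training side.
#' @param seed RNG seed for the draw.
#' @return list with `train`, `test` (data.frames) and `train_vessels`,
#'   `test_vessels`.
#' @export
split_by_vessel <- function(dataset, n_train, seed = 1L) {
  vessels <- sort(unique(dataset$vessel_id))
  if (length(vessels) < 2) stop("need >= 2 vessels to split")
  if (n_train >= length(vessels)) stop("n_train must be below the number of vessels")
  tv <- with_seed(seed, sample(vessels, n_train))
  list(train = dataset[dataset$vessel_id %in% tv, , drop = FALSE],
       test = dataset[!dataset$vessel_id %in% tv, , drop = FALSE],
       train_vessels = sort(tv),
       test_vessels = setdiff(vessels, tv))
}

FEATURE_COLS <- c("step_distance_m", "turning_angle_deg", "tod_sin", "tod_cos")

#' Train the trawling classifier
#'
#' Fits a random forest of `state` on the three trajectory predictors (step
#' distance, turning angle, cyclic time of day). Defaults: 500 trees,
#' `sqrt(p)` candidate variables per split, unlimited depth, out-of-bag
#' scoring.
#'
#' @param train data.frame with `state` and the feature columns.
#' @param ntree,mtry forest hyperparameters.
#' @param seed RNG seed for the forest.
#' @return an `activity_model`: the fitted forest plus a version stamp.
#' @export
train_classifier <- function(train, ntree = 500, mtry = NULL, seed = 1L) {
  if (!all(ACTIVITY_LEVELS %in% train$state)) {
    missing <- setdiff(ACTIVITY_LEVELS, unique(as.character(train$state)))
    stop("training set lacks class: ", paste(missing, collapse = ", "))
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(FEATURE_COLS))))
  x <- train[, FEATURE_COLS, drop = FALSE]
  cc <- stats::complete.cases(x)
  fit <- with_seed(seed, randomForest::randomForest(
    x = x[cc, , drop = FALSE], y = droplevels(train$state[cc]),
    ntree = ntree, mtry = mtry))
  structure(list(forest = fit, features = FEATURE_COLS, ntree = ntree,
                 mtry = mtry, seed = seed,
                 version = as.character(utils::packageVersion("trawlwatch"))),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  oob <- tryCatch(x$forest$err.rate[x$forest$ntree, "OOB"], error = function(e) NA)
  cat(sprintf("<activity_model: random forest, %d trees, mtry %d, OOB error %.3f>\n",
              x$ntree, x$mtry, oob))
  invisible(x)
}

#' Predict per-fix trawling activity for a trajectory
#'
#' One state per fix: eligible fixes get the forest's vote; the first two
#' fixes (no turning angle) inherit the trip's first computable prediction;
#' endpoint-buffer-flagged fixes are forced to `not_trawling`.
#'
#' @param model an `activity_model`.
#' @param traj a regularized `trajectory`.
#' @param local_utc_offset_h passed to [compute_features()].
#' @return data.frame `trip_id`, `time`, `state`, `source = "predicted"`.
#' @export
predict_activity <- function(model, traj, local_utc_offset_h = -5) {
  stopifnot(inherits(model, "activity_model"))
  feats <- compute_features(traj, local_utc_offset_h)
  if (is.null(feats)) stop("trajectory too short to predict")
  if (!all(model$features %in% names(feats))) stop("feature/model schema mismatch")
  state <- factor(rep("not_trawling", nrow(feats)), levels = ACTIVITY_LEVELS)
  el <- feats$eligible & stats::complete.cases(feats[, model$features, drop = FALSE])
  if (any(el))
    state[el] <- stats::predict(model$forest, feats[el, model$features, drop = FALSE])
  # leading fixes without a turning angle inherit the first real prediction
  lead <- which(!feats$eligible & seq_len(nrow(feats)) <= 2)
  fl <- traj$records$flagged[retained(traj)]
  if (length(lead) && any(el)) state[lead[!fl[lead]]] <- state[which(el)[1]]
  state[fl] <- "not_trawling"
  data.frame(trip_id = traj$trip_id, time = feats$time, state = state,
             source = "predicted")
}

#' Evaluate the classifier on a held-out feature set
#'
#' Accuracy is the number of correctly classified fixes (both classes) over
#' the total number of fixes, with the full confusion matrix.
#'
#' @param model an `activity_model`.
#' @param test data.frame with `state` and the feature columns (held-out
#'   vessels).
#' @param train_vessels,test_vessels optional vessel lists recorded in the
#'   report.
#' @return an `accuracy_report`.
#' @export
evaluate_classifier <- function(model, test, train_vessels = NULL, test_vessels = NULL) {
  if (is.null(test) || nrow(test) == 0) stop("empty test set")
  cc <- stats::complete.cases(test[, model$features, drop = FALSE])
  test <- test[cc, , drop = FALSE]
  pred <- stats::predict(model$forest, test[, model$features, drop = FALSE])
  truth <- factor(as.character(test$state), levels = ACTIVITY_LEVELS)
  pred <- factor(as.character(pred), levels = ACTIVITY_LEVELS)
  confusion <- table(truth = truth, predicted = pred)
  n <- length(truth)
  n_correct <- sum(diag(confusion))
  structure(list(n_fixes = n, n_correct = n_correct, accuracy = n_correct / n,
                 confusion = confusion,
                 train_vessels = train_vessels, test_vessels = test_vessels),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report: %d/%d fixes correct, accuracy %.3f>\n",
              x$n_correct, x$n_fixes, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Optional run-length smoother for predicted states
#'
#' Drops trawling runs shorter than `min_run` fixes (relabels them
#' `not_trawling`). Off by default in the pipeline; the classifier is
#' per-fix, as trawling states last hours at a 3-minute cadence.
#'
#' @param labels data.frame with a `state` column, time-ordered within trip.
#' @param min_run minimum run length (fixes) for a trawling bout.
#' @export
smooth_states <- function(labels, min_run = 3) {
  st <- as.character(labels$state)
  r <- rle(st)
  drop <- r$values == "trawling" & r$lengths < min_run
  r$values[drop] <- "not_trawling"
  labels$state <- factor(inverse.rle(r), levels = ACTIVITY_LEVELS)
  labels
}
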