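# Per-trip discard accounting: the discard proportion Dp = (Tc - Cc) / Tc,
# track/catch reconciliation, observer-vs-fisher weight calibration and
# monthly summaries.

#' Discard proportion of a trip
#'
#' `Dp = (Tc - Cc) / Tc`, the share of the total catch weight discarded,
#' where `Tc` is the trip's total catch and `Cc` its retained commercial
#' catch. Vectorized; violations (`Tc = 0`, `Cc > Tc`, negatives) raise
#' errors rather than being clamped.
#'
#' @param Tc total catch per trip, kg.
#' @param Cc commercial (retained) catch per trip, kg.
#' @param trip_id optional ids used in error messages.
#' @return numeric vector of proportions in `[0, 1]`.
#' @export
discard_proportion <- function(Tc, Cc, trip_id = NULL) {
  id <- function(i) if (is.null(trip_id)) paste0("element ", i) else trip_id[i]
  bad <- which(!is.na(Tc) & Tc <= 0)
  if (length(bad)) stop("Tc must be positive (", id(bad[1]), ")")
  bad <- which(!is.na(Cc) & Cc < 0)
  if (length(bad)) stop("Cc must be non-negative (", id(bad[1]), ")")
  bad <- which(!is.na(Tc) & !is.na(Cc) & Cc > Tc)
  if (length(bad)) stop("commercial catch exceeds total catch (", id(bad[1]), ")")
  (Tc - Cc) / Tc
}

#' Per-trip catch table with discard proportions
#'
#' `Tc` is the sum of per-haul total weights; `Cc` the sum of per-species
#' commercial weights reported for the trip. Trips without a species table
#' keep `Tc` but have `Dp` missing and are flagged.
#'
#' @param hauls data.frame `trip_id`, `haul_index`, `total_kg` (optionally
#'   `start` times).
#' @param species data.frame `trip_id`, `species`, `kg`.
#' @param trips optional data.frame `trip_id`, `date` (and `reporter`) used
#'   for month assignment; otherwise the date is parsed from haul start times
#'   (noon-rule fishing day) when available.
#' @param reporter reporter attached to all rows when `trips` lacks one.
#' @param local_utc_offset_h local offset for fishing-day month assignment.
#' @return data.frame `trip_id`, `reporter`, `Tc`, `Cc`, `Dp`, `month`,
#'   `dp_missing`.
#' @export
build_trip_catch <- function(hauls, species = NULL, trips = NULL,
                             reporter = "fisher", local_utc_offset_h = -5) {
  stopifnot(all(c("trip_id", "total_kg") %in% names(hauls)))
  if (any(duplicated(hauls[, c("trip_id", "haul_index")])))
    stop("duplicate haul_index within a trip")
  Tc <- tapply(hauls$total_kg, hauls$trip_id, sum)
  out <- data.frame(trip_id = names(Tc), Tc = as.numeric(Tc))
  if (!is.null(species) && nrow(species) > 0) {
    Cc <- tapply(species$kg, species$trip_id, sum)
    out$Cc <- as.numeric(Cc[out$trip_id])
  } else out$Cc <- NA_real_
  out$dp_missing <- is.na(out$Cc)
  out$Dp <- NA_real_
  ok <- !out$dp_missing
  out$Dp[ok] <- discard_proportion(out$Tc[ok], out$Cc[ok], out$trip_id[ok])
  # month of the trip's fishing day
  out$month <- NA_character_
  if (!is.null(trips) && "date" %in% names(trips)) {
    out$month <- format(as.Date(trips$date[match(out$trip_id, trips$trip_id)]), "%Y-%m")
    if ("reporter" %in% names(trips))
      out$reporter <- trips$reporter[match(out$trip_id, trips$trip_id)]
  } else if ("start" %in% names(hauls)) {
    first <- hauls[!duplicated(hauls$trip_id), ]
    fd <- fishing_date(first$start, local_utc_offset_h)
    out$month <- format(fd[match(out$trip_id, first$trip_id)], "%Y-%m")
  }
  if (is.null(out$reporter)) out$reporter <- reporter
  rownames(out) <- NULL
  out[, c("trip_id", "reporter", "Tc", "Cc", "Dp", "month", "dp_missing")]
}

#' Reconcile tracked trips against catch reports
#'
#' Partitions the union of reported trips into track+catch, track-only and
#' catch-only (disjoint and exhaustive by construction), with a per-vessel
#' breakdown where vessel ids are supplied.
#'
#' @param tracked data.frame with `trip_id` (and optionally `vessel_id`) for
#'   trips with positional data, or a character vector of ids.
#' @param catch same, for trips with catch records.
#' @return a `reconciliation_report`.
#' @export
reconcile <- function(tracked, catch) {
  as_tbl <- function(x) {
    if (is.character(x)) x <- data.frame(trip_id = x, vessel_id = NA_character_)
    if (!"vessel_id" %in% names(x)) x$vessel_id <- NA_character_
    x[, c("trip_id", "vessel_id")]
  }
  tracked <- as_tbl(tracked); catch <- as_tbl(catch)
  if (any(duplicated(tracked$trip_id))) stop("duplicate trip_ids in tracked trips")
  if (any(duplicated(catch$trip_id))) stop("duplicate trip_ids in catch trips")
  all_ids <- unique(c(tracked$trip_id, catch$trip_id))
  vess <- tracked$vessel_id[match(all_ids, tracked$trip_id)]
  vess[is.na(vess)] <- catch$vessel_id[match(all_ids, catch$trip_id)][is.na(vess)]
  cat_of <- ifelse(all_ids %in% tracked$trip_id & all_ids %in% catch$trip_id, "track_catch",
                   ifelse(all_ids %in% tracked$trip_id, "track_only", "catch_only"))
  trips <- data.frame(trip_id = all_ids, vessel_id = vess, category = cat_of)
  counts <- c(track_catch = sum(cat_of == "track_catch"),
              track_only = sum(cat_of == "track_only"),
              catch_only = sum(cat_of == "catch_only"))
  stopifnot(sum(counts) == length(all_ids))  # partition invariant
  by_vessel <- as.data.frame.matrix(table(trips$vessel_id, trips$category))
  structure(list(counts = counts, trips = trips, by_vessel = by_vessel,
                 track_only_rate = unname(counts["track_only"] /
                   (counts["track_only"] + counts["track_catch"]))),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat(sprintf("<reconciliation: %d track+catch, %d track-only, %d catch-only (track-only rate %.3f)>\n",
              x$counts["track_catch"], x$counts["track_only"], x$counts["catch_only"],
              x$track_only_rate))
  invisible(x)
}

#' Calibrate fisher weight estimates against observer measurements
#'
#' Ordinary least squares of the fisher's estimated haul weight on the
#' observer's measured weight (observer on the x-axis as ground truth).
#'
#' @param observer_kg measured weights, kg.
#' @param fisher_kg fisher-estimated weights, kg (same hauls).
#' @return a `calibration_fit` with `intercept`, `slope`, `r_squared`,
#'   `n_hauls` and the underlying `lm` fit.
#' @export
calibrate_weights <- function(observer_kg, fisher_kg) {
  ok <- stats::complete.cases(observer_kg, fisher_kg)
  observer_kg <- observer_kg[ok]; fisher_kg <- fisher_kg[ok]
  if (length(observer_kg) < 3) stop("need at least 3 observer/fisher weight pairs")
  if (any(observer_kg <= 0)) stop("observer weights must be positive")
  if (stats::var(observer_kg) == 0) stop("zero variance in measured weights")
  fit <- stats::lm(fisher_kg ~ observer_kg)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((fisher_kg - mean(fisher_kg))^2)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = if (tss == 0) 1 else 1 - rss / tss,
                 n_hauls = length(observer_kg), fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit: fisher = %.2f + %.3f x observer, R^2 = %.3f, n = %d>\n",
              x$intercept, x$slope, x$r_squared, x$n_hauls))
  invisible(x)
}

#' Simulate observer/fisher haul-weight pairs under a linear calibration model
#'
#' Observer weights are uniform on `weight_range`; fisher estimates follow
#' `intercept + slope * observer + noise`, with the Gaussian noise variance
#' set so the population R-squared equals `r_squared` given the uniform
#' predictor variance.
#'
#' @param n number of hauls.
#' @param intercept,slope,r_squared generating calibration model.
#' @param weight_range observer weight range, kg.
#' @param seed RNG seed.
#' @return data.frame `observer_kg`, `fisher_kg`.
#' @export
simulate_calibration_pairs <- function(n = 162, intercept = -1.14, slope = 0.98,
                                       r_squared = 0.898,
                                       weight_range = c(5, 200), seed = 1L) {
  stopifnot(r_squared > 0, r_squared < 1, n >= 3)
  var_signal <- slope^2 * diff(weight_range)^2 / 12
  noise_sd <- sqrt(var_signal * (1 - r_squared) / r_squared)
  with_seed(seed, {
    obs <- stats::runif(n, weight_range[1], weight_range[2])
    data.frame(observer_kg = obs,
               fisher_kg = intercept + slope * obs + stats::rnorm(n, 0, noise_sd))
  })
}

#' Monthly discard summary by reporter
#'
#' Per month and reporter: number of trips with a defined `Dp`, and the mean,
#' median and interquartile range of `Dp`. This is the tidy table that
#' month-contrast models consume; the package deliberately stops at the
#' summary.
#'
#' @param trip_catches data.frame as from [build_trip_catch()].
#' @return data.frame `month`, `reporter`, `n`, `mean_Dp`, `median_Dp`,
#'   `q25`, `q75`.
#' @export
monthly_summary <- function(trip_catches) {
  d <- trip_catches[!is.na(trip_catches$Dp) & !is.na(trip_catches$month), , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(month = character(), reporter = character(), n = integer(),
                      mean_Dp = numeric(), median_Dp = numeric(),
                      q25 = numeric(), q75 = numeric()))
  sp <- split(d, list(d$month, d$reporter), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    q <- stats::quantile(g$Dp, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(month = g$month[1], reporter = g$reporter[1], n = nrow(g),
               mean_Dp = mean(g$Dp), median_Dp = q[2], q25 = q[1], q75 = q[3])
  }))
  out <- out[order(out$month, out$reporter), ]
  rownames(out) <- NULL
  out
}
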