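#' Convert an ordinal milk log to entry quantiles
#'
#' Ordinal entry positions are normalized by the number of cows recorded in
#' that milking: `quantile = position / N_d`. This makes the domain
#' restriction uniform across days and divides out uncontrolled daily
#' variation in herd size — a cow that always enters last has entry quantile
#' exactly 1 on every day regardless of how many herd mates were milked.
#' Cows absent on a day get `NA`.
#'
#' @param log a `milk_log` (see [simulate_milkings()]), or a data frame with
#'   columns `day`, `subperiod`, `cow_id`, `position`.
#' @return a [quantile_matrix()] (cows x days).
#' @export
to_quantiles <- function(log) {
  if (inherits(log, "milk_log")) {
    records <- log$records
    enrolled <- log$enrolled
    subperiod <- log$subperiod
  } else {
    records <- as.data.frame(log)
    enrolled <- NULL
    subperiod <- NULL
  }
  need <- c("day", "cow_id", "position")
  if (!all(need %in% names(records))) {
    stop("milk log must have columns day, cow_id, position")
  }
  dup <- duplicated(records[c("day", "cow_id")])
  if (any(dup)) {
    off <- records[dup, c("day", "cow_id")]
    stop("duplicate (day, cow) records: ",
         paste(sprintf("(%s, %s)", off$day, off$cow_id), collapse = ", "))
  }

  days <- sort(unique(records$day))
  cows <- sort(unique(records$cow_id))
  n_d <- tapply(records$position, factor(records$day, levels = days), length)
  bad <- tapply(records$position, factor(records$day, levels = days),
                function(p) any(sort(p) != seq_along(p)))
  if (any(bad)) {
    stop("positions within a day must be a permutation of 1..N_d; offending days: ",
         paste(days[which(bad)], collapse = ", "))
  }

  vals <- matrix(NA_real_, length(cows), length(days),
                 dimnames = list(cows, as.character(days)))
  ri <- match(records$cow_id, cows)
  ci <- match(records$day, days)
  vals[cbind(ri, ci)] <- records$position / as.numeric(n_d[ci])

  if (is.null(subperiod)) {
    if ("subperiod" %in% names(records)) {
      subperiod <- tapply(as.character(records$subperiod),
                          factor(records$day, levels = days),
                          function(s) s[[1L]])
    } else subperiod <- rep("pen", length(days))
  } else subperiod <- subperiod[as.character(days)]
  if (!is.null(enrolled)) enrolled <- enrolled[as.character(days)]

  quantile_matrix(vals, subperiod = subperiod, enrolled = enrolled)
}

#' Drop unusable observation days
#'
#' Applies the day-level record filters: a warm-up window at the start of
#' the trial (so the herd can establish its queueing pattern during rolling
#' enrollment), explicit drop windows around management changes (by default
#' the 2 days preceding the transition to pasture, the 4 days following
#' pasture access, and the final 7 days on trial), and a daily-coverage rule
#' removing any day on which fewer than `min_coverage` of the enrolled herd
#' was recorded in the parlor.
#'
#' @param qm a [quantile_matrix()].
#' @param warmup number of initial days to drop (default 55, appropriate for
#'   raw farm logs; synthetic logs from [simulate_milkings()] start after
#'   warm-up, so pass 0).
#' @param drop_windows list of integer day-index vectors to drop, or the
#'   string `"management"` (default) to derive the windows above from the
#'   subperiod labels, or `NULL` for none.
#' @param min_coverage minimum recorded fraction of the enrolled herd
#'   (default 0.75); days strictly below it are dropped.
#' @return the filtered `quantile_matrix`; dropped days and reasons are
#'   attached as attribute `"dropped_days"` (a data frame).
#' @export
filter_days <- function(qm, warmup = 55L, drop_windows = "management",
                        min_coverage = 0.75) {
  stopifnot(inherits(qm, "quantile_matrix"))
  days <- as.integer(colnames(qm))
  if (warmup >= length(days)) stop("warmup must be smaller than the number of days")

  reason <- rep(NA_character_, length(days))
  reason[seq_len(warmup)] <- "warmup"

  if (identical(drop_windows, "management")) {
    sub <- day_subperiod(qm)
    drop_windows <- list()
    if (any(sub == "pen") && any(sub == "pasture")) {
      trans <- max(which(sub == "pen"))            # last pen day index
      drop_windows$pre_pasture <- days[max(1L, trans - 1L):trans]
      drop_windows$post_pasture <- days[(trans + 1L):min(length(days), trans + 4L)]
    }
    drop_windows$trial_end <- days[max(1L, length(days) - 6L):length(days)]
  }
  for (w in seq_along(drop_windows)) {
    nm <- names(drop_windows)[w]
    if (is.null(nm) || nm == "") nm <- paste0("window", w)
    hit <- days %in% drop_windows[[w]] & is.na(reason)
    reason[hit] <- nm
  }

  cov <- colSums(!is.na(qm)) / pmax(day_enrolled(qm), 1L)
  low <- cov < min_coverage & is.na(reason)
  reason[low] <- "low_coverage"

  keep <- is.na(reason)
  if (!any(keep)) stop("all days removed by filters")
  out <- qm[, keep]
  attr(out, "dropped_days") <- data.frame(day = days[!keep],
                                          reason = reason[!keep],
                                          stringsAsFactors = FALSE)
  out
}

#' Drop cows with insufficient attendance
#'
#' Removes cows not present in at least `min_attendance` of the (already
#' day-filtered) milkings. The boundary is inclusive: a cow present in
#' exactly half of 80 milkings survives the default 0.5 threshold.
#'
#' @param qm a [quantile_matrix()].
#' @param min_attendance minimum fraction of days with a record (default 0.5).
#' @return the filtered `quantile_matrix`.
#' @export
filter_cows <- function(qm, min_attendance = 0.5) {
  stopifnot(inherits(qm, "quantile_matrix"),
            min_attendance >= 0, min_attendance <= 1)
  att <- rowMeans(!is.na(qm))
  qm[att >= min_attendance, ]
}

#' Restrict to cows with no recorded health events
#'
#' @param qm a [quantile_matrix()].
#' @param attributes data frame with columns `cow_id` and `n_health_events`
#'   (e.g. the profiles from [draw_herd()]), covering all cows in `qm`.
#' @return the `quantile_matrix` restricted to healthy cows.
#' @export
subset_healthy <- function(qm, attributes) {
  stopifnot(inherits(qm, "quantile_matrix"))
  idx <- match(rownames(qm), attributes$cow_id)
  if (anyNA(idx)) {
    stop("cows missing from attribute table: ",
         paste(rownames(qm)[is.na(idx)], collapse = ", "))
  }
  healthy <- attributes$n_health_events[idx] == 0L
  if (!any(healthy)) stop("no healthy cows remain")
  qm[healthy, ]
}
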