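#' Subperiod consistency of median entry quantiles
#'
#' Computes each cow's median entry quantile separately over the pen and
#' pasture subperiods and correlates them across cows, with Pearson's R and
#' Kendall's tau (tau-b, tie-corrected — quantile medians can tie). High
#' agreement indicates temporal stationarity of queue positions across the
#' housing change.
#'
#' @param qm a [quantile_matrix()] whose days carry both subperiod labels.
#' @return an object of class `subperiod_summary`: `per_cow` (data frame of
#'   pen/pasture medians), `pearson_r`, `pearson_p`, `kendall_tau`,
#'   `kendall_p`, `n_cows`.
#' @export
subperiod_consistency <- function(qm) {
  sub <- day_subperiod(qm)
  if (!all(c("pen", "pasture") %in% sub)) {
    stop("both pen and pasture subperiods must be present")
  }
  med <- function(cols) apply(unclass(qm)[, cols, drop = FALSE], 1L,
                              stats::median, na.rm = TRUE)
  pen <- med(sub == "pen")
  pas <- med(sub == "pasture")
  ok <- !is.na(pen) & !is.na(pas)
  if (sum(ok) < 3L) stop("need at least 3 cows with medians in both subperiods")
  pr <- stats::cor.test(pen[ok], pas[ok], method = "pearson")
  kt <- suppressWarnings(stats::cor.test(pen[ok], pas[ok], method = "kendall"))
  structure(list(per_cow = data.frame(cow_id = rownames(qm),
                                      pen_median = pen, pasture_median = pas,
                                      row.names = NULL),
                 pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
                 kendall_tau = unname(kt$estimate), kendall_p = kt$p.value,
                 n_cows = sum(ok)),
            class = "subperiod_summary")
}

#' @export
print.subperiod_summary <- function(x, ...) {
  cat(sprintf("<subperiod_summary> %d cows; Pearson R = %.3f (p = %s), Kendall tau = %.3f (p = %s)\n",
              x$n_cows, x$pearson_r, format.pval(x$pearson_p, digits = 3),
              x$kendall_tau, format.pval(x$kendall_p, digits = 3)))
  invisible(x)
}

#' @export
plot.subperiod_summary <- function(x, ...) {
  graphics::plot(x$per_cow$pen_median, x$per_cow$pasture_median,
                 xlab = "median entry quantile (pen)",
                 ylab = "median entry quantile (pasture)",
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Within-group median sensor table (tube-plot data)
#'
#' For each (day, hour, queue group) and every sensor channel, the median
#' over the cows in that group — the long table behind the tube plots,
#' whose circular axis is the hour and longitudinal axis the day. Groups
#' are ordered by their median entry quantile when `qm` is supplied.
#'
#' @param sensor a `sensor_log` data frame.
#' @param queue_labels named integer vector of queue-group labels covering
#'   every cow in `sensor`.
#' @param channels channel columns to summarize.
#' @return data frame of class `tube_table`: `day`, `hour`, `queue_group`,
#'   `channel`, `median`, `n_cows`.
#' @export
tube_table <- function(sensor, queue_labels,
                       channels = c("eating", "rumination", "nonactive",
                                    "active", "highactive", "temperature")) {
  miss <- setdiff(unique(sensor$cow_id), names(queue_labels))
  if (length(miss)) stop("queue_labels missing for cows: ",
                         paste(miss, collapse = ", "))
  grp <- queue_labels[sensor$cow_id]
  empty <- setdiff(unique(queue_labels), unique(grp))
  if (length(empty)) warning("queue groups with no sensor records omitted: ",
                             paste(empty, collapse = ", "))
  out <- lapply(channels, function(ch) {
    agg <- stats::aggregate(sensor[[ch]],
                            by = list(day = sensor$day, hour = sensor$hour,
                                      queue_group = grp),
                            FUN = stats::median)
    cnt <- stats::aggregate(sensor[[ch]],
                            by = list(day = sensor$day, hour = sensor$hour,
                                      queue_group = grp),
                            FUN = length)
    data.frame(agg[c("day", "hour", "queue_group")], channel = ch,
               median = agg$x, n_cows = cnt$x)
  })
  out <- do.call(rbind, out)
  class(out) <- c("tube_table", "data.frame")
  out
}
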