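#' Entry-quantile matrix
#'
#' The central container of the package: a cows x days numeric matrix of
#' parlor entry quantiles in (0, 1], with `NA` marking cow-days without a
#' record. Row names are cow ids, column names are day indices. Two per-day
#' metadata vectors travel with the matrix: the overnight-housing subperiod
#' of each day (`"pen"` or `"pasture"`) and the number of cows enrolled in
#' the herd that day (the denominator of the daily-coverage filter).
#'
#' `NA` is the only missing marker; 0 is outside the valid quantile range and
#' is rejected, so absent records can never be confused with a leading queue
#' position.
#'
#' @param values numeric matrix, cows in rows, days in columns; entries in
#'   (0, 1] or `NA`.
#' @param subperiod character vector, one of `"pen"`/`"pasture"` per column.
#' @param enrolled integer vector, herd size enrolled on each day; defaults
#'   to the column-wise count of non-missing records.
#' @return an object of class `quantile_matrix` (a numeric matrix carrying
#'   `subperiod` and `enrolled` attributes).
#' @seealso [to_quantiles()] which builds one from a raw milk log.
#' @export
quantile_matrix <- function(values, subperiod = NULL, enrolled = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("quantile values must be numeric")
  v <- values[!is.na(values)]
  if (length(v) && (any(v <= 0) || any(v > 1))) {
    stop("entry quantiles must lie in (0, 1]; use NA for missing records")
  }
  if (is.null(subperiod)) subperiod <- rep("pen", ncol(values))
  subperiod <- rep_len(as.character(subperiod), ncol(values))
  if (is.null(enrolled)) enrolled <- colSums(!is.na(values))
  enrolled <- rep_len(as.integer(enrolled), ncol(values))
  if (is.null(rownames(values))) rownames(values) <- paste0("cow", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- as.character(seq_len(ncol(values)))
  structure(values,
            subperiod = subperiod,
            enrolled = enrolled,
            class = c("quantile_matrix", "matrix", "array"))
}

#' @export
`[.quantile_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sub <- attr(x, "subperiod")
  enr <- attr(x, "enrolled")
  y <- unclass(x)[i, j, drop = FALSE]
  if (!missing(j)) {
    sub <- sub[j]
    enr <- enr[j]
  }
  if (drop && (nrow(y) == 1L || ncol(y) == 1L)) return(drop(y))
  quantile_matrix(y, subperiod = sub, enrolled = enr)
}

#' @export
print.quantile_matrix <- function(x, ...) {
  sub <- attr(x, "subperiod")
  cat(sprintf("<quantile_matrix> %d cows x %d days (%d pen, %d pasture), %.1f%% missing\n",
              nrow(x), ncol(x), sum(sub == "pen"), sum(sub == "pasture"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
summary.quantile_matrix <- function(object, ...) {
  med <- apply(unclass(object), 1L, stats::median, na.rm = TRUE)
  att <- rowMeans(!is.na(object))
  out <- data.frame(cow_id = rownames(object), median_quantile = med,
                    attendance = att, row.names = NULL)
  out
}

# day-wise subperiod / enrollment accessors used across modules
day_subperiod <- function(qm) attr(qm, "subperiod")
day_enrolled  <- function(qm) attr(qm, "enrolled")
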