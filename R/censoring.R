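#' Per-group detection frequency
#'
#' Tabulates, for every compartment x congener present in the input, how
#' many samples had a quantifiable concentration. Rows with status
#' \code{not_determined} are excluded from the denominator (the congener
#' was never analyzed in those samples, so they carry no information
#' about detectability).
#'
#' @param x a \code{pfw_measurements} data.frame.
#' @return A data.frame with columns \code{compartment}, \code{congener},
#'   \code{n_total}, \code{n_detected}, \code{frequency}.
#' @export
detection_frequency <- function(x) {
  x <- validate_measurements(x)
  x <- x[x$status != "not_determined", , drop = FALSE]
  if (nrow(x) == 0L)
    stop("no determined measurements to summarize")
  key <- interaction(x$compartment, x$congener, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(x, key), function(sub) {
    data.frame(compartment = sub$compartment[1L],
               congener = sub$congener[1L],
               n_total = nrow(sub),
               n_detected = sum(sub$status == "detected"),
               stringsAsFactors = FALSE)
  }))
  out$frequency <- out$n_detected / out$n_total
  rownames(out) <- NULL
  out
}

#' Screen congeners by detection frequency
#'
#' Partitions compartment x congener series into those detectable often
#' enough to analyze statistically and those excluded. The boundary is
#' inclusive: a series detected in exactly the threshold fraction of
#' samples is analyzable.
#'
#' @param summaries output of [detection_frequency()].
#' @param threshold minimum detected fraction, in (0, 1]. Default 0.60.
#' @return \code{summaries} with an added logical column
#'   \code{analyzable}.
#' @export
screen_congeners <- function(summaries, threshold = 0.60) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single number in (0, 1]")
  if (nrow(summaries) == 0L) stop("empty detection summary")
  summaries$analyzable <- summaries$frequency >= threshold
  summaries
}

# Hirsch-Stedinger exceedance probabilities and Weibull-type plotting
# positions for left-censored data. Returns positions for every entry.
hs_plotting_positions <- function(values, censored, limits) {
  thresholds <- sort(unique(c(0, limits[censored])))
  k <- length(thresholds)
  bounds <- c(thresholds, Inf)
  # detects counted in [T_j, T_{j+1}); censored obs at their limit
  a <- vapply(seq_len(k), function(j)
    sum(!censored & values >= bounds[j] & values < bounds[j + 1]), 0L)
  # B_j: observations known to lie below T_j
  b <- vapply(seq_len(k), function(j)
    sum((censored & limits <= thresholds[j]) |
        (!censored & values < thresholds[j])), 0L)
  pe <- numeric(k + 1L)  # P(X > T_j); pe[k+1] = 0 above the top interval
  for (j in rev(seq_len(k))) {
    denom <- a[j] + b[j]
    pe[j] <- if (denom == 0L) pe[j + 1L] else
      pe[j + 1L] + a[j] / denom * (1 - pe[j + 1L])
  }
  pp <- numeric(length(values))
  for (j in seq_len(k)) {
    in_int <- !censored & values >= bounds[j] & values < bounds[j + 1]
    if (any(in_int)) {
      r <- rank(values[in_int], ties.method = "first")
      pp[in_int] <- (1 - pe[j]) + (pe[j] - pe[j + 1L]) * r / (a[j] + 1L)
    }
    at_lim <- censored & limits == thresholds[j]
    if (any(at_lim)) {
      r <- seq_len(sum(at_lim))
      pp[at_lim] <- (1 - pe[j]) * r / (sum(at_lim) + 1L)
    }
  }
  pp
}

#' Impute nondetects by robust regression on order statistics
#'
#' Regression probability plotting for left-censored concentrations:
#' ranked observations receive Hirsch-Stedinger plotting positions that
#' account for the censoring thresholds, the log of the detected values
#' is regressed (ordinary least squares) on the standard-normal quantiles
#' of those positions, and each censored entry is replaced by the
#' back-transformed prediction at its own plotting position. Detected
#' values are never altered (robust ROS), and imputed values are not
#' clipped at their detection limit: the fitted line does not guarantee
#' predictions below the limit, and clipping would bias downstream means.
#' A prediction above its limit raises a warning instead.
#'
#' @param values numeric vector; detected concentrations (entries at
#'   censored positions are ignored and may be \code{NA}).
#' @param censored logical vector flagging left-censored entries.
#' @param limits detection limits; either one per censored entry (in
#'   order) or a full-length vector.
#' @return A list of class \code{pfw_ros} with elements \code{values}
#'   (completed series), \code{source} (\code{"observed"}/
#'   \code{"imputed"}), \code{fit} (named intercept/slope of the
#'   log-concentration vs normal-quantile line) and
#'   \code{plotting_positions}.
#' @export
#' @examples
#' r <- ros_impute(c(NA, 1.5, 2, 3, 4),
#'                 censored = c(TRUE, FALSE, FALSE, FALSE, FALSE),
#'                 limits = 1.0)
#' r$values[1]  # estimated concentration for the nondetect
ros_impute <- function(values, censored = rep(FALSE, length(values)),
                       limits = NULL) {
  n <- length(values)
  if (length(censored) != n)
    stop("censored flags must match values in length")
  censored <- as.logical(censored)
  if (all(censored)) stop("all values censored; nothing to fit")
  det <- values[!censored]
  if (anyNA(det)) stop("detected entries must carry values")
  if (any(det <= 0))
    stop("nonpositive detected value; log-scale ROS requires > 0")
  if (sum(!censored) < 3L)
    stop("insufficient detects (need >= 3) for the order-statistics fit")
  if (mean(censored) > 0.40)
    warning("censored fraction exceeds 40%; ROS fit may be unstable")

  lim_full <- rep(NA_real_, n)
  if (any(censored)) {
    if (is.null(limits))
      stop("detection limits required when censored entries are present")
    if (length(limits) == sum(censored)) {
      lim_full[censored] <- limits
    } else if (length(limits) == n) {
      lim_full <- limits
    } else if (length(limits) == 1L) {
      lim_full[censored] <- limits
    } else stop("limits must have length 1, n_censored, or length(values)")
    if (any(is.na(lim_full[censored]) | lim_full[censored] <= 0))
      stop("every censored entry needs a positive detection limit")
  }

  pp <- hs_plotting_positions(values, censored, lim_full)
  q <- stats::qnorm(pp)
  fit <- stats::lm.fit(cbind(1, q[!censored]), log(values[!censored]))
  coefs <- c(intercept = unname(fit$coefficients[1]),
             slope = unname(fit$coefficients[2]))
  out <- values
  out[censored] <- exp(coefs["intercept"] + coefs["slope"] * q[censored])
  if (any(censored) && any(out[censored] > lim_full[censored]))
    warning("imputed value(s) exceed their detection limit; kept as fitted")
  structure(
    list(values = out,
         source = ifelse(censored, "imputed", "observed"),
         fit = coefs,
         plotting_positions = pp),
    class = "pfw_ros")
}

#' Log-transform strictly positive concentrations
#'
#' Natural-log convention; all downstream ratios and profile shares are
#' invariant to the base.
#'
#' @param x numeric vector of positive concentrations.
#' @return \code{log(x)}.
#' @export
log_transform <- function(x) {
  if (any(is.na(x)) || any(x <= 0))
    stop("log transform requires strictly positive, non-missing values")
  log(x)
}
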