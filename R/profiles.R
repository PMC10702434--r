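#' Per-sample congener proportion profile
#'
#' The fraction each congener contributes to the sample's summed PFAS
#' concentration. Nondetects contribute zero to the sum (profiles are a
#' descriptive comparison; upstream imputation may be applied first by
#' replacing nondetect rows with detected ones). Congeners not determined
#' in the sample's matrix are excluded from the denominator entirely, and
#' the congener panel actually summed is recorded so profiles over
#' different analyte panels are only compared knowingly.
#'
#' @param x measurements for exactly one sample (one compartment).
#' @return A data.frame of class \code{pfw_profile} with columns
#'   \code{sample_id}, \code{compartment}, \code{congener},
#'   \code{proportion}; the denominator panel is in
#'   \code{attr(, "panel")}.
#' @export
sample_profile <- function(x) {
  x <- validate_measurements(x)
  if (length(unique(x$sample_id)) != 1L)
    stop("sample_profile expects measurements for exactly one sample")
  x <- x[x$status != "not_determined", , drop = FALSE]
  vals <- ifelse(x$status == "detected", x$value, 0)
  total <- sum(vals)
  if (nrow(x) == 0L || total <= 0)
    stop("no available congener values; profile undefined")
  out <- data.frame(sample_id = x$sample_id[1L],
                    compartment = x$compartment[1L],
                    congener = x$congener,
                    proportion = vals / total,
                    stringsAsFactors = FALSE)
  attr(out, "panel") <- sort(x$congener)
  class(out) <- c("pfw_profile", "data.frame")
  out
}

#' Profiles for every sample in a measurement table
#'
#' @param x a \code{pfw_measurements} data.frame.
#' @return One \code{pfw_profile} per sample, row-bound.
#' @export
sample_profiles <- function(x) {
  x <- validate_measurements(x)
  pieces <- lapply(split(x, x$sample_id), function(sub) {
    p <- sample_profile(sub)
    p$panel_size <- length(attr(p, "panel"))
    p
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("pfw_profile", "data.frame")
  out
}

#' Compartment mean profile
#'
#' Arithmetic mean of the per-sample proportions over all samples of one
#' compartment (mean of proportions, not ratio of mean concentrations:
#' every sample's composition counts equally regardless of its total
#' burden). Congeners missing from a sample's profile count as zero so
#' that all means are taken over the same sample set.
#'
#' @param profiles row-bound \code{pfw_profile} rows, all one
#'   compartment.
#' @return A data.frame with columns \code{compartment}, \code{congener},
#'   \code{mean_proportion}, \code{n_samples}.
#' @export
compartment_profile <- function(profiles) {
  if (length(unique(profiles$compartment)) != 1L)
    stop("profiles span multiple compartments; summarize one at a time")
  samples <- unique(profiles$sample_id)
  congeners <- unique(profiles$congener)
  m <- matrix(0, length(samples), length(congeners),
              dimnames = list(samples, congeners))
  m[cbind(match(profiles$sample_id, samples),
          match(profiles$congener, congeners))] <- profiles$proportion
  data.frame(compartment = profiles$compartment[1L],
             congener = congeners,
             mean_proportion = colMeans(m),
             n_samples = length(samples),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Approximate compartment profile from published means
#'
#' Shares of the summed congener means per compartment. This is a
#' ratio-of-means approximation to the per-sample mean-of-proportions
#' profile (raw per-sample data are not published), flagged as such via
#' the \code{basis} column.
#'
#' @param summaries a \code{pfw_summaries} table
#'   (default [table1_summaries()]).
#' @return A data.frame with columns \code{compartment}, \code{congener},
#'   \code{share}, \code{basis}.
#' @export
profile_from_summaries <- function(summaries = table1_summaries()) {
  avail <- summaries[summaries$flag == "value", , drop = FALSE]
  out <- do.call(rbind, lapply(split(avail, avail$compartment),
                               function(sub) {
    data.frame(compartment = sub$compartment,
               congener = sub$congener,
               share = sub$mean / sum(sub$mean),
               stringsAsFactors = FALSE)
  }))
  out$basis <- "ratio_of_means"
  rownames(out) <- NULL
  out
}
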