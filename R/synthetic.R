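#' Configuration for the synthetic food-web concentration generator
#'
#' States the simulated world: per-compartment sample sizes (defaults:
#' the study design 5, 6, 6, 5, 5, 15, 15), a congener x compartment
#' matrix of true arithmetic mean concentrations (defaults: the published
#' measurable means, \code{NA} where a congener was ND/X), a common
#' geometric SD for the lognormal concentration model (the study
#' log-transforms concentrations to reach normality, so a lognormal is
#' the natural emulation), and detection limits. True transfer ratios
#' for any compartment pair follow from the mean matrix, so the
#' population mean ratio of a simulated pair equals the configured truth
#' by construction.
#'
#' @param means congener x compartment matrix of true arithmetic means.
#' @param n named integer vector of per-compartment sample sizes.
#' @param gsd geometric standard deviation (> 1 for dispersion); scalar
#'   or congener x compartment matrix. Default 1.6, a moderate
#'   environmental spread.
#' @param detection_limits scalar or congener x compartment matrix;
#'   0 disables censoring.
#' @param pairs transfer pairs used for ground-truth ratios.
#' @param seed master seed; substreams per compartment x congener.
#' @return A list of class \code{pfw_web_config}.
#' @export
web_config <- function(means = NULL, n = NULL, gsd = 1.6,
                       detection_limits = 0, pairs = table2_pairs(),
                       seed = 1L) {
  comps <- pfw_compartments()
  if (is.null(n)) n <- stats::setNames(comps$n, comps$id)
  if (any(n < 1L)) stop("sample sizes must be >= 1")
  if (is.null(means)) {
    t1 <- table1_summaries()
    congeners <- unique(t1$congener)
    means <- matrix(NA_real_, length(congeners), length(names(n)),
                    dimnames = list(congeners, names(n)))
    ok <- t1$flag == "value"
    means[cbind(match(t1$congener[ok], congeners),
                match(t1$compartment[ok], names(n)))] <- t1$mean[ok]
  }
  means <- as.matrix(means)
  expand <- function(v) {
    if (length(v) == 1L)
      matrix(v, nrow(means), ncol(means), dimnames = dimnames(means))
    else as.matrix(v)
  }
  gsd <- expand(gsd)
  if (any(gsd <= 1, na.rm = TRUE))
    stop("geometric SD must exceed 1")
  structure(list(means = means, n = n, gsd = gsd,
                 detection_limits = expand(detection_limits),
                 pairs = pairs, seed = as.integer(seed)),
            class = "pfw_web_config")
}

#' Simulate a censored food-web concentration dataset
#'
#' Per compartment x congener with a configured mean, draws lognormal
#' concentrations whose arithmetic population mean equals that mean
#' (meanlog = log(mean) - sdlog^2/2). Draws below the detection limit
#' are emitted as nondetects carrying the limit. Ground truth (true
#' means, true pairwise ratios, true censoring probabilities) travels
#' alongside so tests never re-derive truth from the data.
#'
#' @param config a [web_config()].
#' @return list with \code{measurements} (a \code{pfw_measurements}
#'   data.frame) and \code{truth} (list: \code{means}, \code{ratios},
#'   \code{censoring_probability}).
#' @export
gen_concentrations <- function(config = web_config()) {
  stopifnot(inherits(config, "pfw_web_config"))
  means <- config$means
  rows <- list()
  cens_p <- means * NA_real_
  for (comp in colnames(means)) {
    for (cg in rownames(means)) {
      mu <- means[cg, comp]
      if (is.na(mu)) next
      sdlog <- log(config$gsd[cg, comp])
      meanlog <- log(mu) - sdlog^2 / 2
      set.seed(derive_seed(config$seed, "conc", comp, cg))
      v <- stats::rlnorm(config$n[[comp]], meanlog, sdlog)
      dl <- config$detection_limits[cg, comp]
      cens_p[cg, comp] <- stats::plnorm(dl, meanlog, sdlog)
      nd <- v < dl
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%02d", comp, seq_along(v)),
        compartment = comp, congener = cg,
        value = ifelse(nd, NA_real_, v),
        status = ifelse(nd, "nondetect", "detected"),
        detection_limit = ifelse(nd, dl, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  m <- validate_measurements(do.call(rbind, rows))
  pr <- config$pairs
  ratios <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    data.frame(factor_kind = pr$factor_kind[i],
               numerator = pr$numerator[i],
               denominator = pr$denominator[i],
               congener = rownames(means),
               true_ratio = means[, pr$numerator[i]] /
                 means[, pr$denominator[i]],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(measurements = m,
       truth = list(means = means, ratios = ratios,
                    censoring_probability = cens_p))
}

#' Configuration for the synthetic fatty-acid signature generator
#'
#' Four analysis groups (aquatic invertebrates, terrestrial
#' invertebrates, nestling liver, nestling carcass) with Dirichlet
#' compositional noise around group mean signatures over the seven major
#' dietary fatty acids. Default centroids plant the study's qualitative
#' structure: the terrestrial marker 18:2n6 peaks in terrestrial
#' invertebrates, the aquatic markers 20:1n9 and 20:5n3 peak in aquatic
#' invertebrates, and swallow tissues sit between, carcass closer to the
#' terrestrial source.
#'
#' @param group_means named list of mean proportion vectors (each sums
#'   to 1, shared fatty-acid names).
#' @param n named integer vector of per-group sample sizes (defaults
#'   5, 5, 15, 15 matching the study compartments).
#' @param concentration Dirichlet concentration (> 0); larger is
#'   tighter. Default 150, a tight composition typical of replicate
#'   signatures.
#' @param seed master seed.
#' @return A list of class \code{pfw_fa_config}.
#' @export
fa_config <- function(group_means = NULL, n = NULL, concentration = 150,
                      seed = 1L) {
  if (is.null(group_means)) {
    fas <- c("16:0", "18:0", "18:1n9", "18:2n6", "20:1n9", "20:5n3",
             "22:6n3")
    group_means <- list(
      aquatic_invertebrates = c(0.20, 0.08, 0.12, 0.08, 0.15, 0.22, 0.15),
      terrestrial_invertebrates = c(0.22, 0.10, 0.20, 0.35, 0.02, 0.04,
                                    0.07),
      liver = c(0.25, 0.18, 0.20, 0.12, 0.04, 0.06, 0.15),
      carcass = c(0.22, 0.10, 0.22, 0.25, 0.05, 0.07, 0.09))
    group_means <- lapply(group_means, stats::setNames, fas)
  }
  sums <- vapply(group_means, sum, 0)
  if (any(abs(sums - 1) > 1e-8))
    stop("group mean vectors must sum to 1")
  if (is.null(n))
    n <- stats::setNames(c(5L, 5L, 15L, 15L), names(group_means))
  if (concentration <= 0) stop("concentration must be positive")
  structure(list(group_means = group_means, n = n,
                 concentration = concentration, seed = as.integer(seed)),
            class = "pfw_fa_config")
}

# one Dirichlet(alpha) draw per row via independent gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate fatty-acid signatures
#'
#' @param config a [fa_config()].
#' @return list with \code{signatures} (tidy data.frame:
#'   \code{sample_id}, \code{group}, \code{fatty_acid},
#'   \code{proportion}) and \code{truth} (the group mean vectors).
#' @export
gen_fa_signatures <- function(config = fa_config()) {
  stopifnot(inherits(config, "pfw_fa_config"))
  rows <- list()
  for (grp in names(config$group_means)) {
    mu <- config$group_means[[grp]]
    set.seed(derive_seed(config$seed, "fa", grp))
    draws <- rdirichlet(config$n[[grp]], config$concentration * mu)
    for (i in seq_len(nrow(draws))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%02d", grp, i), group = grp,
        fatty_acid = names(mu), proportion = draws[i, ],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(signatures = out, truth = config$group_means)
}

#' Deterministic dataset pinned to the published compartment means
#'
#' For every measurable compartment x congener cell, constructs the
#' compartment's n concentration values so that the sample mean equals
#' the published mean exactly and all values fall inside the published
#' range, with spread targeting the published SE where the range allows
#' it (symmetric normal-quantile pattern, re-centered exactly). ND and X
#' cells produce no rows. Cells whose printed mean lies outside the
#' printed range (flagged in the fixture) collapse to constant values at
#' the mean. Running the transfer-factor pipeline on this dataset
#' reproduces the published BAF/BMF table up to bootstrap noise.
#'
#' @param summaries a \code{pfw_summaries} table
#'   (default [table1_summaries()]).
#' @return A \code{pfw_measurements} data.frame.
#' @export
gen_table1_like <- function(summaries = table1_summaries()) {
  avail <- summaries[summaries$flag == "value", , drop = FALSE]
  rows <- lapply(seq_len(nrow(avail)), function(i) {
    r <- avail[i, ]
    z <- stats::qnorm(seq_len(r$n) / (r$n + 1))
    z <- z - mean(z)
    if (max(abs(z)) > 0) z <- z / stats::sd(z)
    s_target <- r$se * sqrt(r$n)
    lo <- min(r$range_low, r$mean, na.rm = TRUE)
    hi <- max(r$range_high, r$mean, na.rm = TRUE)
    s_max <- if (max(abs(z)) == 0) 0 else
      min((r$mean - lo) / max(abs(z)), (hi - r$mean) / max(abs(z)))
    s <- max(0, min(s_target, 0.999 * s_max, na.rm = TRUE))
    v <- r$mean + s * z
    v <- v - (mean(v) - r$mean)   # exact mean despite rounding
    data.frame(sample_id = sprintf("%s_%02d", r$compartment,
                                   seq_len(r$n)),
               compartment = r$compartment, congener = r$congener,
               value = v, status = "detected",
               detection_limit = NA_real_, stringsAsFactors = FALSE)
  })
  validate_measurements(do.call(rbind, rows))
}
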