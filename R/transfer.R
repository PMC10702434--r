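#' Bootstrap resampling specification
#'
#' Controls the sample-size-balanced resampling behind every transfer
#' factor: compartments contribute unequal sample sizes (5-15), so each
#' side of a ratio is re-drawn to a common size before its mean is taken.
#'
#' @param n_draws resampled values per compartment (study value 1000).
#' @param seed master seed; per pair x congener streams are derived from
#'   it deterministically.
#' @param with_replacement draw with replacement (default; drawing 1000
#'   values from at most 15 requires it).
#' @param n_boot paired re-draws used to attach a bootstrap distribution
#'   (spread and percentile interval) to the point estimate.
#' @return A list of class \code{pfw_bootstrap_spec}.
#' @export
bootstrap_spec <- function(n_draws = 1000L, seed = 1L,
                           with_replacement = TRUE, n_boot = 200L) {
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("n_draws must be >= 1")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  structure(list(n_draws = n_draws, seed = as.integer(seed),
                 with_replacement = isTRUE(with_replacement),
                 n_boot = as.integer(n_boot)),
            class = "pfw_bootstrap_spec")
}

# deterministic substream seed from a master seed and string labels
derive_seed <- function(seed, ...) {
  s <- paste(..., sep = ":")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 7919) %% 2147483647)
}

#' Balanced resample of exact concentration values
#'
#' Draws \code{n_draws} values uniformly from the input (with
#' replacement by default). Inputs must be "exact" values — observed or
#' imputed concentrations, never nondetect placeholders — and every
#' output value is an element of the input.
#'
#' @param values nonempty numeric vector.
#' @param spec a [bootstrap_spec()].
#' @return Numeric vector of length \code{spec$n_draws}.
#' @export
bootstrap_balance <- function(values, spec = bootstrap_spec()) {
  if (length(values) == 0L) stop("cannot resample an empty value set")
  if (anyNA(values)) stop("exact values required; NA present")
  if (!spec$with_replacement && spec$n_draws > length(values))
    stop("n_draws exceeds available values for without-replacement draws")
  set.seed(spec$seed)
  values[sample.int(length(values), spec$n_draws,
                    replace = spec$with_replacement)]
}

#' Bootstrap sample-size-balanced transfer factor
#'
#' Each side is re-drawn to \code{n_draws} balanced values \code{n_boot}
#' times. The point estimate is the mean of all numerator draws over the
#' mean of all denominator draws (organism over abiotic medium for a
#' BAF, predator tissue over prey for a BMF), which converges on the
#' ratio of compartment sample means. The attached bootstrap mean, SD
#' and percentile 95% interval come from paired classical bootstrap
#' replicates at the original sample sizes, so they reflect the
#' compartments' sampling variability; the headline value does not
#' depend on this enrichment.
#'
#' @param numerator_values,denominator_values exact concentration values
#'   for the two compartments (native units; the ratio carries their
#'   mixed units).
#' @param pair optional list/row with \code{factor_kind},
#'   \code{numerator}, \code{denominator} labels.
#' @param congener optional congener id label.
#' @param spec a [bootstrap_spec()].
#' @return A one-row data.frame of class \code{pfw_transfer} with the
#'   estimate, bootstrap summaries and a computability status.
#' @export
transfer_factor <- function(numerator_values, denominator_values,
                            pair = NULL, congener = NA_character_,
                            spec = bootstrap_spec()) {
  lab <- function(field, default) {
    if (!is.null(pair) && !is.null(pair[[field]])) pair[[field]] else default
  }
  base <- data.frame(factor_kind = lab("factor_kind", NA_character_),
                     numerator = lab("numerator", NA_character_),
                     denominator = lab("denominator", NA_character_),
                     congener = congener,
                     status = "computed", reason = NA_character_,
                     point_estimate = NA_real_, bootstrap_mean = NA_real_,
                     bootstrap_sd = NA_real_, interval_2_5 = NA_real_,
                     interval_97_5 = NA_real_,
                     stringsAsFactors = FALSE)
  not_comp <- function(reason) {
    base$status <- "not_computable"; base$reason <- reason
    class(base) <- c("pfw_transfer", "data.frame")
    base
  }
  if (length(numerator_values) == 0L)
    return(not_comp("no measurable concentration in numerator compartment"))
  if (length(denominator_values) == 0L)
    return(not_comp("no measurable concentration in denominator compartment"))

  set.seed(spec$seed)
  draw_mean <- function(v, size) mean(v[sample.int(length(v), size,
                                                   replace = spec$with_replacement)])
  num_means <- numeric(spec$n_boot)
  den_means <- numeric(spec$n_boot)
  for (i in seq_len(spec$n_boot)) {
    num_means[i] <- draw_mean(numerator_values, spec$n_draws)
    den_means[i] <- draw_mean(denominator_values, spec$n_draws)
  }
  if (mean(den_means) == 0) return(not_comp("zero denominator"))
  # ratio of full bootstrap means: headline value is insensitive to n_boot
  base$point_estimate <- mean(num_means) / mean(den_means)
  # distribution: classical paired bootstrap at the original sample sizes
  # (balanced n_draws resamples only measure resampling noise, not the
  # sampling variability of the compartments themselves)
  reps <- vapply(seq_len(spec$n_boot), function(i) {
    d <- draw_mean(denominator_values, length(denominator_values))
    if (d == 0) return(NA_real_)
    draw_mean(numerator_values, length(numerator_values)) / d
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  base$bootstrap_mean <- mean(reps)
  base$bootstrap_sd <- stats::sd(reps)
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  base$interval_2_5 <- qs[1]
  base$interval_97_5 <- qs[2]
  class(base) <- c("pfw_transfer", "data.frame")
  base
}

#' Transfer factors for a full pair x congener grid
#'
#' Attempts one transfer factor per requested compartment pair and
#' congener. A compartment contributes the detected (or upstream-imputed)
#' values of its samples; a side with no measurable value — the congener
#' below detection or not determined there — yields status
#' \code{not_computable} with the reason recorded. Each cell draws from
#' its own random stream derived from the master seed and the pair and
#' congener labels, so results are reproducible cell-wise and invariant
#' to the order in which cells are computed.
#'
#' @param x a \code{pfw_measurements} data.frame (exact values are rows
#'   with status \code{detected}).
#' @param pairs data.frame of pairs as from [table2_pairs()].
#' @param congeners congener ids to attempt; default: the published
#'   transfer-table panel.
#' @param spec a [bootstrap_spec()].
#' @return A data.frame of class \code{pfw_transfer}, one row per
#'   pair x congener.
#' @export
transfer_matrix <- function(x, pairs = table2_pairs(), congeners = NULL,
                            spec = bootstrap_spec()) {
  x <- validate_measurements(x)
  known <- pfw_compartments()$id
  bad <- !(pairs$numerator %in% known) | !(pairs$denominator %in% known)
  if (any(bad))
    stop("unknown compartment in pair ", pairs$numerator[which(bad)[1]],
         "/", pairs$denominator[which(bad)[1]])
  if (is.null(congeners)) congeners <- unique(table2_cells()$congener)
  det <- x[x$status == "detected", , drop = FALSE]
  vals <- split(det$value, paste(det$compartment, det$congener, sep = "\r"))
  rows <- vector("list", nrow(pairs) * length(congeners))
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    for (cg in congeners) {
      k <- k + 1L
      cell_spec <- spec
      cell_spec$seed <- derive_seed(spec$seed, pairs$numerator[i],
                                    pairs$denominator[i], cg)
      rows[[k]] <- transfer_factor(
        vals[[paste(pairs$numerator[i], cg, sep = "\r")]],
        vals[[paste(pairs$denominator[i], cg, sep = "\r")]],
        pair = pairs[i, ], congener = cg, spec = cell_spec)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pfw_transfer", "data.frame")
  out
}

#' Classify a computed transfer factor
#'
#' A factor indicates bioaccumulation (BAF) or biomagnification (BMF)
#' when it exceeds 1; the boundary is exclusive.
#'
#' @param factor a \code{pfw_transfer} row (or data.frame of rows).
#' @return Logical vector, \code{TRUE} where the point estimate > 1.
#' @export
classify_transfer <- function(factor) {
  if (any(factor$status != "computed"))
    stop("cannot classify a not_computable transfer factor")
  factor$point_estimate > 1
}

#' Render a transfer matrix as a publication-style table
#'
#' Wide pair x congener table with rounded ratios and the human-readable
#' \code{"-"} sentinel for cells that could not be calculated. Machine
#' output should use the tidy matrix (with its explicit status column)
#' instead.
#'
#' @param tfm output of [transfer_matrix()].
#' @param digits significant digits for the rendered ratios.
#' @return A character data.frame, one row per pair.
#' @export
format_transfer_table <- function(tfm, digits = 3) {
  pairs <- unique(tfm[, c("factor_kind", "numerator", "denominator")])
  congeners <- unique(tfm$congener)
  out <- pairs
  for (cg in congeners) {
    sub <- tfm[tfm$congener == cg, ]
    idx <- match(paste(pairs$numerator, pairs$denominator),
                 paste(sub$numerator, sub$denominator))
    cell <- ifelse(sub$status[idx] == "computed",
                   signif(sub$point_estimate[idx], digits), NA)
    out[[cg]] <- ifelse(is.na(cell), "-", as.character(cell))
  }
  rownames(out) <- NULL
  out
}
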