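#' Per-compartment concentration summaries (study fixture)
#'
#' The published arithmetic mean +/- SE and range of every congener in
#' every compartment, with censoring flags: \code{"value"} (measurable
#' mean), \code{"ND"} (below detection in all samples) and \code{"X"}
#' (congener not determined in that compartment). Standard errors printed
#' as "< 0.001" are stored as 0.001 (the printed upper bound). A few
#' cells carry a \code{note} documenting a corrected exponent typo or a
#' mean printed outside its own range; those cells are stored as printed
#' and flagged, never silently altered.
#'
#' @param include_totals keep the whole-panel total rows
#'   (\code{Sigma46PFAS})? Totals are summaries of sums, not congeners,
#'   and are excluded from per-congener computations by default.
#' @return A data.frame of class \code{pfw_summaries} with columns
#'   \code{compartment}, \code{congener}, \code{class_label},
#'   \code{carbons}, \code{flag}, \code{mean}, \code{se},
#'   \code{range_low}, \code{range_high}, \code{n}, \code{units},
#'   \code{note}.
#' @export
#' @examples
#' t1 <- table1_summaries()
#' subset(t1, compartment == "liver" & congener == "PFOS")
table1_summaries <- function(include_totals = FALSE) {
  raw <- table1_raw()
  comps <- pfw_compartments()
  pref <- compartment_prefixes()
  out <- do.call(rbind, lapply(names(pref), function(comp) {
    p <- pref[[comp]]
    mean_chr <- raw[[paste0(p, "_mean")]]
    flag <- ifelse(mean_chr == "ND", "ND",
                   ifelse(mean_chr == "X", "X", "value"))
    num <- function(x) suppressWarnings(as.numeric(x))
    data.frame(
      compartment = comp,
      congener = raw$congener,
      class_label = raw$class,
      carbons = suppressWarnings(as.integer(raw$carbons)),
      flag = flag,
      mean = ifelse(flag == "value", num(mean_chr), NA_real_),
      se = num(raw[[paste0(p, "_se")]]),
      range_low = num(raw[[paste0(p, "_lo")]]),
      range_high = num(raw[[paste0(p, "_hi")]]),
      n = comps$n[match(comp, comps$id)],
      units = comps$units[match(comp, comps$id)],
      note = ifelse(raw$note == "", NA_character_, raw$note),
      stringsAsFactors = FALSE
    )
  }))
  if (!include_totals) out <- out[out$class_label != "total", ]
  rownames(out) <- NULL
  class(out) <- c("pfw_summaries", "data.frame")
  out
}

#' Transfer-factor compartment pairs (study fixture)
#'
#' The eleven ordered compartment pairs for which bioaccumulation
#' factors (BAF, organism over abiotic medium) and non-trophic-adjusted
#' biomagnification factors (BMF, predator tissue over prey) were
#' computed: seven BAF pairs and four BMF pairs.
#'
#' @return A data.frame with columns \code{factor_kind} ("BAF"/"BMF"),
#'   \code{numerator}, \code{denominator}, and \code{units} (the mixed
#'   units the raw ratio carries).
#' @export
table2_pairs <- function() {
  cells <- table2_cells()
  pairs <- unique(cells[, c("factor_kind", "numerator", "denominator")])
  comps <- pfw_compartments()
  pairs$units <- paste0(
    "(", comps$units[match(pairs$numerator, comps$id)], ")/(",
    comps$units[match(pairs$denominator, comps$id)], ")")
  rownames(pairs) <- NULL
  pairs
}

#' Published transfer-factor cells (study fixture)
#'
#' Every pair x congener cell of the published BAF/BMF table: the printed
#' ratio where one was reported, and status \code{"dash"} where the cell
#' was printed as "-" (not calculated).
#'
#' @return A data.frame with columns \code{factor_kind},
#'   \code{numerator}, \code{denominator}, \code{congener},
#'   \code{printed} (numeric, \code{NA} for dashes) and
#'   \code{printed_status} ("value"/"dash").
#' @export
table2_cells <- function() {
  path <- system.file("extdata", "table2.csv", package = "pfasweb",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  congeners <- setdiff(names(raw), c("factor_kind", "numerator",
                                     "denominator"))
  out <- do.call(rbind, lapply(congeners, function(cg) {
    cell <- raw[[cg]]
    data.frame(
      factor_kind = raw$factor_kind,
      numerator = raw$numerator,
      denominator = raw$denominator,
      congener = cg,
      printed = suppressWarnings(as.numeric(ifelse(cell == "-", NA, cell))),
      printed_status = ifelse(cell == "-", "dash", "value"),
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(match(out$factor_kind, c("BAF", "BMF")),
               match(paste(out$numerator, out$denominator),
                     unique(paste(raw$numerator, raw$denominator))))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
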