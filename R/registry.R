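#' Environmental compartments of the study food web
#'
#' The seven sampled pools of the aquatic-terrestrial food web around a
#' tree swallow colony: three abiotic media (air, surface water, sediment)
#' and four biotic ones (aquatic and terrestrial macroinvertebrates,
#' nestling gastrointestinal tract, nestling liver). Concentration units
#' are fixed per compartment and are never converted between media, so
#' transfer-factor ratios carry mixed units (documented per pair).
#'
#' @return A data.frame with columns \code{id}, \code{kind}
#'   (\code{"abiotic"} or \code{"biotic"}), \code{units}, and \code{n}
#'   (the study design sample size).
#' @export
#' @examples
#' pfw_compartments()
pfw_compartments <- function() {
  data.frame(
    id = c("air", "surface_water", "sediment", "aquatic_invertebrates",
           "terrestrial_invertebrates", "gi_tract", "liver"),
    kind = c("abiotic", "abiotic", "abiotic", "biotic", "biotic",
             "biotic", "biotic"),
    units = c("ng/m3", "ng/mL", "ng/g", "ng/g ww", "ng/g ww",
              "ng/g ww", "ng/g ww"),
    n = c(5L, 6L, 6L, 5L, 5L, 15L, 15L),
    stringsAsFactors = FALSE
  )
}

#' PFAS congener panel
#'
#' The 31 congeners of the study panel with their structural class and
#' number of perfluorinated carbon atoms, plus the derived chain-length
#' category. Classes: perfluorocarboxylic acids (PFCA), perfluorosulfonic
#' acids (PFSA), fluorotelomer sulfonates (FTS), alcohols (FTOH) and
#' carboxylates (FTCA), and the perfluorooctane sulfonamide precursor
#' families (FOSA, FOSAA, FOSE).
#'
#' @return A data.frame with columns \code{id}, \code{class_label},
#'   \code{carbons}, \code{chain_category}.
#' @export
pfw_congeners <- function() {
  t1 <- table1_raw()
  t1 <- t1[t1$class != "total", c("congener", "class", "carbons")]
  data.frame(
    id = t1$congener,
    class_label = t1$class,
    carbons = as.integer(t1$carbons),
    chain_category = chain_category(t1$class, as.integer(t1$carbons)),
    stringsAsFactors = FALSE
  )
}

#' Chain-length category of a perfluoroalkyl acid
#'
#' Short/long classification by convention: PFCAs are long-chain at
#' >= 8 perfluorinated carbons, PFSAs at >= 7. Precursor classes (FTS,
#' FTOH, FTCA, FOSA, FOSAA, FOSE) have no short/long convention and
#' return \code{NA}.
#'
#' @param class_label character vector of congener classes.
#' @param carbons integer vector of perfluorinated carbon counts.
#' @return character vector: \code{"short"}, \code{"long"} or \code{NA}.
#' @export
#' @examples
#' chain_category("PFCA", 7) # short
#' chain_category("PFSA", 7) # long
chain_category <- function(class_label, carbons) {
  stopifnot(length(class_label) == length(carbons))
  out <- rep(NA_character_, length(class_label))
  pfca <- class_label == "PFCA"
  pfsa <- class_label == "PFSA"
  out[pfca] <- ifelse(carbons[pfca] >= 8L, "long", "short")
  out[pfsa] <- ifelse(carbons[pfsa] >= 7L, "long", "short")
  out
}

# internal: raw wide fixture table
table1_raw <- function() {
  path <- system.file("extdata", "table1.csv", package = "pfasweb",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
}

compartment_prefixes <- function() {
  c(air = "air", surface_water = "sw", sediment = "sed",
    aquatic_invertebrates = "ai", terrestrial_invertebrates = "ti",
    gi_tract = "gi", liver = "liver")
}
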