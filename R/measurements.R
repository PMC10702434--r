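#' Read a tidy table of congener measurements
#'
#' Reads and validates one concentration observation per row. Each row is
#' a sample x compartment x congener record with a censoring status:
#' \code{detected} (a concentration was quantified), \code{nondetect}
#' (below the reported detection limit), or \code{not_determined} (the
#' congener was not analyzed in that matrix).
#'
#' @param path CSV file with columns \code{sample_id},
#'   \code{compartment}, \code{congener}, \code{value}, \code{status},
#'   \code{detection_limit}.
#' @return A validated data.frame of class \code{pfw_measurements}, row
#'   order preserved.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  validate_measurements(df)
}

#' Write measurements back to tidy CSV
#'
#' Inverse of [read_measurements()]: a write-then-read round trip
#' reproduces values, statuses and detection limits exactly.
#'
#' @param x a \code{pfw_measurements} data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(x, path) {
  x <- validate_measurements(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a measurement table
#'
#' Enforces the record invariants: known compartment and congener ids, a
#' value present iff the status is \code{detected}, a positive detection
#' limit for every nondetect, and non-negative concentrations.
#'
#' @param df data.frame with the measurement columns.
#' @return \code{df} with class \code{pfw_measurements}.
#' @export
validate_measurements <- function(df) {
  needed <- c("sample_id", "compartment", "congener", "value", "status",
              "detection_limit")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$value <- as.numeric(df$value)
  df$detection_limit <- as.numeric(df$detection_limit)

  bad_comp <- !df$compartment %in% pfw_compartments()$id
  if (any(bad_comp))
    stop("unknown compartment '", df$compartment[which(bad_comp)[1]],
         "' in row ", which(bad_comp)[1])
  bad_cong <- !df$congener %in% pfw_congeners()$id
  if (any(bad_cong))
    stop("unknown congener '", df$congener[which(bad_cong)[1]],
         "' in row ", which(bad_cong)[1])
  bad_status <- !df$status %in% c("detected", "nondetect", "not_determined")
  if (any(bad_status))
    stop("invalid status '", df$status[which(bad_status)[1]],
         "' in row ", which(bad_status)[1])

  det <- df$status == "detected"
  if (any(det & is.na(df$value)))
    stop("detected measurement without a value in row ",
         which(det & is.na(df$value))[1])
  if (any(!det & !is.na(df$value)))
    stop("value present with status '", df$status[which(!det & !is.na(df$value))[1]],
         "' in row ", which(!det & !is.na(df$value))[1])
  if (any(det & df$value < 0))
    stop("negative concentration in row ", which(det & df$value < 0)[1])
  nd <- df$status == "nondetect"
  if (any(nd & (is.na(df$detection_limit) | df$detection_limit <= 0)))
    stop("nondetect without a positive detection limit in row ",
         which(nd & (is.na(df$detection_limit) | df$detection_limit <= 0))[1])
  class(df) <- unique(c("pfw_measurements", class(df)))
  df
}

#' Collapse duplicate analytical measurements
#'
#' Replicate determinations of the same sample x compartment x congener
#' are collapsed to their arithmetic mean before any analysis. Duplicates
#' that are all nondetects keep a single nondetect row (at the smallest
#' reported limit); a detected replicate takes precedence over a
#' nondetect one.
#'
#' @param x a \code{pfw_measurements} data.frame.
#' @return A deduplicated \code{pfw_measurements} data.frame.
#' @export
collapse_duplicates <- function(x) {
  x <- validate_measurements(x)
  key <- paste(x$sample_id, x$compartment, x$congener, sep = "\r")
  if (!anyDuplicated(key)) return(x)
  pieces <- lapply(split(seq_len(nrow(x)), key), function(idx) {
    sub <- x[idx, , drop = FALSE]
    if (nrow(sub) == 1L) return(sub)
    det <- sub[sub$status == "detected", , drop = FALSE]
    if (nrow(det) > 0L) {
      out <- det[1L, , drop = FALSE]
      out$value <- mean(det$value)
      return(out)
    }
    nd <- sub[sub$status == "nondetect", , drop = FALSE]
    if (nrow(nd) > 0L) {
      out <- nd[1L, , drop = FALSE]
      out$detection_limit <- min(nd$detection_limit)
      return(out)
    }
    sub[1L, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  out <- out[order(match(paste(out$sample_id, out$compartment,
                               out$congener, sep = "\r"), key)), ]
  rownames(out) <- NULL
  class(out) <- unique(c("pfw_measurements", class(out)))
  out
}
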