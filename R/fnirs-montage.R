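#' Action observation network ROI labels
#'
#' The 12 bilateral regions of interest: inferior frontal gyrus, middle
#' frontal gyrus, premotor cortex, motor cortex, superior temporal gyrus
#' and inferior parietal lobule, left and right.
#'
#' @format Character vector of length 12.
#' @export
aon_rois <- c(
  "LIFG", "LMFG", "LPMC", "LMC", "LSTG", "LIPL",
  "RIFG", "RMFG", "RPMC", "RMC", "RSTG", "RIPL"
)

#' Build a channel montage
#'
#' Describes the optode layout as a channel table: long channels (~30 mm
#' source-detector separation, probing cortex) each mapped to exactly one
#' ROI, and short channels (8 mm, probing scalp/skull only) used as
#' nuisance regressors. Long channels are distributed as evenly as
#' possible across the ROIs. The default sizes mirror the acquisition
#' montage: 78 long and 8 short channels over 12 AON regions.
#'
#' @param n_long Number of long channels (>= number of ROIs).
#' @param n_short Number of short channels (> 0).
#' @param rois ROI labels.
#' @param long_distance_mm Long-channel separation, must be in (20, 40).
#' @param short_distance_mm Short-channel separation, must be < 20.
#' @return Tibble with columns `channel`, `source`, `detector`,
#'   `distance_mm`, `type` ("long"/"short"), `roi` (NA for short channels).
#' @export
make_montage <- function(n_long = 78, n_short = 8, rois = aon_rois,
                         long_distance_mm = 30, short_distance_mm = 8) {
  stopifnot(n_long >= length(rois), n_short > 0)
  if (long_distance_mm <= 20 || long_distance_mm >= 40) {
    stop("long channels must have separation in (20, 40) mm", call. = FALSE)
  }
  if (short_distance_mm >= 20) {
    stop("short channels must have separation < 20 mm", call. = FALSE)
  }
  long <- tibble::tibble(
    channel = sprintf("L%02d", seq_len(n_long)),
    source = sprintf("S%02d", ((seq_len(n_long) - 1) %% 24) + 1),
    detector = sprintf("D%02d", ((seq_len(n_long) - 1) %% 23) + 1),
    distance_mm = long_distance_mm,
    type = "long",
    roi = rep(rois, length.out = n_long) # round-robin: counts differ by <= 1
  )
  short <- tibble::tibble(
    channel = sprintf("S%02d", seq_len(n_short)),
    source = sprintf("S%02d", ((seq_len(n_short) - 1) %% 24) + 1),
    detector = sprintf("SD%d", seq_len(n_short)),
    distance_mm = short_distance_mm,
    type = "short",
    roi = NA_character_
  )
  out <- dplyr::bind_rows(long, short)
  validate_montage(out)
  out
}

validate_montage <- function(montage) {
  needed <- c("channel", "source", "detector", "distance_mm", "type", "roi")
  missing_cols <- setdiff(needed, names(montage))
  if (length(missing_cols) > 0) {
    stop("montage lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  long <- montage[montage$type == "long", ]
  short <- montage[montage$type == "short", ]
  if (any(long$distance_mm <= 20 | long$distance_mm >= 40)) {
    stop("long channels must have distance in (20, 40) mm", call. = FALSE)
  }
  if (any(short$distance_mm >= 20)) {
    stop("short channels must have distance < 20 mm", call. = FALSE)
  }
  if (anyNA(long$roi)) {
    stop("every long channel must map to exactly one ROI", call. = FALSE)
  }
  if (anyDuplicated(montage$channel)) {
    stop("duplicated channel ids in montage", call. = FALSE)
  }
  invisible(montage)
}

#' Tabulated haemoglobin extinction coefficients
#'
#' Decadic molar extinction coefficients at 760 and 850 nm, read from the
#' versioned table shipped with the package (see the file header for the
#' source citation).
#'
#' @return Tibble with columns `wavelength_nm`, `hbo`, `hbr`.
#' @export
extinction_coefficients <- function() {
  path <- system.file("extdata", "extinction_coefficients.tsv",
    package = "dyadsync", mustWork = TRUE
  )
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
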