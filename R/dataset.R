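#' Replicate-structured light-response dataset
#'
#' Container for one light-response experiment: a long table with one row
#' per light step per replicate, plus scalar metadata. Recognised channel
#' columns (all optional beyond `i`):
#' `pn` (net CO2 assimilation, umol m^-2 s^-1), `j` (electron transport
#' rate, umol m^-2 s^-1), `phipsii` (PSII operating efficiency), `npq`
#' (non-photochemical quenching), `gs` (stomatal conductance to water,
#' mol m^-2 s^-1), `tr` (transpiration, mmol m^-2 s^-1), `ci`
#' (intercellular CO2, umol mol^-1), and the derived efficiency channels
#' added by [derive_channels()]. Unknown columns are kept as extras.
#'
#' @param data A data.frame with at least a numeric `i` column (irradiance,
#'   umol photons m^-2 s^-1, >= 0). A `replicate` column is added (single
#'   replicate) when absent.
#' @param leaf_area Measured leaf area, m^2 (default the 2 cm^2 chamber of
#'   a leaf-chamber fluorometer).
#' @param chl Chlorophyll content, mg m^-2 (optional; needed for pigment
#'   derivations).
#' @param ca Chamber CO2 concentration, umol mol^-1.
#' @param extra_metadata Named list of further metadata kept verbatim.
#' @return An object of class `"lrc_dataset"`: a list with elements
#'   `data` (the validated table) and `metadata`.
#' @examples
#' d <- light_response_dataset(data.frame(
#'   i = c(0, 50, 100, 200, 400, 800),
#'   pn = c(-3.4, -0.2, 2.1, 6.0, 12.0, 18.0)))
#' @export
light_response_dataset <- function(data, leaf_area = 2e-4, chl = NULL,
                                   ca = 390, extra_metadata = list()) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (!"i" %in% names(data)) {
    stop("dataset must contain an irradiance column `i`", call. = FALSE)
  }
  bad <- which(!is.finite(data$i))
  if (length(bad) > 0) {
    warning("dropping ", length(bad), " row(s) with missing irradiance (rows ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "", ")")
    data <- data[-bad, , drop = FALSE]
  }
  if (any(data$i < 0)) stop("irradiance must be >= 0", call. = FALSE)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  n_steps <- tapply(data$i, data$replicate, function(x) length(unique(x)))
  if (any(n_steps < 5)) {
    stop("each replicate must cover at least 5 distinct light steps",
         call. = FALSE)
  }
  meta <- c(list(leaf_area = leaf_area, chl = chl, ca = ca), extra_metadata)
  structure(list(data = data, metadata = meta), class = "lrc_dataset")
}

#' @export
print.lrc_dataset <- function(x, ...) {
  d <- x$data
  cat("Light-response dataset:",
      length(unique(d$replicate)), "replicate(s),",
      length(unique(d$i)), "light steps,",
      "channels:", paste(setdiff(names(d), c("i", "replicate")), collapse = ", "),
      "\n")
  invisible(x)
}

channels_of <- function(dataset) {
  setdiff(names(dataset$data), c("i", "replicate"))
}

require_channel <- function(dataset, channel) {
  if (!channel %in% names(dataset$data)) {
    stop("channel `", channel, "` not present in dataset (has: ",
         paste(channels_of(dataset), collapse = ", "), ")", call. = FALSE)
  }
  invisible(dataset)
}

#' Default gas-exchange instrument column map
#'
#' Maps the column headers written by common portable photosynthesis
#' systems onto the package's channel names.
#'
#' @return A named character vector, `names` = instrument header,
#'   value = package channel name.
#' @export
instrument_column_map <- function() {
  c(PARi = "i", Photo = "pn", ETR = "j", Cond = "gs", Trmmol = "tr",
    Ci = "ci", PhiPS2 = "phipsii", NPQ = "npq")
}

#' Read a light-response dataset from delimited text
#'
#' Reads a CSV export with a header row, renames instrument columns via
#' `column_map`, and validates the result. Columns not covered by the map
#' are preserved as extras with a warning. Rows are stored in file order;
#' fitting is order-independent.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping file headers to channel
#'   names; defaults to [instrument_column_map()] (a file already using the
#'   package names needs no mapping).
#' @param ... Passed on to [light_response_dataset()] (metadata).
#' @return An `lrc_dataset`.
#' @export
read_dataset <- function(path, column_map = instrument_column_map(), ...) {
  raw <- utils::read.csv(path, check.names = FALSE)
  hit <- names(raw) %in% names(column_map)
  names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  known <- c("i", "replicate", "pn", "j", "phipsii", "npq", "gs", "tr", "ci",
             "lue", "ce", "wue_i", "wue_inst")
  extras <- setdiff(names(raw), known)
  if (length(extras) > 0) {
    warning("unrecognised column(s) kept as extras: ",
            paste(extras, collapse = ", "))
  }
  if (!"i" %in% names(raw)) {
    stop("no irradiance column found (expected `i` or an instrument header ",
         "covered by `column_map`)", call. = FALSE)
  }
  light_response_dataset(raw, ...)
}

#' Write a light-response dataset to CSV
#'
#' Writes the long table in the same dialect [read_dataset()] reads, so a
#' write/read round trip reproduces the dataset.
#'
#' @param dataset An `lrc_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "lrc_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE)
  invisible(path)
}
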