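#' Standard 8 x 8 MEA channel map
#'
#' Builds the electrode layout of a 60-electrode planar MEA: an 8 x 8 grid
#' with the four corner positions unpopulated and one electrode wired as the
#' internal reference, leaving 59 usable recording/stimulation electrodes at a
#' 200 um pitch. Electrode identifiers follow the column-row convention of
#' commercial layouts (`"E<col><row>"`), so the reference defaults to `"E15"`
#' (column 1, row 5).
#'
#' @param spacing_um Centre-to-centre electrode pitch in micrometres.
#' @param reference Identifier of the electrode wired as reference; it must
#'   not be one of the (absent) corner positions.
#' @return An object of class `mea_channel_map`: a data frame with columns
#'   `electrode_id`, `row`, `col` and `role` (`"recording"` or
#'   `"reference"`), with the pitch stored in attribute `spacing_um`.
#' @examples
#' map <- mea_channel_map()
#' sum(map$role == "recording") # 59
#' @export
mea_channel_map <- function(spacing_um = 200, reference = "E15") {
  grid <- expand.grid(row = 1:8, col = 1:8)
  corners <- with(grid, (row %in% c(1, 8)) & (col %in% c(1, 8)))
  grid <- grid[!corners, , drop = FALSE]
  grid$electrode_id <- sprintf("E%d%d", grid$col, grid$row)
  if (!reference %in% grid$electrode_id) {
    stop("reference electrode '", reference, "' is not a populated grid position",
         call. = FALSE)
  }
  grid$role <- ifelse(grid$electrode_id == reference, "reference", "recording")
  grid <- grid[order(grid$col, grid$row), c("electrode_id", "row", "col", "role")]
  rownames(grid) <- NULL
  structure(grid, spacing_um = spacing_um, class = c("mea_channel_map", "data.frame"))
}

#' Recording electrodes of a channel map
#'
#' @param map A [mea_channel_map()].
#' @return Character vector of the 59 recording electrode identifiers.
#' @export
recording_channels <- function(map) {
  stopifnot(inherits(map, "mea_channel_map"))
  map$electrode_id[map$role == "recording"]
}

#' Channels surrounding a stimulation electrode
#'
#' Returns the recording electrodes in the 8-neighbourhood (Chebyshev
#' distance 1) of the given electrode. Grid positions that are unpopulated
#' (the four corners) or wired as reference are omitted, so edge electrodes
#' return five or fewer neighbours. These are the channels on which responses
#' to electrical stimulation are evaluated.
#'
#' @param stim_electrode Identifier of the stimulation electrode.
#' @param map A [mea_channel_map()].
#' @return Character vector of neighbouring recording electrode identifiers.
#' @examples
#' adjacent_channels("E44", mea_channel_map()) # 8 interior neighbours
#' @export
adjacent_channels <- function(stim_electrode, map) {
  stopifnot(inherits(map, "mea_channel_map"))
  i <- match(stim_electrode, map$electrode_id)
  if (is.na(i)) {
    stop("unknown electrode '", stim_electrode, "'", call. = FALSE)
  }
  dr <- abs(map$row - map$row[i])
  dc <- abs(map$col - map$col[i])
  nb <- dr <= 1 & dc <= 1 & !(dr == 0 & dc == 0) & map$role == "recording"
  map$electrode_id[nb]
}
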