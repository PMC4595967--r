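#' Assemble a recording session
#'
#' A session bundles position tracking, per-cell spike trains and cell
#' metadata, and is the universal input to the analysis pipeline.
#'
#' @param positions data.frame with columns `t_s` (seconds, strictly
#'   increasing), `x_cm`, `y_cm` (room-frame cm) and `hd_deg` (head
#'   direction, degrees in `[0, 360)`).
#' @param spikes either a named list of numeric spike-time vectors (seconds,
#'   sorted; names are cell ids) or a data.frame with columns `cell_id`,
#'   `t_s`.
#' @param cells data.frame with columns `cell_id`, `region` (`"V1"` or
#'   `"CA1"`), `layer` (`"L2/3"`, `"L4"`, `"L5/6"` or `"unassigned"`) and
#'   `day` (recording-day integer).
#' @param track_length_cm linearized trajectory length in cm.
#' @param metadata optional list (animal id, notes, ...).
#'
#' @return An object of class `track_session`.
#' @export
track_session <- function(positions, spikes, cells, track_length_cm = 300,
                          metadata = list()) {
  stopifnot(is.data.frame(positions),
            all(c("t_s", "x_cm", "y_cm", "hd_deg") %in% names(positions)))
  if (nrow(positions) < 2L) stop("need at least 2 position samples")
  if (any(diff(positions$t_s) <= 0)) stop("position timestamps must be strictly increasing")
  if (is.data.frame(spikes)) {
    stopifnot(all(c("cell_id", "t_s") %in% names(spikes)))
    spikes <- split(spikes$t_s, as.character(spikes$cell_id))
  }
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "region", "layer", "day") %in% names(cells)))
  bad <- setdiff(cells$region, c("V1", "CA1"))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  missing_meta <- setdiff(names(spikes), as.character(cells$cell_id))
  if (length(missing_meta))
    stop("spike trains without cell metadata: ", paste(missing_meta, collapse = ", "))
  # clip spikes to the tracked time range
  rng <- range(positions$t_s)
  spikes <- lapply(spikes, function(x) x[x >= rng[1] & x <= rng[2]])
  structure(list(positions = positions, spikes = spikes,
                 cells = cells, track_length_cm = track_length_cm,
                 metadata = metadata),
            class = "track_session")
}

#' @export
print.track_session <- function(x, ...) {
  dur <- diff(range(x$positions$t_s))
  cat("<track_session>", nrow(x$positions), "position samples,",
      sprintf("%.1f min;", dur / 60), length(x$spikes), "cells (",
      sum(x$cells$region == "V1"), "V1 /", sum(x$cells$region == "CA1"),
      "CA1 ); track", x$track_length_cm, "cm\n")
  invisible(x)
}

#' Read a session from CSV files
#'
#' Expects `positions.csv` (`t_s,x_cm,y_cm,hd_deg`), `spikes.csv`
#' (`cell_id,t_s`) and `cells.csv` (`cell_id,region,layer,day`) in `dir`.
#'
#' @param dir directory containing the three CSV files.
#' @param track_length_cm trajectory length in cm.
#' @return A [track_session()].
#' @export
read_session <- function(dir, track_length_cm = 300) {
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  spk <- utils::read.csv(file.path(dir, "spikes.csv"))
  cel <- utils::read.csv(file.path(dir, "cells.csv"))
  track_session(pos, spk, cel, track_length_cm = track_length_cm)
}

#' Write a session to CSV files
#'
#' Inverse of [read_session()].
#'
#' @param session a [track_session()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$positions, file.path(dir, "positions.csv"),
                   row.names = FALSE)
  spk <- data.frame(
    cell_id = rep(names(session$spikes), lengths(session$spikes)),
    t_s = unlist(session$spikes, use.names = FALSE))
  utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
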