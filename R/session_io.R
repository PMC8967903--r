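# Plain-text persistence for session bundles and trial matrices: a bundle is a
# directory of CSV arrays plus a JSON metadata file, so runs are portable and
# diffable. The stimulus table round-trips as a standalone CSV.

#' Write a session bundle to a directory
#'
#' Layout: `dff.csv` (neurons x frames, row names = neuron ids), `speed.csv`,
#' `pupil.csv`, `stim_table.csv` (columns epoch_type, start_frame, end_frame,
#' direction, temporal_frequency; frames 0-based inclusive-exclusive),
#' optional `truth.csv`, and `meta.json`.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(neuron_id = rownames(bundle$dff), bundle$dff,
                       check.names = FALSE),
            file.path(dir, "dff.csv"), row.names = FALSE)
  write.csv(data.frame(speed = bundle$speed), file.path(dir, "speed.csv"), row.names = FALSE)
  write.csv(data.frame(pupil = bundle$pupil), file.path(dir, "pupil.csv"), row.names = FALSE)
  write.csv(bundle$stim_table, file.path(dir, "stim_table.csv"), row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    tr$shared_gain_sd <- attr(bundle$truth, "shared_gain_sd")
    write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  meta <- list(frame_rate = bundle$frame_rate, region = bundle$region,
               layer = bundle$layer, session_id = bundle$session_id)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir bundle directory.
#' @return a `session_bundle`.
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  dffdf <- read.csv(file.path(dir, "dff.csv"), check.names = FALSE)
  dff <- as.matrix(dffdf[, -1, drop = FALSE])
  rownames(dff) <- dffdf$neuron_id
  dimnames(dff)[[2]] <- NULL
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
    attr(truth, "shared_gain_sd") <- truth$shared_gain_sd[1]
    truth$shared_gain_sd <- NULL
  }
  bundle <- structure(list(
    dff = dff,
    speed = read.csv(file.path(dir, "speed.csv"))$speed,
    pupil = read.csv(file.path(dir, "pupil.csv"))$pupil,
    stim_table = read.csv(file.path(dir, "stim_table.csv"), stringsAsFactors = FALSE),
    frame_rate = meta$frame_rate, region = meta$region, layer = meta$layer,
    session_id = meta$session_id, truth = truth, config = NULL
  ), class = "session_bundle")
  validate_session_bundle(bundle)
  bundle
}
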