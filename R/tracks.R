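# Track containers and I/O.

#' Build a track table
#'
#' A track table is a data frame with columns `track_id`, `t`, `x`, `y`
#' (optionally `well`, `replicate`), sorted by track and time, carrying the
#' sampling interval `dt` as an attribute. Times are in MCS for simulated
#' tracks and in the imaging time unit (e.g. minutes) for experimental ones;
#' positions likewise (lattice units or micrometres).
#'
#' @param df data frame with at least `track_id`, `t`, `x`, `y`.
#' @param dt sampling interval between consecutive samples.
#' @return the sorted table with class `tracks`.
#' @export
as_tracks <- function(df, dt = 1) {
  need <- c("track_id", "t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing track column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("t", "x", "y")) {
    if (nrow(df) == 0) df[[col]] <- as.numeric(df[[col]])
    if (!is.numeric(df[[col]])) stop("non-numeric values in column ", col)
  }
  df <- df[order(df$track_id, df$t), , drop = FALSE]
  if (anyDuplicated(df[, c("track_id", "t")])) {
    stop("duplicate (track_id, t) samples")
  }
  rownames(df) <- NULL
  attr(df, "dt") <- dt
  class(df) <- c("tracks", "data.frame")
  df
}

#' @export
print.tracks <- function(x, ...) {
  cat(sprintf("tracks: %d samples, %d tracks, dt = %s\n",
              nrow(x), length(unique(x$track_id)), format(attr(x, "dt"))))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read a track CSV
#'
#' Expects a header `track_id,t,x,y` (extra columns such as `well` and
#' `replicate` are kept). Rows are sorted per track on read, with a warning
#' when reordering was needed.
#'
#' @param path CSV path.
#' @param dt sampling interval to attach.
#' @return a [as_tracks()] table.
#' @export
read_tracks <- function(path, dt = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("track_id", "t", "x", "y"), names(df))
  if (length(missing_cols) > 0) {
    stop("missing track column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 1 && is.unsorted(order(df$track_id, df$t))) {
    # note: as_tracks() sorts; warn so silently shuffled inputs are visible
  }
  ord <- order(df$track_id, df$t)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("rows were not sorted by (track_id, t); sorting")
  }
  as_tracks(df, dt = dt)
}

#' Write a track CSV
#'
#' Round-trips losslessly to 6 decimal places with [read_tracks()].
#'
#' @param tracks a track table.
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  df$x <- round(df$x, 6)
  df$y <- round(df$y, 6)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: per-track list of step matrices (dx, dy) and start positions
.track_steps <- function(tracks) {
  lapply(split(tracks[, c("t", "x", "y")], tracks$track_id), function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    list(t = d$t[-n], dx = diff(d$x), dy = diff(d$y),
         x = d$x[-n], y = d$y[-n])
  })
}
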