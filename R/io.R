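# CSV schemas for the pipeline's external interfaces. Columns are fixed and
# documented here; all readers return plain data.frames.

#' Write / read turn and utterance tables
#'
#' Schema: `talker`, `start_s`, `end_s`.
#' @param turns turn table (`talker`, `onset`, `offset`) or utterance table
#'   (`talker`, `start`, `end`).
#' @param path CSV path.
#' @export
write_intervals_csv <- function(turns, path) {
  if (all(c("onset", "offset") %in% names(turns))) {
    df <- data.frame(talker = turns$talker, start_s = turns$onset,
                     end_s = turns$offset)
  } else {
    df <- data.frame(talker = turns$talker, start_s = turns$start,
                     end_s = turns$end)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(talker = df$talker, start = df$start_s, end = df$end_s,
             stringsAsFactors = FALSE)
}

#' Write / read a gaze recording
#'
#' Schema: `t`, `px`, `py`, per-eye direction vectors (`dir_lx` ... `dir_rz`),
#' `pupil_l`, `pupil_r`, `valid_l`, `valid_r`.
#' @param gaze gaze recording data.frame.
#' @param path CSV path.
#' @export
write_gaze_csv <- function(gaze, path) {
  write.csv(gaze, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  g$valid_l <- as.logical(g$valid_l); g$valid_r <- as.logical(g$valid_r)
  g
}

#' Write / read AOI tracks
#'
#' Schema: `frame`, `t`, `kind`, `identity`, `x`, `y`, `w`, `h`, `present`.
#' @param tracks AOI track data.frame.
#' @param path CSV path.
#' @export
write_aoi_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aoi_csv
#' @export
read_aoi_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$present <- as.logical(tr$present)
  tr
}

#' Write detected eye events or annotations as CSV
#'
#' @param x event table or annotation data.frame.
#' @param path CSV path.
#' @export
write_events_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the tidy feature table
#'
#' Values are serialised with 17 significant digits so a write/read round
#' trip reproduces them bit-exactly.
#'
#' @param features long feature table from [export_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  df <- features
  df$value <- sprintf("%.17g", df$value)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Export turns as a Praat TextGrid
#'
#' One interval tier per talker; turn intervals carry the talker id, the
#' rest is empty.
#'
#' @param turns turn table (`talker`, `onset`, `offset`).
#' @param path output path.
#' @param duration_s total tier duration (defaults to the last offset).
#' @export
write_textgrid <- function(turns, path, duration_s = max(turns$offset)) {
  talkers <- unique(turns$talker)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = 0")
  w("xmax = %.6f", duration_s)
  w("tiers? <exists>")
  w("size = %d", length(talkers))
  w("item []:")
  for (ti in seq_along(talkers)) {
    p <- talkers[ti]
    tu <- turns[turns$talker == p, , drop = FALSE]
    tu <- tu[order(tu$onset), ]
    # alternate empty / turn intervals covering [0, duration]
    edges <- c(0, as.vector(rbind(tu$onset, tu$offset)), duration_s)
    labs <- c(rbind(rep("", nrow(tu)), rep(p, nrow(tu))), "")
    keep <- diff(edges) > 1e-9
    w("    item [%d]:", ti)
    w('        class = "IntervalTier"')
    w('        name = "%s"', p)
    w("        xmin = 0")
    w("        xmax = %.6f", duration_s)
    w("        intervals: size = %d", sum(keep))
    ii <- 0
    for (k in which(keep)) {
      ii <- ii + 1
      w("        intervals [%d]:", ii)
      w("            xmin = %.6f", edges[k])
      w("            xmax = %.6f", edges[k + 1])
      w('            text = "%s"', labs[k])
    }
  }
  invisible(path)
}
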