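#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is the temporal grid shared by every time-activity curve
#' (TAC) in an analysis: the start and end time of each acquisition frame, in
#' seconds from injection.  Frames must be sorted, strictly positive in
#' duration and non-overlapping (small gaps are allowed).
#'
#' @param start numeric vector of frame start times (seconds).
#' @param end numeric vector of frame end times (seconds), same length.
#' @return An object of class `frame_schedule` with fields `start`, `end`
#'   and `n_frames`.
#' @examples
#' sch <- frame_schedule(c(0, 30, 60), c(30, 60, 120))
#' frame_mid(sch)
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end))
    stop("frame start/end vectors differ in length")
  n <- length(start)
  if (n < 2L) stop("a frame schedule needs at least 2 frames")
  if (anyNA(start) || anyNA(end) || !all(is.finite(c(start, end))))
    stop("frame times must be finite")
  if (any(end <= start))
    stop("every frame must satisfy end > start; offending frame(s): ",
         paste(which(end <= start), collapse = ", "))
  if (is.unsorted(start, strictly = TRUE))
    stop("frames must be sorted by strictly increasing start time")
  if (any(start[-1L] < end[-n] - 1e-9))
    stop("overlapping frames: frame ", which(start[-1L] < end[-n] - 1e-9)[1L] + 1L,
         " starts before the previous frame ends")
  structure(list(start = start, end = end, n_frames = n),
            class = "frame_schedule")
}

#' Frame midpoints and durations
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector, seconds.
#' @export
frame_mid <- function(schedule) (schedule$start + schedule$end) / 2

#' @rdname frame_mid
#' @export
frame_dur <- function(schedule) schedule$end - schedule$start

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f-%.0f s (%.1f min total)\n",
              x$n_frames, x$start[1L], x$end[x$n_frames],
              (x$end[x$n_frames] - x$start[1L]) / 60))
  invisible(x)
}

#' Test two schedules for exact equality
#'
#' Training and testing data must share one temporal grid; no interpolation
#' is ever attempted.
#'
#' @param a,b frame schedules.
#' @return logical scalar.
#' @export
same_schedule <- function(a, b) {
  a$n_frames == b$n_frames &&
    isTRUE(all.equal(a$start, b$start, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$end, b$end, tolerance = 1e-9))
}

#' Read a frame timing sidecar file
#'
#' Two dialects are accepted and converted to start/end seconds:
#' a two-column CSV with headers `frame_start`,`frame_end` (or the first two
#' columns if unnamed), and a BIDS-style JSON object with
#' `FrameTimesStart` and `FrameDuration` arrays.  Use `unit = "min"` when the
#' file is expressed in minutes.
#'
#' @param path file path (.csv/.tsv or .json).
#' @param unit `"s"` (default) or `"min"`.
#' @return a [frame_schedule()].
#' @export
read_frame_schedule <- function(path, unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("timing file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$FrameTimesStart) || is.null(j$FrameDuration))
      stop("JSON timing file must carry FrameTimesStart and FrameDuration")
    start <- as.numeric(j$FrameTimesStart)
    end <- start + as.numeric(j$FrameDuration)
  } else {
    tab <- utils::read.csv(path, sep = if (ext == "tsv") "\t" else ",")
    cols <- if (all(c("frame_start", "frame_end") %in% names(tab)))
      tab[c("frame_start", "frame_end")] else tab[1:2]
    start <- as.numeric(cols[[1L]])
    end <- as.numeric(cols[[2L]])
  }
  f <- if (unit == "min") 60 else 1
  frame_schedule(start * f, end * f)
}

#' Write a frame timing CSV
#'
#' @param schedule a [frame_schedule()].
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.csv(
    data.frame(frame_start = schedule$start, frame_end = schedule$end),
    path, row.names = FALSE)
  invisible(path)
}

#' Default 49-minute TSPO acquisition schedule
#'
#' 6 x 30 s, 8 x 120 s, 6 x 300 s frames (20 frames, 2940 s), the phantom
#' simulator's default.
#' @return a [frame_schedule()].
#' @export
default_schedule <- function() {
  dur <- c(rep(30, 6), rep(120, 8), rep(300, 6))
  end <- cumsum(dur)
  frame_schedule(end - dur, end)
}
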