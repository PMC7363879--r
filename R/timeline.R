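# Gaze timelines: ordered, non-overlapping AOI segments covering a trial at
# millisecond resolution.  Gaps in the raw fixation record (saccades, blinks,
# track loss) become NEITHER segments.

#' Build a gap-free gaze timeline from fixation segments
#'
#' Sorts the supplied fixations, rejects overlaps, and fills every uncovered
#' interval of `[0, trial_duration]` with `NEITHER` segments so the returned
#' timeline is contiguous.
#'
#' @param fixations A data.frame with columns `aoi`, `onset`, `offset`
#'   (milliseconds; `onset_ms`/`offset_ms` are accepted as synonyms).  May be
#'   empty.
#' @param trial_duration Trial duration in ms the timeline must cover.
#' @return A data.frame with class `"gaze_timeline"` and columns `aoi`,
#'   `onset`, `offset`, contiguous from 0 to `trial_duration`.
#' @examples
#' build_timeline(data.frame(aoi = "SELF", onset = 100, offset = 300), 500)
#' @export
build_timeline <- function(fixations, trial_duration) {
  if (!is.numeric(trial_duration) || length(trial_duration) != 1 ||
      trial_duration <= 0) {
    stop("trial_duration must be a positive duration in ms", call. = FALSE)
  }
  if (is.null(fixations) || nrow(as.data.frame(fixations)) == 0) {
    out <- data.frame(aoi = "NEITHER", onset = 0, offset = trial_duration,
                      stringsAsFactors = FALSE)
    class(out) <- c("gaze_timeline", "data.frame")
    return(out)
  }
  fx <- as.data.frame(fixations)
  if ("onset_ms" %in% names(fx) && !"onset" %in% names(fx)) {
    fx$onset <- fx$onset_ms
    fx$offset <- fx$offset_ms
  }
  stopifnot(all(c("aoi", "onset", "offset") %in% names(fx)))
  fx$aoi <- toupper(as.character(fx$aoi))
  if (any(!fx$aoi %in% AOI_LEVELS)) {
    stop("aoi labels must be SELF, OTHER or NEITHER", call. = FALSE)
  }
  if (any(fx$onset < 0 | fx$onset >= fx$offset)) {
    stop("fixations require 0 <= onset < offset", call. = FALSE)
  }
  fx <- fx[order(fx$onset), c("aoi", "onset", "offset")]
  if (nrow(fx) > 1 && any(fx$onset[-1] < fx$offset[-nrow(fx)])) {
    stop("overlapping fixations in timeline input", call. = FALSE)
  }
  # fill gaps (and the leading/trailing uncovered intervals) with NEITHER
  pieces <- vector("list", 2 * nrow(fx) + 1)
  cursor <- 0
  j <- 0
  for (i in seq_len(nrow(fx))) {
    if (fx$onset[i] > cursor) {
      j <- j + 1
      pieces[[j]] <- data.frame(aoi = "NEITHER", onset = cursor,
                                offset = fx$onset[i])
    }
    j <- j + 1
    pieces[[j]] <- fx[i, ]
    cursor <- fx$offset[i]
  }
  if (cursor < trial_duration) {
    j <- j + 1
    pieces[[j]] <- data.frame(aoi = "NEITHER", onset = cursor,
                              offset = trial_duration)
  }
  out <- do.call(rbind, pieces[seq_len(j)])
  rownames(out) <- NULL
  # merge adjacent segments with the same label
  keep <- c(TRUE, out$aoi[-1] != out$aoi[-nrow(out)])
  if (!all(keep)) {
    grp <- cumsum(keep)
    out <- data.frame(aoi = out$aoi[keep],
                      onset = tapply(out$onset, grp, min)[unique(grp)],
                      offset = tapply(out$offset, grp, max)[unique(grp)],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  class(out) <- c("gaze_timeline", "data.frame")
  out
}

#' First informative fixation of a trial
#'
#' Returns the AOI of the first `SELF` or `OTHER` segment lasting at least
#' `min_duration` ms; shorter fixations are ignored.
#'
#' @param timeline A gaze timeline (see [build_timeline()]).
#' @param min_duration Minimum fixation duration in ms (default 100).
#' @return `"SELF"`, `"OTHER"`, or `"NONE"` if no qualifying fixation exists.
#' @export
first_fixation <- function(timeline, min_duration = 100) {
  tl <- as.data.frame(timeline)
  ok <- tl$aoi %in% c("SELF", "OTHER") &
    (tl$offset - tl$onset) >= min_duration
  if (!any(ok)) return("NONE")
  tl$aoi[which(ok)[1]]
}

#' Extend a gaze timeline to a longer horizon
#'
#' Continues the timeline so it covers `to_ms`, by alternating between the
#' two AOIs starting opposite to the last fixated one, with a fixed segment
#' duration.  This is the deterministic extrapolation policy used when
#' observed gaze is shorter than a simulation horizon; the synthetic-data
#' generator extends its own timelines stochastically at generation time.
#'
#' @param timeline A gaze timeline.
#' @param to_ms Target coverage in ms.
#' @param segment_ms Duration of appended alternating fixations (default 250).
#' @return The extended `"gaze_timeline"`.
#' @export
extend_timeline <- function(timeline, to_ms, segment_ms = 250) {
  tl <- as.data.frame(timeline)
  end <- max(tl$offset)
  if (end >= to_ms) {
    class(tl) <- c("gaze_timeline", "data.frame")
    return(tl)
  }
  fixated <- tl$aoi[tl$aoi != "NEITHER"]
  last <- if (length(fixated) > 0) fixated[length(fixated)] else "OTHER"
  cur <- if (last == "SELF") "OTHER" else "SELF"
  add <- list()
  while (end < to_ms) {
    nxt <- min(end + segment_ms, to_ms)
    add[[length(add) + 1]] <- data.frame(aoi = cur, onset = end, offset = nxt)
    end <- nxt
    cur <- if (cur == "SELF") "OTHER" else "SELF"
  }
  out <- rbind(tl, do.call(rbind, add))
  rownames(out) <- NULL
  class(out) <- c("gaze_timeline", "data.frame")
  out
}

#' Split a fixations table into per-trial gaze timelines
#'
#' @param fixations A fixations table (see [addm_fixations()]).
#' @param trials A trials table; one timeline is built per trial, covering
#'   that trial's condition deadline.
#' @param extend If `TRUE`, timelines shorter than the deadline are extended
#'   with [extend_timeline()]; otherwise they are padded with `NEITHER` (the
#'   default `build_timeline()` behaviour covers the deadline already).
#' @return A list of `"gaze_timeline"` objects in the row order of `trials`,
#'   named `subject.trial`.
#' @export
timelines_from_fixations <- function(fixations, trials, extend = FALSE) {
  fx <- as.data.frame(fixations)
  tr <- as.data.frame(trials)
  key_fx <- paste(fx$subject, fx$trial, sep = ".")
  key_tr <- paste(tr$subject, tr$trial, sep = ".")
  idx <- split(seq_len(nrow(fx)), key_fx)
  out <- vector("list", nrow(tr))
  names(out) <- key_tr
  dur <- deadline_s(tr$condition) * 1000
  for (i in seq_len(nrow(tr))) {
    rows <- idx[[key_tr[i]]]
    segs <- if (is.null(rows)) NULL else fx[rows, ]
    tl <- build_timeline(segs, dur[i])
    if (extend) tl <- extend_timeline(tl, dur[i])
    out[[i]] <- tl
  }
  out
}

# timeline -> integer AOI codes + boundaries for the C++ core
timeline_codes <- function(timeline) {
  tl <- as.data.frame(timeline)
  list(aoi = match(tl$aoi, AOI_LEVELS) - 1L,
       onset = as.numeric(tl$onset),
       offset = as.numeric(tl$offset))
}
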