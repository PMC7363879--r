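# Trial and fixation tables, validation, and choice classification.
#
# A trials table has one row per trial with columns
#   subject, trial, self, other, condition (HIGH/LOW),
#   choice (ACCEPT/REJECT/MISSED), rt (s, NA iff MISSED)
# and a fixations table has one row per AOI fixation with columns
#   subject, trial, aoi (SELF/OTHER/NEITHER), onset_ms, offset_ms.
# Proposal amounts are dollars in [0, 100] offered against the fixed $50/$50
# default; gaze is millisecond-resolved, RTs are in seconds.

TRIAL_COLS <- c("subject", "trial", "self", "other", "condition", "choice", "rt")
FIX_COLS <- c("subject", "trial", "aoi", "onset_ms", "offset_ms")
AOI_LEVELS <- c("NEITHER", "SELF", "OTHER")
CHOICE_LEVELS <- c("ACCEPT", "REJECT", "MISSED")

#' Construct and validate a trials table
#'
#' Checks the schema used throughout the package: proposal amounts within
#' $0--$100, conditions `HIGH`/`LOW`, choices `ACCEPT`/`REJECT`/`MISSED`,
#' reaction times present exactly for responded trials and never exceeding the
#' condition's deadline, and unique trial indices within subject.
#'
#' @param data A data.frame with columns `subject`, `trial`, `self`, `other`,
#'   `condition`, `choice`, `rt`.
#' @return The validated data.frame with class `"addm_trials"`.
#' @examples
#' addm_trials(data.frame(subject = "s1", trial = 1, self = 40, other = 70,
#'                        condition = "HIGH", choice = "ACCEPT", rt = 0.85))
#' @export
addm_trials <- function(data) {
  missing_cols <- setdiff(TRIAL_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("trials table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[TRIAL_COLS]
  data$subject <- as.character(data$subject)
  data$trial <- as.integer(data$trial)
  data$self <- as.numeric(data$self)
  data$other <- as.numeric(data$other)
  data$condition <- toupper(as.character(data$condition))
  data$choice <- toupper(as.character(data$choice))
  data$rt <- suppressWarnings(as.numeric(data$rt))

  problems <- character(0)
  bad <- function(test, msg) {
    idx <- which(test)
    if (length(idx) > 0) {
      problems <<- c(problems,
                     paste0(msg, " (row", if (length(idx) > 1) "s" else "",
                            " ", paste(head(idx, 10), collapse = ", "),
                            if (length(idx) > 10) ", ..." else "", ")"))
    }
  }
  bad(is.na(data$self) | data$self < 0 | data$self > 100,
      "self amount outside $0-$100")
  bad(is.na(data$other) | data$other < 0 | data$other > 100,
      "other amount outside $0-$100")
  bad(!data$condition %in% names(DEADLINES), "condition not HIGH/LOW")
  bad(!data$choice %in% CHOICE_LEVELS, "choice not ACCEPT/REJECT/MISSED")
  bad(data$choice == "MISSED" & !is.na(data$rt), "MISSED trial with an rt")
  bad(data$choice != "MISSED" & is.na(data$rt), "responded trial without rt")
  ok_cond <- data$condition %in% names(DEADLINES)
  dl <- rep(NA_real_, nrow(data))
  dl[ok_cond] <- deadline_s(data$condition[ok_cond])
  bad(!is.na(data$rt) & !is.na(dl) & (data$rt <= 0 | data$rt > dl),
      "rt non-positive or exceeding the condition deadline")
  dup <- duplicated(data[c("subject", "trial")])
  bad(dup, "duplicated subject/trial index")
  if (length(problems) > 0) {
    stop("invalid trials table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  class(data) <- c("addm_trials", "data.frame")
  data
}

#' Read a trials table from CSV
#'
#' @param path Path to a UTF-8, comma-delimited file with header
#'   `subject,trial,self,other,condition,choice,rt`.  The `rt` field is empty
#'   for missed trials.
#' @return A validated `"addm_trials"` data.frame.
#' @seealso [write_trials()], [addm_trials()]
#' @export
read_trials <- function(path) {
  addm_trials(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trials table to CSV
#'
#' @param trials A trials table (see [addm_trials()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- addm_trials(trials)
  write.csv(as.data.frame(trials), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Construct and validate a fixations table
#'
#' @param data A data.frame with columns `subject`, `trial`, `aoi`,
#'   `onset_ms`, `offset_ms`.  AOI labels are `SELF`, `OTHER` or `NEITHER`;
#'   onsets/offsets are milliseconds from trial onset with
#'   `0 <= onset < offset`.
#' @return The validated data.frame with class `"addm_fixations"`.
#' @export
addm_fixations <- function(data) {
  missing_cols <- setdiff(FIX_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("fixations table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[FIX_COLS]
  data$subject <- as.character(data$subject)
  data$trial <- as.integer(data$trial)
  data$aoi <- toupper(as.character(data$aoi))
  data$onset_ms <- as.numeric(data$onset_ms)
  data$offset_ms <- as.numeric(data$offset_ms)
  if (any(!data$aoi %in% AOI_LEVELS)) {
    stop("fixation aoi labels must be SELF, OTHER or NEITHER", call. = FALSE)
  }
  if (any(is.na(data$onset_ms) | is.na(data$offset_ms) |
          data$onset_ms < 0 | data$onset_ms >= data$offset_ms)) {
    stop("fixations require 0 <= onset_ms < offset_ms", call. = FALSE)
  }
  class(data) <- c("addm_fixations", "data.frame")
  data
}

#' Read a fixations table from CSV
#'
#' @param path Path to a UTF-8, comma-delimited file with header
#'   `subject,trial,aoi,onset_ms,offset_ms`.
#' @return A validated `"addm_fixations"` data.frame.
#' @export
read_fixations <- function(path) {
  addm_fixations(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a fixations table to CSV
#'
#' @param fixations A fixations table (see [addm_fixations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  fixations <- addm_fixations(fixations)
  write.csv(as.data.frame(fixations), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Classify responses as generous, selfish, neutral or missed
#'
#' A response is generous when it sacrifices own payoff relative to the
#' $50/$50 default to the partner's benefit: accepting a proposal with
#' `self < 50 < other`, or rejecting one with `self > 50 > other`.  The
#' complementary responded cases are selfish.  Proposals that do not pit a
#' loss against a gain (both amounts on the same side of $50, or either
#' exactly $50) are neutral, and missed trials pass through as `MISSED`.
#'
#' @param self,other Proposal amounts in dollars (vectors recycled together).
#' @param choice Character vector, `ACCEPT`, `REJECT` or `MISSED`.
#' @return Character vector with values `GENEROUS`, `SELFISH`, `NEUTRAL`,
#'   `MISSED`.
#' @examples
#' classify_choice(40, 70, "ACCEPT")  # GENEROUS
#' classify_choice(70, 40, "ACCEPT")  # SELFISH
#' @export
classify_choice <- function(self, other, choice) {
  n <- max(length(self), length(other), length(choice))
  self <- rep_len(as.numeric(self), n)
  other <- rep_len(as.numeric(other), n)
  choice <- rep_len(toupper(as.character(choice)), n)
  out <- rep(NA_character_, n)
  out[choice == "MISSED"] <- "MISSED"
  tradeoff <- (self - DEFAULT_SPLIT) * (other - DEFAULT_SPLIT) < 0
  responded <- choice %in% c("ACCEPT", "REJECT")
  out[responded & !tradeoff] <- "NEUTRAL"
  gen <- responded & tradeoff &
    ((self < DEFAULT_SPLIT & choice == "ACCEPT") |
       (self > DEFAULT_SPLIT & choice == "REJECT"))
  out[gen] <- "GENEROUS"
  out[responded & tradeoff & !gen] <- "SELFISH"
  out
}

#' Direction of the generous response for a proposal
#'
#' @param self,other Proposal amounts in dollars.
#' @return Integer vector: `+1` when accepting is generous, `-1` when
#'   rejecting is generous, `0` when the proposal has no self/other trade-off.
#' @export
generous_direction <- function(self, other) {
  out <- integer(length(self))
  tradeoff <- (self - DEFAULT_SPLIT) * (other - DEFAULT_SPLIT) < 0
  out[tradeoff & self < DEFAULT_SPLIT] <- 1L
  out[tradeoff & self > DEFAULT_SPLIT] <- -1L
  out
}
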