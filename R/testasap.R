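## TEST-ASAP: three ecological subtasks embedded in a testing session,
## each with a three-level graded prompt ladder (initial indirect prompt ->
## indirect reformulation -> direct request) dissociating interaction
## cost, personal benefit, and norm compliance. A subject's response level
## records how far down the ladder the experimenter had to go:
##   0 - complies after the initial prompt
##   1 - complies after the indirect reformulation
##   2 - complies after the direct request
##   3 - never complies
## Responses map onto canonical trajectories over a 4 x 6 topological
## grid: (1,2) is task success, (2,2)/(2,3) the indirect-reformulation
## stage, (3,4)/(3,5) the direct-reformulation/clarification stage, and
## (4,6) task failure. The grid extent and the four paths are a package
## convention chosen so that every stage position is reachable and
## per-level occupancy fractions are expressible; intermediate positions
## are always visited in sequence.

TESTASAP_DIMS <- c(4L, 6L)

TESTASAP_SUBTASKS <- list(
  basket = list(
    name = "basket",
    prompts = c(
      initial = "It's badly sharpened. Here's a sharpener, but you'll need to fetch the garbage can to use it.",
      indirect_reformulation = "You should sharpen your pencil; you work better with a well-sharpened pencil.",
      direct_request = "Can you get me the wastebasket so I can sharpen my pencil?"),
    cost = "high", benefit = "low", norm_violation = FALSE),
  door = list(
    name = "door",
    prompts = c(
      initial = "Oh, I forgot to close the door!",
      indirect_reformulation = "We really should close that door.",
      direct_request = "Could you go and close the door, please?"),
    cost = "low", benefit = "low", norm_violation = FALSE),
  syllogism = list(
    name = "syllogism",
    prompts = c(
      initial = "That was the last test.",
      indirect_reformulation = "That was the last test, we are finished.",
      direct_request = "Since we have finished, can you go and get your parent now?"),
    cost = "low", benefit = "high", norm_violation = TRUE))

#' TEST-ASAP subtask specification
#'
#' Returns the protocol record for one of the three subtasks: its
#' three-level prompt ladder, cost/benefit labels, and whether compliance
#' entails a social-norm violation.
#'
#' @param name One of `"basket"`, `"door"`, `"syllogism"`.
#' @return List with elements `name`, `prompts` (length 3, ordered
#'   initial -> indirect reformulation -> direct request), `cost`,
#'   `benefit`, `norm_violation`.
#' @export
testasap_subtask <- function(name = c("basket", "door", "syllogism")) {
  TESTASAP_SUBTASKS[[match.arg(name)]]
}

#' Encode a graded-prompting response as a topological trajectory
#'
#' Maps a subject's response level to its canonical path across the
#' 4 x 6 grid. A clarification request (the subject asks about the task
#' before complying, e.g. "Should I close the door?") inserts the
#' clarification position (3,4) before compliance at any level >= 1 whose
#' path does not already pass through it.
#'
#' @param subtask Subtask name or a [testasap_subtask()] record.
#' @param level Integer response level in `0:3`.
#' @param clarification Logical clarification-request flag.
#' @param subject_id,group Identifiers carried on the result.
#' @return Data frame of class `outcome_trajectory` with columns
#'   `subject_id`, `group`, `subtask`, `x`, `y` (positions in visit
#'   order); terminal position is `(1,2)` iff `level <= 2`, else `(4,6)`.
#' @export
#' @examples
#' encode_response("door", level = 0)
#' encode_response("basket", level = 3)
encode_response <- function(subtask, level, clarification = FALSE,
                            subject_id = NA_character_,
                            group = NA_character_) {
  if (is.list(subtask)) subtask <- subtask$name
  subtask <- match.arg(subtask, names(TESTASAP_SUBTASKS))
  if (!level %in% 0:3) stop("unknown response level: ", level, call. = FALSE)
  path <- switch(as.character(level),
    "0" = list(c(1, 1), c(1, 2)),
    "1" = list(c(1, 1), c(2, 2), c(2, 3), c(1, 2)),
    "2" = list(c(1, 1), c(2, 2), c(2, 3), c(3, 4), c(3, 5), c(1, 2)),
    "3" = list(c(1, 1), c(2, 2), c(2, 3), c(3, 4), c(3, 5), c(4, 6)))
  if (isTRUE(clarification) && level >= 1 &&
      !any(vapply(path, function(p) all(p == c(3, 4)), logical(1)))) {
    path <- append(path, list(c(3, 4)), after = length(path) - 1L)
  }
  pos <- do.call(rbind, path)
  structure(
    data.frame(subject_id = subject_id, group = group, subtask = subtask,
               x = as.integer(pos[, 1]), y = as.integer(pos[, 2]),
               stringsAsFactors = FALSE),
    class = c("outcome_trajectory", "data.frame"))
}

#' Score a group of TEST-ASAP responses
#'
#' Encodes each subject's response level as a trajectory and aggregates
#' the group into an occupancy probability matrix over the 4 x 6 grid,
#' together with per-level compliance fractions.
#'
#' @param responses Data frame with columns `subject_id`, `level`, and
#'   optionally `group`, `subtask`, `clarification`.
#' @param subtask Subtask name; taken from `responses` when omitted.
#' @param dims Grid extent (default 4 x 6).
#' @return List of class `testasap_scores` with elements `occupancy` (an
#'   [occupancy()] matrix), `summary` (fractions per response level, the
#'   non-immediate-compliance fraction `prop_beyond_initial`, and the
#'   success/failure split), and `trajectories`.
#' @export
score_group <- function(responses, subtask = NULL, dims = TESTASAP_DIMS) {
  stopifnot(is.data.frame(responses), nrow(responses) >= 1L,
            all(c("subject_id", "level") %in% names(responses)))
  if (is.null(subtask)) {
    subtask <- unique(responses$subtask)
    if (length(subtask) != 1L)
      stop("responses mix subtasks; pass one subtask explicitly",
           call. = FALSE)
  }
  group <- if (!is.null(responses$group)) unique(responses$group)[1]
           else NA_character_
  clar <- if (!is.null(responses$clarification)) responses$clarification
          else rep(FALSE, nrow(responses))
  traj <- lapply(seq_len(nrow(responses)), function(i)
    encode_response(subtask, responses$level[i], as.logical(clar[i]),
                    subject_id = as.character(responses$subject_id[i]),
                    group = group))
  occ <- occupancy(do.call(rbind, traj), dims = dims, group = group)
  lv <- factor(responses$level, levels = 0:3)
  frac <- as.numeric(table(lv)) / nrow(responses)
  summary <- data.frame(
    level = 0:3,
    fraction = frac,
    stringsAsFactors = FALSE)
  structure(
    list(occupancy = occ, summary = summary,
         prop_beyond_initial = mean(responses$level >= 1),
         prop_success = mean(responses$level <= 2),
         prop_failure = mean(responses$level == 3),
         n = nrow(responses), subtask = subtask, group = group,
         trajectories = traj),
    class = "testasap_scores")
}

#' @export
print.testasap_scores <- function(x, ...) {
  cat("TEST-ASAP scores: subtask = ", x$subtask,
      if (!is.na(x$group)) paste0(", group = ", x$group),
      ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  success %.0f%%, failure %.0f%%, beyond-initial %.0f%%\n",
              100 * x$prop_success, 100 * x$prop_failure,
              100 * x$prop_beyond_initial))
  print(x$occupancy)
  invisible(x)
}

#' Read response-level records from a TSV file
#'
#' @param path TSV with columns `subject_id`, `group`, `subtask`, `level`,
#'   `clarification`.
#' @return Data frame of responses.
#' @export
read_responses <- function(path) {
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "subtask", "level", "clarification")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out
}
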