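## Core data model: a dialogue is a roster of participants plus an ordered
## table of annotated speech acts. Each act carries:
##   speaker    - participant identifier
##   epsilon    - dialogical time (integer rank of the act in the exchange)
##   content    - the utterance or bracketed nonverbal action
##   act_type   - one of DO, MK, DMK, DC, DM
##   x, y       - topological address: x indexes themes (concatenations),
##                y indexes depth of elaboration within a theme
##   delta_*    - binary polarity toward an object of analysis
##                (delta_task, delta_interlocutor, ...)
##   decisive   - binary decisivity flag; a decisive act must be positively
##                task-polarized (d = 1 implies delta_task = 1), which makes
##                celerity <= vergence hold by construction
##   plane      - index of the thematic plane (default 1)

REQUIRED_ACT_COLS <- c("speaker", "epsilon", "content", "act_type",
                       "x", "y", "delta_task", "decisive")

#' Construct a dialogue object
#'
#' Bundles a table of annotated speech acts into a `dialogue` object.
#' Dialogical time `epsilon` may be supplied on any integer scale
#' (including zero or negative values for pre-task talk); it is shifted to
#' a 1-based internal index preserving order, with the original values kept
#' in `epsilon_raw`.
#'
#' @param acts Data frame with columns `speaker`, `epsilon`, `content`,
#'   `act_type`, `x`, `y`, `delta_task`, `decisive`, optionally further
#'   `delta_<object>` polarity columns (`delta_interlocutor` is added as 0
#'   with a validation warning if absent) and a `plane` column (default 1).
#' @param id Dialogue identifier.
#' @param participants Character vector of speaker identifiers; defaults to
#'   the speakers observed in `acts`.
#' @param condition Free-text label for the interactional condition, e.g.
#'   `"cooperative task"`.
#' @param validate If `TRUE` (default), stop when [validate_dialogue()]
#'   reports any violation.
#'
#' @return An object of class `dialogue`: a list with elements `id`,
#'   `participants`, `condition` and `acts` (the act table ordered by
#'   `epsilon`).
#' @seealso [validate_dialogue()], [build_dialogue()], [read_transcript()]
#' @export
#' @examples
#' acts <- data.frame(
#'   speaker = c("A", "B"), epsilon = 1:2,
#'   content = c("Shall we start?", "Yes."),
#'   act_type = c("DMK", "MK"), x = 1L, y = 1:2,
#'   delta_task = 1L, delta_interlocutor = c(0L, 1L), decisive = 1L)
#' d <- dialogue(acts, id = "demo")
#' d
dialogue <- function(acts, id = "dialogue", participants = NULL,
                     condition = NA_character_, validate = TRUE) {
  stopifnot(is.data.frame(acts))
  missing_cols <- setdiff(REQUIRED_ACT_COLS, names(acts))
  if (length(missing_cols))
    stop("acts is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  acts <- as.data.frame(acts, stringsAsFactors = FALSE)
  if (nrow(acts) == 0L) stop("a dialogue must contain at least one speech act",
                             call. = FALSE)
  if (!is.numeric(acts$epsilon) || anyNA(acts$epsilon) ||
      any(acts$epsilon != floor(acts$epsilon)))
    stop("epsilon must be integer-valued", call. = FALSE)
  if (is.null(acts$plane)) acts$plane <- 1L
  if (is.null(acts$delta_interlocutor)) {
    # unlisted objects of analysis default to null polarity
    acts$delta_interlocutor <- 0L
    attr(acts, "delta_defaulted") <- "interlocutor"
  }
  acts <- acts[order(acts$epsilon), , drop = FALSE]
  acts$epsilon_raw <- as.integer(acts$epsilon)
  acts$epsilon <- as.integer(acts$epsilon - min(acts$epsilon) + 1L)
  for (col in c("x", "y", "decisive", "plane", grep("^delta_", names(acts), value = TRUE)))
    acts[[col]] <- as.integer(acts[[col]])
  rownames(acts) <- NULL
  if (is.null(participants)) participants <- unique(acts$speaker)
  d <- structure(
    list(id = as.character(id), participants = as.character(participants),
         condition = condition, acts = acts),
    class = "dialogue")
  if (isTRUE(validate)) {
    v <- validate_dialogue(d)
    if (nrow(v))
      stop("invalid dialogue (", nrow(v), " violation(s)); first: ",
           v$message[1], ". Use validate = FALSE to inspect.", call. = FALSE)
  }
  d
}

#' @export
print.dialogue <- function(x, ...) {
  cat("<dialogue> ", x$id, "\n", sep = "")
  cat("  participants: ", paste(x$participants, collapse = ", "), "\n", sep = "")
  if (!is.na(x$condition)) cat("  condition: ", x$condition, "\n", sep = "")
  cat("  ", nrow(x$acts), " speech acts in ",
      length(unique(x$acts$x)), " concatenation(s), ",
      length(unique(x$acts$plane)), " plane(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dialogue <- function(x, ...) x$acts

#' Extract the act table from a dialogue or pass a data frame through
#' @param x A `dialogue` or a data frame of acts.
#' @return Data frame of speech acts.
#' @keywords internal
acts_of <- function(x) {
  if (inherits(x, "dialogue")) x$acts
  else if (is.data.frame(x)) x
  else stop("expected a dialogue or a data frame of speech acts", call. = FALSE)
}

#' Names of the polarity objects annotated on a dialogue
#' @param x A `dialogue` or act table.
#' @return Character vector of object-of-analysis identifiers (e.g.
#'   `"task"`, `"interlocutor"`).
#' @export
polarity_objects <- function(x) {
  sub("^delta_", "", grep("^delta_", names(acts_of(x)), value = TRUE))
}

#' Validate a dialogue against the data-model invariants
#'
#' Validation never raises: it returns a table of violations, empty when
#' all invariants hold. Checked rules: known act types; positive integer
#' addresses; addresses unique within a plane; `epsilon` unique; polarity
#' and decisivity flags binary; every decisive act positively
#' task-polarized (`d = 1` implies `delta_task = 1`, the premise of the
#' primacy inequality C <= V); every speaker in the roster.
#'
#' @param d A `dialogue` (or act table).
#' @return Data frame with columns `epsilon` (internal index of the
#'   offending act, `NA` for dialogue-level rules), `rule`, `message`;
#'   zero rows iff the dialogue is valid.
#' @export
#' @examples
#' acts <- data.frame(speaker = "A", epsilon = 1, content = "hi",
#'                    act_type = "MK", x = 1, y = 1,
#'                    delta_task = 0, decisive = 1)
#' d <- dialogue(acts, validate = FALSE)
#' validate_dialogue(d)  # decisive act not task-polarized
validate_dialogue <- function(d) {
  acts <- acts_of(d)
  v <- list()
  add <- function(epsilon, rule, message)
    v[[length(v) + 1L]] <<- data.frame(epsilon = epsilon, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  bad_type <- !acts$act_type %in% ACT_TYPES
  for (i in which(bad_type))
    add(acts$epsilon[i], "act_type",
        sprintf("unknown act type '%s' at epsilon %d", acts$act_type[i],
                acts$epsilon[i]))
  bad_addr <- is.na(acts$x) | is.na(acts$y) | acts$x < 1L | acts$y < 1L
  for (i in which(bad_addr))
    add(acts$epsilon[i], "address",
        sprintf("address (x=%s, y=%s) at epsilon %d is not positive",
                acts$x[i], acts$y[i], acts$epsilon[i]))
  dup_eps <- duplicated(acts$epsilon)
  for (i in which(dup_eps))
    add(acts$epsilon[i], "duplicate_epsilon",
        sprintf("duplicate epsilon %d", acts$epsilon[i]))
  key <- paste(acts$plane, acts$x, acts$y)
  dup_addr <- duplicated(key) & !bad_addr
  for (i in which(dup_addr))
    add(acts$epsilon[i], "duplicate_address",
        sprintf("duplicate address (x=%d, y=%d) in plane %d at epsilon %d",
                acts$x[i], acts$y[i], acts$plane[i], acts$epsilon[i]))
  flag_cols <- c("decisive", grep("^delta_", names(acts), value = TRUE))
  for (col in flag_cols) {
    bad <- !acts[[col]] %in% c(0L, 1L)
    for (i in which(bad))
      add(acts$epsilon[i], "binary_flag",
          sprintf("%s at epsilon %d is not 0/1", col, acts$epsilon[i]))
  }
  undecisive <- acts$decisive == 1L & acts$delta_task == 0L
  for (i in which(undecisive))
    add(acts$epsilon[i], "decisive_not_task_polarized",
        sprintf("decisive act not task-polarized at epsilon %d",
                acts$epsilon[i]))
  if (inherits(d, "dialogue")) {
    off_roster <- !acts$speaker %in% d$participants
    for (i in which(off_roster))
      add(acts$epsilon[i], "speaker",
          sprintf("speaker '%s' at epsilon %d not in roster",
                  acts$speaker[i], acts$epsilon[i]))
    if (length(d$participants) < 2L)
      add(NA_integer_, "participants", "fewer than two participants")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(epsilon = integer(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Assemble a dialogue from an ordered act sequence
#'
#' Groups speech acts into concatenations (themes) by their `x`
#' coordinate. When the acts carry no addresses, themes are assigned from
#' `theme_breaks`: a new theme starts at each listed `epsilon`, and `y` is
#' the act's position within its theme. Acts already carrying `x`/`y` are
#' grouped as addressed, which permits back-references (an act returning to
#' an earlier theme after an intervening one).
#'
#' @param acts Data frame of speech acts ordered by `epsilon` (columns as
#'   in [dialogue()]; `x`, `y` optional here).
#' @param theme_breaks Integer vector of `epsilon` values at which a new
#'   theme starts (ignored when `acts` carries addresses); must be a
#'   subset of the observed `epsilon`.
#' @param ... Passed to [dialogue()] (`id`, `participants`, `condition`).
#' @return A validated `dialogue`.
#' @export
build_dialogue <- function(acts, theme_breaks = NULL, ...) {
  stopifnot(is.data.frame(acts), nrow(acts) >= 1L)
  if (is.unsorted(acts$epsilon, strictly = TRUE))
    stop("acts must be strictly ordered by epsilon", call. = FALSE)
  if (is.null(acts$x) || is.null(acts$y)) {
    if (!is.null(theme_breaks) && !all(theme_breaks %in% acts$epsilon))
      stop("theme_breaks must be a subset of the observed epsilon values",
           call. = FALSE)
    acts$x <- cumsum(acts$epsilon %in% setdiff(theme_breaks, acts$epsilon[1]) |
                       seq_len(nrow(acts)) == 1L)
    acts$y <- stats::ave(acts$x, acts$x, FUN = seq_along)
  }
  dialogue(acts, ...)
}

#' Split a dialogue into its concatenations
#'
#' @param d A `dialogue`.
#' @return Named list of act tables, one per concatenation (theme), in
#'   order of theme index `x`; each element keeps its acts in `epsilon`
#'   order.
#' @export
concatenations <- function(d) {
  acts <- acts_of(d)
  split(acts, acts$x)
}
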