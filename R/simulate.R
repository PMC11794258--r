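## Synthetic dialogue generator. Emulates the statistical structure of
## two-party task dialogues: alternating speakers with a configurable
## floor-holding probability, per-speaker act-type distributions, Bernoulli
## polarity flags per phase (an optional mid-dialogue change point switches
## the task-polarity probability, emulating a prompt/regime change), and
## decisivity drawn only for positively task-polarized acts so that every
## generated dialogue satisfies the primacy premise d <= delta_task.

# Default per-speaker act-type distributions follow the usage profiles
# observed for an experimenter and a child subject in task dialogue
# (experimenter: overwhelmingly verbal information; subject: more
# information through motor action).
DEFAULT_ACT_PROBS <- local({
  exp_p <- c(DO = 0.04, MK = 0.77, DMK = 0.13, DC = 0.03, DM = 0.02)
  sub_p <- c(DO = 0.17, MK = 0.63, DMK = 0.12, DC = 0.03, DM = 0.05)
  rbind(EXP = exp_p / sum(exp_p), SUBJ = sub_p / sum(sub_p))
})

#' Configuration for the synthetic dialogue generator
#'
#' @param n_concatenations Number of themes (concatenations).
#' @param acts_per_concatenation Acts per theme: a single count or a
#'   `c(min, max)` range sampled per theme.
#' @param speakers Two speaker identifiers.
#' @param act_type_probs 2 x 5 matrix of per-speaker act-type
#'   probabilities (rows = speakers, columns = `DO, MK, DMK, DC, DM`);
#'   defaults to empirical experimenter/subject task-dialogue profiles.
#' @param p_delta_task Probability an act is positively task-polarized;
#'   length 1, or length 2 `c(pre, post)` when `change_point` is set.
#' @param p_delta_interlocutor Probability of positive interlocutor
#'   polarity; length 1 or 2 as above.
#' @param p_decisive_given_positive Probability a task-polarized act is
#'   decisive (decisivity is never drawn for delta_task = 0 acts). The
#'   default 0.75 matches the celerity/vergence ratio of the packaged
#'   worked example.
#' @param change_point Optional internal `epsilon` at which the second
#'   phase begins (prompt scenarios).
#' @param turn_persistence Probability the current speaker holds the
#'   floor for the next act (default 0.3, loosely matching multi-act
#'   turns in task transcripts).
#' @param seed Optional integer seed recorded in the output metadata.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_concatenations = 15,
                             acts_per_concatenation = 20,
                             speakers = c("EXP", "SUBJ"),
                             act_type_probs = NULL,
                             p_delta_task = 0.9,
                             p_delta_interlocutor = 0.9,
                             p_decisive_given_positive = 0.75,
                             change_point = NULL,
                             turn_persistence = 0.3,
                             seed = NULL) {
  stopifnot(length(speakers) == 2L, n_concatenations >= 1,
            all(acts_per_concatenation >= 1),
            length(acts_per_concatenation) %in% 1:2)
  if (is.null(act_type_probs)) {
    act_type_probs <- DEFAULT_ACT_PROBS
    rownames(act_type_probs) <- speakers
  }
  stopifnot(is.matrix(act_type_probs), nrow(act_type_probs) == 2L,
            ncol(act_type_probs) == 5L,
            all(abs(rowSums(act_type_probs) - 1) < 1e-8))
  probs <- c(p_delta_task, p_delta_interlocutor,
             p_decisive_given_positive, turn_persistence)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  for (p in c("p_delta_task", "p_delta_interlocutor"))
    if (length(get(p)) == 2L && is.null(change_point))
      stop(p, " has two phases but no change_point is set", call. = FALSE)
  structure(list(n_concatenations = n_concatenations,
                 acts_per_concatenation = acts_per_concatenation,
                 speakers = speakers, act_type_probs = act_type_probs,
                 p_delta_task = p_delta_task,
                 p_delta_interlocutor = p_delta_interlocutor,
                 p_decisive_given_positive = p_decisive_given_positive,
                 change_point = change_point,
                 turn_persistence = turn_persistence, seed = seed),
            class = "generator_config")
}

phase_prob <- function(p, epsilon, change_point) {
  if (length(p) == 1L || is.null(change_point)) rep(p[1], length(epsilon))
  else ifelse(epsilon < change_point, p[1], p[2])
}

#' Generate a synthetic annotated dialogue
#'
#' Draws a dialogue under a [generator_config()]: themes of configurable
#' size, alternating speakers with floor persistence, per-speaker act
#' types, phase-dependent Bernoulli polarities, and decisivity drawn only
#' for task-polarized acts. The result always passes
#' [validate_dialogue()], hence satisfies the primacy inequality C <= V on
#' every act subset.
#'
#' @param config A `generator_config`.
#' @param id Dialogue identifier.
#' @return A validated `dialogue`; the generating config (including the
#'   seed) is attached as attribute `"config"`.
#' @export
#' @examples
#' d <- generate_dialogue(generator_config(n_concatenations = 3,
#'                                         acts_per_concatenation = 5,
#'                                         seed = 1))
#' vergence(d)
generate_dialogue <- function(config = generator_config(),
                              id = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  apc <- config$acts_per_concatenation
  sizes <- if (length(apc) == 2L)
    sample(apc[1]:apc[2], config$n_concatenations, replace = TRUE)
  else rep(apc, config$n_concatenations)
  n <- sum(sizes)
  x <- rep(seq_len(config$n_concatenations), sizes)
  y <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  epsilon <- seq_len(n)
  speaker <- character(n)
  speaker[1] <- sample(config$speakers, 1)
  hold <- runif(n - 1) < config$turn_persistence
  for (i in seq_len(n - 1)) {
    speaker[i + 1] <- if (hold[i]) speaker[i]
                      else setdiff(config$speakers, speaker[i])
  }
  act_type <- character(n)
  for (s in config$speakers) {
    idx <- which(speaker == s)
    act_type[idx] <- sample(ACT_TYPES, length(idx), replace = TRUE,
                            prob = config$act_type_probs[s, ])
  }
  p_task <- phase_prob(config$p_delta_task, epsilon, config$change_point)
  p_int <- phase_prob(config$p_delta_interlocutor, epsilon,
                      config$change_point)
  delta_task <- rbinom(n, 1L, p_task)
  delta_int <- rbinom(n, 1L, p_int)
  decisive <- integer(n)
  pos <- delta_task == 1L
  decisive[pos] <- rbinom(sum(pos), 1L, config$p_decisive_given_positive)
  acts <- data.frame(speaker = speaker, epsilon = epsilon,
                     content = paste0("utt-", epsilon),
                     act_type = act_type, x = x, y = y,
                     delta_task = delta_task,
                     delta_interlocutor = delta_int,
                     decisive = decisive, stringsAsFactors = FALSE)
  d <- dialogue(acts, id = id, participants = config$speakers,
                condition = "synthetic")
  attr(d, "config") <- config
  d
}

#' Generate a running-vergence series with a regime change
#'
#' Generates a dialogue whose task-polarity probability switches at the
#' configured change point (a prompt/divergence scenario) and returns its
#' running-vergence trajectory.
#'
#' @param config A `generator_config` with `change_point` set (a config
#'   without one yields a stationary series).
#' @param window Running-vergence window (default 20 acts).
#' @param object Object of analysis.
#' @return A `metric_series` (granularity `"running_per_act"`) with the
#'   generated `dialogue` attached as attribute `"dialogue"` and the raw
#'   polarity flags as attribute `"delta"`.
#' @export
generate_regime_series <- function(config, window = 20, object = "task") {
  d <- generate_dialogue(config, id = "regime")
  s <- running_vergence(d, object = object, window = window)
  attr(s, "dialogue") <- d
  attr(s, "delta") <- d$acts[[paste0("delta_", object)]]
  attr(s, "window") <- window
  s
}

#' Sample graded-prompting response levels for a synthetic group
#'
#' @param n_subjects Number of subjects.
#' @param level_distribution Probabilities of response levels `0:3`
#'   (summing to 1).
#' @param clarification_rate Probability a level >= 1 subject asks a
#'   clarification question.
#' @param seed Optional integer seed.
#' @param group,subtask Labels carried on the records.
#' @return Data frame with columns `subject_id`, `group`, `subtask`,
#'   `level`, `clarification`.
#' @export
generate_group_responses <- function(n_subjects, level_distribution,
                                     clarification_rate = 0, seed = NULL,
                                     group = "synthetic",
                                     subtask = "basket") {
  stopifnot(n_subjects >= 1, length(level_distribution) == 4L)
  if (any(level_distribution < 0) || abs(sum(level_distribution) - 1) > 1e-8)
    stop("level_distribution must be non-negative and sum to 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  level <- sample(0:3, n_subjects, replace = TRUE,
                  prob = level_distribution)
  clar <- as.integer(level >= 1 & runif(n_subjects) < clarification_rate)
  data.frame(subject_id = sprintf("s%02d", seq_len(n_subjects)),
             group = group, subtask = subtask, level = level,
             clarification = clar, stringsAsFactors = FALSE)
}
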