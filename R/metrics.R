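## Kinetic dialogue metrics.
##
## Vergence V = (number of positively polarized speech acts) / (total acts)
## measures cooperation toward an object of analysis; values above 0.5 are
## read as effective cooperation, below 0.5 as divergence.
## Celerity C = (number of decisive acts) / (total acts) measures the
## efficiency of the exchange. On validated input d = 1 implies
## delta_task = 1, so C <= V holds act-set by act-set (the primacy
## inequality).

#' Vergence of a set of speech acts
#'
#' The proportion of positively polarized speech acts relative to the
#' total number of acts, for a chosen object of analysis.
#'
#' @param acts A `dialogue`, concatenation, or data frame of speech acts.
#' @param object Object of analysis, naming the `delta_<object>` polarity
#'   column (default `"task"`).
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' mc <- read_transcript(system.file("extdata", "monte_cristo.tsv",
#'                                   package = "dialtk"))
#' vergence(mc)            # 1: all eight acts task-polarized
#' celerity(mc)            # 0.75: six of eight acts decisive
vergence <- function(acts, object = "task") {
  acts <- acts_of(acts)
  if (nrow(acts) == 0L)
    stop("vergence is undefined on an empty act set", call. = FALSE)
  col <- paste0("delta_", object)
  if (is.null(acts[[col]]))
    stop("no polarity annotation for object '", object, "'", call. = FALSE)
  if (anyNA(acts[[col]]))
    stop("missing polarity annotation for object '", object, "'",
         call. = FALSE)
  mean(acts[[col]] == 1L)
}

#' Celerity of a set of speech acts
#'
#' The proportion of decisive speech acts relative to the total number of
#' acts. `(1 - C) * 100` is the relative slowdown: how much slower the
#' exchange progressed than if all non-decisive acts had been omitted.
#'
#' @inheritParams vergence
#' @return A proportion in `[0, 1]`.
#' @export
celerity <- function(acts) {
  acts <- acts_of(acts)
  if (nrow(acts) == 0L)
    stop("celerity is undefined on an empty act set", call. = FALSE)
  mean(acts$decisive == 1L)
}

#' Construct a metric series
#'
#' An ordered sequence of paired vergence/celerity measurements, indexed
#' either by concatenation number or by dialogical time `epsilon`.
#'
#' @param index Strictly increasing integer index.
#' @param vergence,celerity Values in `[0, 1]`.
#' @param n_acts Number of acts each point was computed over.
#' @param granularity `"per_concatenation"` or `"running_per_act"`.
#' @param object Object of analysis the vergence refers to.
#' @return A data frame of class `metric_series` with attributes
#'   `granularity` and `object`.
#' @export
metric_series <- function(index, vergence, celerity, n_acts,
                          granularity = c("per_concatenation",
                                          "running_per_act"),
                          object = "task") {
  granularity <- match.arg(granularity)
  if (length(index) && is.unsorted(index, strictly = TRUE))
    stop("metric series indices must be strictly increasing", call. = FALSE)
  structure(
    data.frame(index = as.integer(index), vergence = vergence,
               celerity = celerity, n_acts = as.integer(n_acts)),
    granularity = granularity, object = object,
    class = c("metric_series", "data.frame"))
}

#' @export
print.metric_series <- function(x, ...) {
  cat("<metric_series> ", attr(x, "granularity"), ", object = ",
      attr(x, "object"), ", ", nrow(x), " points\n", sep = "")
  print(as.data.frame(unclass(x)), ...)
  invisible(x)
}

#' Per-concatenation vergence and celerity
#'
#' One metric point per concatenation (theme), in theme order.
#'
#' @param d A validated `dialogue`.
#' @param object Object of analysis (default `"task"`).
#' @return A `metric_series` with granularity `"per_concatenation"`.
#' @export
per_concatenation_metrics <- function(d, object = "task") {
  cc <- concatenations(d)
  metric_series(
    index = as.integer(names(cc)),
    vergence = vapply(cc, vergence, numeric(1), object = object),
    celerity = vapply(cc, celerity, numeric(1)),
    n_acts = vapply(cc, nrow, integer(1)),
    granularity = "per_concatenation", object = object)
}

#' Trailing-window running proportion of a binary flag sequence
#'
#' The workhorse behind [running_vergence()] and the counterfactual
#' conditioning series: for each position, the proportion of positive
#' flags over the trailing window ending there (a shorter prefix is used
#' at the start; `window = "cumulative"` uses all flags so far). When
#' `insert_at` is given, a phantom positive flag is attached at that
#' position: every window covering it then averages one extra 1, i.e.
#' `(S + 1) / (n + 1)` — the counterfactual positive-act intervention.
#'
#' @param flags Integer/logical vector of 0/1 flags.
#' @param window Positive integer or `"cumulative"`.
#' @param insert_at Optional position of a phantom positive flag.
#' @return Numeric vector of proportions, same length as `flags`.
#' @export
running_prop <- function(flags, window = 20, insert_at = NULL) {
  n <- length(flags)
  cums <- cumsum(flags)
  idx <- seq_len(n)
  if (identical(window, "cumulative")) {
    lo <- rep(1L, n)
  } else {
    lo <- pmax(1L, idx - as.integer(window) + 1L)
  }
  s <- cums[idx] - ifelse(lo > 1L, cums[pmax(lo - 1L, 1L)], 0)
  cnt <- idx - lo + 1
  if (!is.null(insert_at)) {
    covered <- idx >= insert_at & lo <= insert_at
    s <- s + covered
    cnt <- cnt + covered
  }
  s / cnt
}

#' Running vergence (and celerity) trajectory
#'
#' For each act (optionally restricted to one speaker), the vergence over
#' the trailing window of acts ending there — or over all acts so far when
#' `window = "cumulative"`. Celerity is computed over the same windows.
#'
#' @param d A validated `dialogue`.
#' @param object Object of analysis.
#' @param window Positive integer window length in acts, or
#'   `"cumulative"`. Default 20, chosen to make regime changes visible at
#'   typical task-dialogue lengths of roughly 300-650 acts.
#' @param speaker Optional speaker identifier; restricts the trajectory to
#'   that speaker's acts (vergence toward the interlocutor for one party,
#'   for instance, is the trajectory of their `delta_interlocutor` flags).
#' @param strict If `TRUE`, error when `window` exceeds the number of
#'   acts; otherwise the shorter prefix is used at the start.
#' @return A `metric_series` with granularity `"running_per_act"`, indexed
#'   by internal `epsilon`.
#' @export
running_vergence <- function(d, object = "task", window = 20,
                             speaker = NULL, strict = FALSE) {
  acts <- acts_of(d)
  if (!is.null(speaker)) {
    if (inherits(d, "dialogue") && !speaker %in% d$participants)
      stop("unknown speaker '", speaker, "'", call. = FALSE)
    acts <- acts[acts$speaker == speaker, , drop = FALSE]
    if (nrow(acts) == 0L)
      stop("speaker '", speaker, "' has no acts", call. = FALSE)
  }
  if (!identical(window, "cumulative")) {
    if (!is.numeric(window) || window < 1)
      stop("window must be a positive integer or \"cumulative\"",
           call. = FALSE)
    if (strict && window > nrow(acts))
      stop("window (", window, ") exceeds the number of acts (",
           nrow(acts), ")", call. = FALSE)
  }
  col <- paste0("delta_", object)
  if (is.null(acts[[col]]))
    stop("no polarity annotation for object '", object, "'", call. = FALSE)
  v <- running_prop(acts[[col]], window)
  c_ <- running_prop(acts$decisive, window)
  idx <- seq_len(nrow(acts))
  lo <- if (identical(window, "cumulative")) rep(1L, length(idx))
        else pmax(1L, idx - as.integer(window) + 1L)
  metric_series(acts$epsilon, v, c_, idx - lo + 1L,
                granularity = "running_per_act", object = object)
}

#' Act-type usage profile of a speaker
#'
#' The proportion of each of the five speech-act types among one
#' speaker's acts.
#'
#' @param d A `dialogue`.
#' @param speaker Speaker identifier (must be in the roster and have at
#'   least one act).
#' @return Object of class `act_type_profile`: a named numeric vector of
#'   proportions over `DO, MK, DMK, DC, DM` (summing to 1), with the
#'   speaker and act count as attributes.
#' @export
act_type_profile <- function(d, speaker) {
  acts <- acts_of(d)
  if (inherits(d, "dialogue") && !speaker %in% d$participants)
    stop("speaker '", speaker, "' not in roster", call. = FALSE)
  acts <- acts[acts$speaker == speaker, , drop = FALSE]
  if (nrow(acts) == 0L)
    stop("act-type profile undefined: speaker '", speaker,
         "' has no acts", call. = FALSE)
  counts <- table(factor(acts$act_type, levels = ACT_TYPES))
  structure(as.numeric(counts) / nrow(acts), names = ACT_TYPES,
            speaker = speaker, n_acts = nrow(acts),
            class = "act_type_profile")
}

#' @export
print.act_type_profile <- function(x, digits = 3, ...) {
  cat("act-type profile of ", attr(x, "speaker"), " (",
      attr(x, "n_acts"), " acts)\n", sep = "")
  print(round(setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Pearson correlation between vergence and celerity
#'
#' Tests the association between paired per-segment vergence and celerity
#' values (typically one pair per concatenation). The p-value is two-tailed
#' from the exact t transform with `df = n - 2`.
#'
#' @param series A `metric_series` with at least 3 points and non-constant
#'   vergence and celerity.
#' @return List of class `vc_correlation` with elements `r`, `p`, `df`,
#'   `n`.
#' @export
vc_correlation <- function(series) {
  stopifnot(inherits(series, "metric_series"))
  n <- nrow(series)
  if (n < 3L)
    stop("correlation requires at least 3 metric points", call. = FALSE)
  if (stats::sd(series$vergence) == 0 || stats::sd(series$celerity) == 0)
    stop("degenerate correlation: vergence or celerity series is constant",
         call. = FALSE)
  ct <- cor.test(series$vergence, series$celerity, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 df = unname(ct$parameter), n = n),
            class = "vc_correlation")
}

#' @export
print.vc_correlation <- function(x, ...) {
  cat(sprintf("vergence-celerity Pearson correlation: r(%d) = %.3f, p = %.4g\n",
              x$df, x$r, x$p))
  invisible(x)
}

#' Check the primacy inequality C <= V
#'
#' On any act set whose decisive acts are all positively task-polarized,
#' celerity cannot exceed vergence. This checks the inequality pointwise
#' on a metric series, or on the whole act set of a dialogue.
#'
#' @param x A `metric_series` or a `dialogue` (checked as one segment).
#' @param object Object of analysis when `x` is a dialogue.
#' @param tol Numerical slack (default `1e-12`).
#' @return List with `ok` (logical) and `violations` (indices where
#'   `celerity > vergence`).
#' @export
primacy_check <- function(x, object = "task", tol = 1e-12) {
  if (inherits(x, "metric_series")) {
    bad <- which(x$celerity > x$vergence + tol)
    list(ok = length(bad) == 0L, violations = x$index[bad])
  } else {
    v <- vergence(x, object)
    c_ <- celerity(x)
    list(ok = c_ <= v + tol,
         violations = if (c_ > v + tol) 1L else integer(0))
  }
}
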