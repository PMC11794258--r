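## Recurrent vergence forecaster.
##
## A single-layer Elman recurrence with hidden state h and scalar output:
##   h_e = sigma_h(W_xh x_e + W_hh h_{e-1} + b_h)
##   V_e = sigma_y(W_hy h_e + b_y)
## sigma_h = tanh bounds the hidden state; sigma_y = logistic guarantees
## predicted vergence values in [0, 1]. The input features x_e are the
## normalized dialogical time (epsilon divided by the training-window
## length) and the previous conditioning vergence value, so that observed
## values can re-condition the forecast at stride boundaries and a
## counterfactual prompt can enter through the conditioning series.
## Training minimizes mean squared error by full-sequence backpropagation
## through time (compiled core in src/rnn.cpp) and is deterministic given
## the seed.

activation_fun <- function(name) {
  switch(name,
         tanh = tanh,
         logistic = function(z) 1 / (1 + exp(-z)),
         identity = identity,
         stop("unknown activation '", name, "'", call. = FALSE))
}

#' Recurrent forecaster parameters
#'
#' Initializes (or bundles) the weight matrices and biases of the
#' vergence forecaster. Seeded initialization draws uniform weights in
#' `[-0.5, 0.5]` scaled by `1/sqrt(H)`.
#'
#' @param hidden Hidden size H.
#' @param n_input Number of input features p (default 2: normalized
#'   epsilon and previous conditioning vergence).
#' @param seed Integer seed for initialization (default 1459549).
#' @param Wxh,Whh,bh,Why,by Optional explicit parameters (H x p, H x H,
#'   length H, length H, scalar); all must be supplied together.
#' @param sigma_h,sigma_y Activation names: `"tanh"`, `"logistic"` or
#'   `"identity"` (the compiled trainer supports the default pair).
#' @return List of class `rnn_params`.
#' @export
rnn_params <- function(hidden = 8, n_input = 2, seed = 1459549,
                       Wxh = NULL, Whh = NULL, bh = NULL, Why = NULL,
                       by = NULL, sigma_h = "tanh", sigma_y = "logistic") {
  if (is.null(Wxh)) {
    set.seed(seed)
    sc <- 1 / sqrt(hidden)
    Wxh <- matrix(runif(hidden * n_input, -0.5, 0.5) * sc, hidden, n_input)
    Whh <- matrix(runif(hidden * hidden, -0.5, 0.5) * sc, hidden, hidden)
    bh <- runif(hidden, -0.5, 0.5) * sc
    Why <- runif(hidden, -0.5, 0.5) * sc
    by <- runif(1, -0.5, 0.5) * sc
  } else {
    hidden <- length(bh)
    n_input <- ncol(Wxh)
  }
  stopifnot(nrow(Wxh) == hidden, ncol(Whh) == hidden,
            nrow(Whh) == hidden, length(Why) == hidden, length(by) == 1L,
            all(is.finite(c(Wxh, Whh, bh, Why, by))))
  structure(list(Wxh = Wxh, Whh = Whh, bh = bh, Why = Why, by = by,
                 hidden = hidden, n_input = n_input,
                 sigma_h = sigma_h, sigma_y = sigma_y),
            class = "rnn_params")
}

#' One step of the recurrent forecaster
#'
#' Evaluates the recurrence `h = sigma_h(Wxh x + Whh h_prev + b_h)` and
#' output `V = sigma_y(Why h + b_y)` for a single input.
#'
#' @param params An `rnn_params` object.
#' @param x Input feature vector (length `params$n_input`; a scalar is
#'   accepted when `n_input = 1`).
#' @param h_prev Previous hidden state (length H).
#' @return List with `V` (predicted vergence scalar) and `h` (new hidden
#'   state).
#' @export
#' @examples
#' p <- rnn_params(hidden = 1, n_input = 1,
#'                 Wxh = matrix(1), Whh = matrix(0), bh = 0, Why = 1, by = 0)
#' rnn_step(p, 0, 0)  # V = 0.5, h = 0
rnn_step <- function(params, x, h_prev) {
  stopifnot(inherits(params, "rnn_params"))
  x <- as.numeric(x)
  if (length(x) != params$n_input)
    stop("input has length ", length(x), ", expected ", params$n_input,
         call. = FALSE)
  if (length(h_prev) != params$hidden)
    stop("h_prev has length ", length(h_prev), ", expected ",
         params$hidden, call. = FALSE)
  sh <- activation_fun(params$sigma_h)
  sy <- activation_fun(params$sigma_y)
  h <- sh(drop(params$Wxh %*% x) + drop(params$Whh %*% h_prev) + params$bh)
  V <- sy(sum(params$Why * h) + params$by)
  list(V = V, h = h)
}

# Build the teacher-forced input matrix for a conditioning series v:
# column 1 is epsilon normalized by the training-window length, column 2
# the previous conditioning value (v[1] repeated at the first step).
rnn_inputs <- function(v, epsilon = seq_along(v), n_train = length(v)) {
  cbind(epsilon / n_train, c(v[1], v[-length(v)]))
}

#' Fit the recurrent vergence forecaster
#'
#' Trains the Elman recurrence on a running-vergence trajectory by
#' full-sequence backpropagation through time (mean squared error,
#' full-batch gradient descent). Deterministic given `seed`.
#'
#' @param series A `metric_series` (granularity `"running_per_act"`) or a
#'   numeric vector of vergence values in `[0, 1]`.
#' @param hidden Hidden size H (default 8).
#' @param epochs Training epochs (default 2000).
#' @param lr Learning rate (default 0.01).
#' @param seed Seed for weight initialization (default 1459549).
#' @return Object of class `vergence_rnn`: the trained `rnn_params`, the
#'   observed and fitted series, the per-epoch loss trajectory, and the
#'   training configuration. Supports `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `plot` and [rolling_forecast()] /
#'   [counterfactual_forecast()].
#' @export
#' @examples
#' v <- running_prop(rbinom(120, 1, 0.8), 20)
#' fit <- vergence_rnn(v, epochs = 200)
#' fit
vergence_rnn <- function(series, hidden = 8, epochs = 2000, lr = 0.01,
                         seed = 1459549) {
  v <- if (inherits(series, "metric_series")) series$vergence
       else as.numeric(series)
  stopifnot(epochs >= 1, lr > 0)
  if (length(v) < hidden + 2)
    stop("training series must contain at least hidden + 2 points",
         call. = FALSE)
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("vergence values must lie in [0, 1]", call. = FALSE)
  p0 <- rnn_params(hidden = hidden, n_input = 2, seed = seed)
  X <- rnn_inputs(v)
  fit <- rnn_train_cpp(p0$Wxh, p0$Whh, p0$bh, p0$Why, p0$by, X, v,
                       as.integer(epochs), lr)
  if (fit$diverged_epoch > 0)
    stop("training diverged (non-finite loss) at epoch ",
         fit$diverged_epoch, " with learning rate ", lr, call. = FALSE)
  params <- rnn_params(Wxh = fit$Wxh, Whh = fit$Whh, bh = fit$bh,
                       Why = fit$Why, by = fit$by)
  structure(list(params = params, observed = v,
                 epsilon = if (inherits(series, "metric_series"))
                   series$index else seq_along(v),
                 fitted = as.numeric(fit$fitted),
                 loss = as.numeric(fit$loss), n_train = length(v),
                 config = list(hidden = hidden, epochs = epochs, lr = lr,
                               seed = seed),
                 call = match.call()),
            class = "vergence_rnn")
}

#' @export
print.vergence_rnn <- function(x, ...) {
  cat("Recurrent vergence forecaster\n")
  cat(sprintf("  hidden units: %d, inputs: %d (normalized epsilon, previous vergence)\n",
              x$params$hidden, x$params$n_input))
  cat(sprintf("  trained on %d points, %d epochs, lr = %g, seed = %d\n",
              x$n_train, x$config$epochs, x$config$lr, x$config$seed))
  cat(sprintf("  final MSE: %.5f (epoch 1: %.5f)\n",
              tail(x$loss, 1), x$loss[1]))
  invisible(x)
}

#' @export
summary.vergence_rnn <- function(object, ...) {
  res <- residuals(object)
  cat("Recurrent vergence forecaster\n")
  print(object$call)
  cat(sprintf("\n  training points: %d\n  final MSE: %.5f\n  RMSE: %.5f\n",
              object$n_train, tail(object$loss, 1),
              sqrt(mean(res^2))))
  cat("  residual quartiles:\n")
  print(round(stats::quantile(res), 5))
  invisible(object)
}

#' @export
coef.vergence_rnn <- function(object, ...) {
  p <- object$params
  list(Wxh = p$Wxh, Whh = p$Whh, bh = p$bh, Why = p$Why, by = p$by)
}

#' @export
fitted.vergence_rnn <- function(object, ...) object$fitted

#' @export
residuals.vergence_rnn <- function(object, ...)
  object$observed - object$fitted

#' @export
plot.vergence_rnn <- function(x, ...) {
  plot(x$epsilon, x$observed, type = "l", col = "grey40",
       xlab = "dialogical time (epsilon)", ylab = "vergence",
       ylim = c(0, 1), ...)
  graphics::lines(x$epsilon, x$fitted, col = "steelblue")
  graphics::legend("bottomleft", legend = c("observed", "fitted"),
                   col = c("grey40", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
predict.vergence_rnn <- function(object, newdata = NULL, start = NULL,
                                 stride = 3, ...) {
  rolling_forecast(object, newdata = newdata, start = start,
                   stride = stride)
}

# Advance the hidden state over steps `idx` of conditioning series v
# (teacher forcing: the input vergence feature is the observed previous
# value).
advance_hidden <- function(model, v, idx, h) {
  for (t in idx) {
    x <- c(t / model$n_train, if (t == 1) v[1] else v[t - 1])
    h <- rnn_step(model$params, x, h)$h
  }
  h
}

#' Rolling re-conditioned forecast
#'
#' From `start` onward, the model free-runs `stride` steps ahead (feeding
#' its own predictions back as the vergence input), then the hidden state
#' is re-conditioned on the observed values of those steps, and the cycle
#' repeats to the end of the series. `stride = 1` gives pure
#' one-step-ahead prediction; `stride = length(series)` a single free-run
#' forecast.
#'
#' @param model A fitted [vergence_rnn()].
#' @param newdata Conditioning series (a `metric_series` or numeric
#'   vector); defaults to the training series.
#' @param start First index to forecast (defaults to the step after the
#'   training window, or 2 when forecasting the training series itself).
#' @param stride Re-conditioning stride in speech acts (default 3).
#' @return Object of class `tk_forecast`: data frame `series` with
#'   columns `epsilon`, `observed`, `forecast`, plus `start`, `stride`
#'   and the re-conditioning boundary indices.
#' @export
rolling_forecast <- function(model, newdata = NULL, start = NULL,
                             stride = 3) {
  stopifnot(inherits(model, "vergence_rnn"))
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  v <- if (is.null(newdata)) model$observed
       else if (inherits(newdata, "metric_series")) newdata$vergence
       else as.numeric(newdata)
  n <- length(v)
  if (is.null(start))
    start <- if (n > model$n_train) model$n_train + 1L else 2L
  if (start < 1L || start > n)
    stop("start must lie within the conditioning series", call. = FALSE)
  h <- advance_hidden(model, v, seq_len(start - 1L), rep(0, model$params$hidden))
  pred <- rep(NA_real_, n)
  boundaries <- integer(0)
  t <- start
  while (t <= n) {
    block <- t:min(t + stride - 1L, n)
    # free-run inside the block: feed predictions back
    v_in <- if (t == 1) v[1] else v[t - 1]
    h_free <- h
    for (k in block) {
      step <- rnn_step(model$params, c(k / model$n_train, v_in), h_free)
      pred[k] <- step$V
      h_free <- step$h
      v_in <- step$V
    }
    # re-condition on the observed values of the block
    h <- advance_hidden(model, v, block, h)
    boundaries <- c(boundaries, block[length(block)])
    t <- block[length(block)] + 1L
  }
  structure(list(series = data.frame(epsilon = seq_len(n), observed = v,
                                     forecast = pred),
                 start = start, stride = stride, boundaries = boundaries),
            class = "tk_forecast")
}

#' @export
print.tk_forecast <- function(x, ...) {
  fc <- x$series$forecast[!is.na(x$series$forecast)]
  cat(sprintf("rolling forecast: %d steps from epsilon %d (stride %d)\n",
              length(fc), x$start, x$stride))
  cat(sprintf("  forecast mean %.3f, range [%.3f, %.3f]\n",
              mean(fc), min(fc), max(fc)))
  invisible(x)
}

#' @export
plot.tk_forecast <- function(x, ...) {
  s <- x$series
  plot(s$epsilon, s$observed, type = "l", col = "grey40",
       xlab = "dialogical time (epsilon)", ylab = "vergence",
       ylim = c(0, 1), ...)
  graphics::lines(s$epsilon, s$forecast, col = "firebrick")
  graphics::abline(v = x$start, lty = 3)
  graphics::legend("bottomleft", legend = c("observed", "forecast"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Counterfactual prompt forecast
#'
#' Compares the factual rolling forecast with the forecast obtained when
#' the conditioning series is modified at `intervention_epsilon` as if a
#' positively polarized speech act had occurred there: a phantom
#' `delta = 1` flag is attached at that position and the running vergence
#' recomputed, so every window covering the intervention averages one
#' extra positive act. Both forecasts then proceed by
#' [rolling_forecast()] from `start`.
#'
#' @param model A fitted [vergence_rnn()].
#' @param delta Binary polarity flag sequence underlying the conditioning
#'   series (e.g. `delta_task` per act), or a `metric_series` carrying a
#'   `"delta"` attribute (as produced by [generate_regime_series()]).
#' @param intervention_epsilon Position of the counterfactual positive
#'   act.
#' @param window Running-vergence window used to build the conditioning
#'   series (default 20, matching [running_vergence()]).
#' @param start First forecast index (defaults to the intervention).
#' @param stride Re-conditioning stride (default 3).
#' @return Object of class `tk_counterfactual`: list with `factual` and
#'   `counterfactual` forecasts ([rolling_forecast()] objects) and the
#'   intervention position.
#' @export
counterfactual_forecast <- function(model, delta, intervention_epsilon,
                                    window = 20, start = NULL,
                                    stride = 3) {
  if (inherits(delta, "metric_series")) {
    if (!is.null(attr(delta, "window"))) window <- attr(delta, "window")
    delta <- attr(delta, "delta")
    if (is.null(delta))
      stop("metric_series carries no \"delta\" attribute", call. = FALSE)
  }
  delta <- as.integer(delta)
  n <- length(delta)
  if (intervention_epsilon < 1 || intervention_epsilon > n)
    stop("intervention_epsilon must lie within the series", call. = FALSE)
  if (is.null(start)) start <- intervention_epsilon
  v_f <- running_prop(delta, window)
  v_cf <- running_prop(delta, window, insert_at = intervention_epsilon)
  structure(
    list(factual = rolling_forecast(model, v_f, start = start,
                                    stride = stride),
         counterfactual = rolling_forecast(model, v_cf, start = start,
                                           stride = stride),
         intervention = intervention_epsilon),
    class = "tk_counterfactual")
}

#' @export
print.tk_counterfactual <- function(x, ...) {
  f <- x$factual$series$forecast
  cf <- x$counterfactual$series$forecast
  keep <- !is.na(f)
  cat(sprintf("counterfactual prompt forecast (intervention at epsilon %d)\n",
              x$intervention))
  cat(sprintf("  factual mean %.3f vs counterfactual mean %.3f over %d steps\n",
              mean(f[keep]), mean(cf[keep]), sum(keep)))
  invisible(x)
}

#' Serialize forecaster parameters to JSON
#'
#' Writes the trained weights at full precision so a model reloads
#' exactly.
#'
#' @param model A `vergence_rnn` or `rnn_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnn_params <- function(model, path) {
  p <- if (inherits(model, "vergence_rnn")) model$params else model
  stopifnot(inherits(p, "rnn_params"))
  payload <- list(hidden = p$hidden, n_input = p$n_input,
                  sigma_h = p$sigma_h, sigma_y = p$sigma_y,
                  Wxh = p$Wxh, Whh = p$Whh, bh = p$bh, Why = p$Why,
                  by = p$by)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload forecaster parameters written by [write_rnn_params()]
#' @param path JSON file path.
#' @return An `rnn_params` object.
#' @export
read_rnn_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rnn_params(Wxh = matrix(unlist(p$Wxh), p$hidden, p$n_input),
             Whh = matrix(unlist(p$Whh), p$hidden, p$hidden),
             bh = as.numeric(p$bh), Why = as.numeric(p$Why),
             by = as.numeric(p$by), sigma_h = p$sigma_h,
             sigma_y = p$sigma_y)
}
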