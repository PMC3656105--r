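#' Fitting configuration
#'
#' Settings for the trace-processing and multistart fitting pipeline. The
#' default bounds follow the group-fit protocol: upper bound 200 on every
#' parameter, lower bound 0.01 on all except `r4`, whose lower bound is 190
#' because the shunt resistance is assumed much larger than the others.
#'
#' @param n_starts number of random multistart points.
#' @param seed RNG seed for drawing starts.
#' @param lower,upper named numeric vectors of per-parameter bounds over
#'   `r1, r2, r3, r4, c1, c2` (strictly `lower < upper`).
#' @param v0_fixed input pressure held fixed during the fit (85 mmHg for
#'   the control group, 75 for SCI).
#' @param fit_window length (s) of the post-release window fitted (the
#'   first 4 minutes carry the peak and the decay; later data add nothing).
#' @param lowpass_cutoff,lowpass_order zero-phase Butterworth low-pass
#'   settings (Hz / filter order) applied to raw traces; `NA` disables
#'   filtering (useful for noiseless synthetic data).
#' @param resample_fs common grid rate (Hz) used when averaging traces.
#' @param maxit,reltol simplex iteration cap and convergence tolerance
#'   per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 1000, seed = 1,
                       lower = c(r1 = 0.01, r2 = 0.01, r3 = 0.01,
                                 r4 = 190, c1 = 0.01, c2 = 0.01),
                       upper = c(r1 = 200, r2 = 200, r3 = 200,
                                 r4 = 200, c1 = 200, c2 = 200),
                       v0_fixed = 85,
                       fit_window = 240,
                       lowpass_cutoff = 0.2,
                       lowpass_order = 4,
                       resample_fs = 4,
                       maxit = 2000,
                       reltol = 1e-8) {
  pn <- c("r1", "r2", "r3", "r4", "c1", "c2")
  lower <- lower[pn]; upper <- upper[pn]
  if (anyNA(lower) || anyNA(upper))
    stop("lower and upper must name all of r1..r4, c1, c2", call. = FALSE)
  if (!all(lower < upper))
    stop("need lower < upper for every parameter", call. = FALSE)
  stopifnot(n_starts >= 1, fit_window > 0, v0_fixed > 0,
            is.na(lowpass_cutoff) || lowpass_cutoff > 0,
            lowpass_order >= 1, resample_fs > 0)
  structure(list(n_starts = n_starts, seed = seed, lower = lower,
                 upper = upper, v0_fixed = v0_fixed,
                 fit_window = fit_window,
                 lowpass_cutoff = lowpass_cutoff,
                 lowpass_order = lowpass_order,
                 resample_fs = resample_fs,
                 maxit = maxit, reltol = reltol),
            class = "fit_config")
}

#' Zero-phase low-pass filtering of a trace
#'
#' Forward-backward Butterworth filtering (zero phase shift, squared
#' magnitude response). The record is extended at both ends by reflection
#' before filtering so that the DC level and the edges are preserved.
#'
#' @param trace a [bf_trace()].
#' @param config a [fit_config()] supplying cutoff (Hz) and order.
#' @return The filtered [bf_trace()]; length and timestamps unchanged.
#' @export
lowpass <- function(trace, config = fit_config()) {
  if (is.na(config$lowpass_cutoff)) return(trace)  # filtering disabled
  ny <- trace$fs / 2
  if (config$lowpass_cutoff >= ny)
    stop("lowpass cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(config$lowpass_order, config$lowpass_cutoff / ny,
                       type = "low")
  x <- trace$flux
  n <- length(x)
  # remove the mean (restored below, so DC is preserved exactly) and
  # extend both ends by reflection to suppress edge transients
  mu <- mean(x)
  xc <- x - mu
  npad <- min(n - 1, ceiling(10 * trace$fs / config$lowpass_cutoff))
  xp <- c(2 * xc[1] - xc[(npad + 1):2], xc,
          2 * xc[n] - xc[(n - 1):(n - npad)])
  yp <- signal::filtfilt(bf, xp)
  retrace(trace, yp[(npad + 1):(npad + n)] + mu)
}

#' Crop a trace to its post-release window
#'
#' Keeps the samples in `[t_release, t_release + window]` and re-times them
#' so that release is at `t = 0`.
#'
#' @param trace a [bf_trace()].
#' @param window window length in seconds.
#' @return The cropped [bf_trace()] with `t_release = 0`.
#' @export
crop_post_release <- function(trace, window = 240) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  keep <- trace$t >= trace$t_release & trace$t <= trace$t_release + window
  if (sum(keep) < 2)
    stop("insufficient post-release data for the requested window",
         call. = FALSE)
  bf_trace(trace$flux[keep], fs = trace$fs, subject_id = trace$subject_id,
           group = trace$group, t_release = 0)
}

#' Average traces of one group on a common grid
#'
#' Resamples every trace (assumed aligned at release, i.e. already cropped)
#' onto a common uniform grid by linear interpolation, then takes the
#' pointwise mean. The common grid spans the shortest record.
#'
#' @param traces list of [bf_trace()] of a single group.
#' @param resample_fs grid rate in Hz.
#' @return The group-average [bf_trace()].
#' @export
average_group <- function(traces, resample_fs = 4) {
  if (length(traces) == 0) stop("empty trace list", call. = FALSE)
  groups <- unique(vapply(traces, `[[`, character(1), "group"))
  if (length(groups) != 1)
    stop("all traces must belong to one group", call. = FALSE)
  t_max <- min(vapply(traces, function(tr) max(tr$t), numeric(1)))
  grid <- seq(0, t_max, by = 1 / resample_fs)
  mat <- vapply(traces,
                function(tr) stats::approx(tr$t, tr$flux, xout = grid)$y,
                numeric(length(grid)))
  avg <- rowMeans(mat)
  bf_trace(avg, fs = resample_fs, subject_id = "group-average",
           group = groups, t_release = 0)
}

#' Sum-of-squares error of a circuit against a target trace
#'
#' The fitting objective: the model's closed-form post-release flow,
#' evaluated at the target's sample times (release at `t = 0`, zero stored
#' volume), compared to the target by a plain sum of squared residuals.
#' Invalid or degenerate parameter vectors return `Inf` so optimizers can
#' step over them.
#'
#' @param params a [circuit_params()] (or a list-alike with the 7 fields).
#' @param target a [bf_trace()] cropped to the fit window.
#' @return Non-negative error, or `Inf` for invalid parameters.
#' @export
sse_error <- function(params, target) {
  y <- tryCatch(
    suppressWarnings(predict(step_response(params), target$t)),
    error = function(e) NULL)
  if (is.null(y) || !all(is.finite(y))) return(Inf)
  sum((y - target$flux)^2)
}

# logistic box transform: unconstrained z <-> bounded p
box_encode <- function(p, lo, hi) stats::qlogis(pmin(pmax((p - lo) / (hi - lo),
                                                          1e-12), 1 - 1e-12))
box_decode <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

# Multistart bounded Nelder-Mead on the step-response SSE.
multistart_fit <- function(target, config) {
  lo <- config$lower; hi <- config$upper
  v0 <- config$v0_fixed
  mkpar <- function(p) {
    p <- unname(p)
    suppressWarnings(circuit_params(p[1], p[2], p[3], p[4], p[5], p[6], v0))
  }
  obj <- function(z) {
    p <- box_decode(z, lo, hi)
    pars <- tryCatch(mkpar(p), error = function(e) NULL)
    if (is.null(pars)) return(Inf)
    sse_error(pars, target)
  }
  with_seed(config$seed, {
    starts <- matrix(stats::runif(6 * config$n_starts), ncol = 6)
    starts <- sweep(sweep(starts, 2, hi - lo, `*`), 2, lo, `+`)
    best <- NULL
    n_conv <- 0L
    for (i in seq_len(config$n_starts)) {
      z0 <- box_encode(starts[i, ], lo, hi)
      fit <- tryCatch(
        stats::optim(z0, obj, method = "Nelder-Mead",
                     control = list(maxit = config$maxit,
                                    reltol = config$reltol)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      n_conv <- n_conv + 1L
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        best$start_used <- i
      }
    }
    if (is.null(best))
      stop("no multistart point converged; check bounds and target",
           call. = FALSE)
    p <- box_decode(best$par, lo, hi)
    structure(list(params = mkpar(p),
                   error = best$value,
                   start_used = best$start_used,
                   n_converged = n_conv,
                   seed = config$seed,
                   config = config),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result>  E = %.6g  (start %d of %d converged, seed %s)\n",
              x$error, x$start_used, x$n_converged, format(x$seed)))
  print(x$params)
  invisible(x)
}

#' Fit a circuit to a group of traces
#'
#' The group-fitting pipeline: zero-phase low-pass filtering, cropping to
#' the post-release window, averaging on a common grid, then bounded
#' multistart Nelder-Mead minimization of the sum-of-squares error between
#' the closed-form step response and the averaged trace. Bounds are
#' enforced through a logistic parameter transform so every evaluated point
#' is feasible; starts are drawn uniformly inside the bound box from the
#' seeded generator. Deterministic given the seed.
#'
#' @param traces list of [bf_trace()] from one group.
#' @param config a [fit_config()]; `v0_fixed` must be the group's input
#'   pressure.
#' @return A `fit_result` with fields `params`, `error`, `start_used`,
#'   `n_converged`, `seed`, `config`.
#' @export
fit_group <- function(traces, config = fit_config()) {
  filt <- lapply(traces, lowpass, config = config)
  crop <- lapply(filt, crop_post_release, window = config$fit_window)
  avg <- average_group(crop, resample_fs = config$resample_fs)
  if (max(abs(avg$flux)) == 0)
    warning("degenerate (all-zero) target trace", call. = FALSE)
  multistart_fit(avg, config)
}

#' Fit a circuit to a single subject
#'
#' As [fit_group()] with a single trace and no averaging (the trace is
#' still filtered, cropped and resampled onto the common grid).
#'
#' @param trace a [bf_trace()].
#' @inheritParams fit_group
#' @return A `fit_result`.
#' @export
fit_subject <- function(trace, config = fit_config()) {
  fit_group(list(trace), config)
}

#' Derive the SCI fitting configuration from a control fit
#'
#' The SCI group is fitted with input pressure 75 mmHg and with the upper
#' bounds of both compliances lowered to the control group's best-fit
#' values, encoding the observation that vessel compliance is reduced
#' after SCI.
#'
#' @param control_fit the control group's `fit_result`.
#' @param base a [fit_config()] to modify.
#' @return A new [fit_config()] for the SCI group.
#' @export
sci_bounds_from_control <- function(control_fit, base = fit_config()) {
  upper <- base$upper
  upper["c1"] <- control_fit$params$c1
  upper["c2"] <- control_fit$params$c2
  fit_config(n_starts = base$n_starts, seed = base$seed,
             lower = base$lower, upper = upper,
             v0_fixed = 75,
             fit_window = base$fit_window,
             lowpass_cutoff = base$lowpass_cutoff,
             lowpass_order = base$lowpass_order,
             resample_fs = base$resample_fs,
             maxit = base$maxit, reltol = base$reltol)
}

#' Write a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  out <- list(params = unclass(fit$params),
              error = fit$error,
              start_used = fit$start_used,
              n_converged = fit$n_converged,
              seed = fit$seed,
              config = list(n_starts = fit$config$n_starts,
                            lower = as.list(fit$config$lower),
                            upper = as.list(fit$config$upper),
                            v0_fixed = fit$config$v0_fixed,
                            fit_window = fit$config$fit_window,
                            lowpass_cutoff = fit$config$lowpass_cutoff,
                            lowpass_order = fit$config$lowpass_order,
                            resample_fs = fit$config$resample_fs))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path JSON path.
#' @return A `fit_result` (config echo as plain list).
#' @export
read_fit_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  structure(list(params = circuit_params(p$r1, p$r2, p$r3, p$r4,
                                         p$c1, p$c2, p$v0),
                 error = x$error, start_used = x$start_used,
                 n_converged = x$n_converged, seed = x$seed,
                 config = x$config),
            class = "fit_result")
}
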