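#' Synthetic-trace generator configuration
#'
#' Describes a reactive-hyperemia acquisition to emulate: a pre-occlusion
#' baseline at resting flow, a long occlusion at the biological-zero level,
#' and a post-release segment following the circuit's closed-form step
#' response, with flowmotion oscillations and additive noise on top.
#'
#' @param group `"CTRL"` or `"SCI"`; selects the default base circuit.
#' @param base_params group-level [circuit_params()] around which subjects
#'   are drawn; defaults to the fitted group circuit.
#' @param subject_cv relative spread (log-normal coefficient of variation)
#'   of the per-subject parameter draws.
#' @param fs sampling rate in Hz.
#' @param baseline_duration,occlusion_duration,post_duration segment
#'   durations in seconds (20 min occlusion by default).
#' @param noise_sd additive Gaussian noise, as a fraction of the subject's
#'   resting flow.
#' @param flowmotion list of `c(frequency_hz, amplitude_fraction)` pairs;
#'   each sinusoid gets a random phase per subject. The defaults place small
#'   oscillations in the endothelial/myogenic/cardiac bands.
#' @param biological_zero residual flux during full occlusion, as a
#'   fraction of resting flow (occluded Doppler signals are not exactly 0).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(group = c("CTRL", "SCI"),
                         base_params = NULL,
                         subject_cv = 0.15,
                         fs = 32,
                         baseline_duration = 120,
                         occlusion_duration = 1200,
                         post_duration = 600,
                         noise_sd = 0.10,
                         flowmotion = list(c(0.01, 0.05), c(0.1, 0.05), c(1, 0.03)),
                         biological_zero = 0.05) {
  group <- match.arg(group)
  if (is.null(base_params))
    base_params <- if (group == "CTRL") control_circuit() else sci_circuit()
  stopifnot(inherits(base_params, "circuit_params"),
            subject_cv >= 0, fs > 0,
            baseline_duration > 0, occlusion_duration > 0, post_duration > 0,
            noise_sd >= 0, biological_zero >= 0)
  fmax <- max(vapply(flowmotion, `[`, numeric(1), 1), 0)
  if (fs <= 2 * fmax)
    stop("fs must exceed twice the highest flowmotion frequency", call. = FALSE)
  structure(list(group = group, base_params = base_params,
                 subject_cv = subject_cv, fs = fs,
                 baseline_duration = baseline_duration,
                 occlusion_duration = occlusion_duration,
                 post_duration = post_duration,
                 noise_sd = noise_sd, flowmotion = flowmotion,
                 biological_zero = biological_zero),
            class = "synth_config")
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Generate one synthetic reactive-hyperemia trace
#'
#' Concatenates baseline (resting flow), occlusion (biological zero) and the
#' post-release closed-form step response of `subject_params`, then adds
#' flowmotion sinusoids with seeded random phases and additive Gaussian
#' noise, clipping at zero. The ground truth (parameters, noiseless
#' post-release curve, resting flow, peak time) is attached as attribute
#' `"truth"`.
#'
#' @param config a [synth_config()].
#' @param subject_params the subject's [circuit_params()]; defaults to the
#'   config's base parameters.
#' @param seed RNG seed (the same seed reproduces the trace exactly).
#' @param subject_id label for the trace.
#' @return A [bf_trace()] with a `"truth"` attribute.
#' @export
synth_trace <- function(config, subject_params = config$base_params,
                        seed = NULL, subject_id = "S1") {
  with_seed(seed, {
    fs <- config$fs
    rest <- steady_state(subject_params)
    sr <- step_response(subject_params)
    n_base <- round(config$baseline_duration * fs)
    n_occl <- round(config$occlusion_duration * fs)
    n_post <- round(config$post_duration * fs)
    t_post <- (seq_len(n_post) - 1) / fs
    clean <- c(rep(rest, n_base),
               rep(config$biological_zero * rest, n_occl),
               predict(sr, t_post))
    n <- length(clean)
    t_all <- (seq_len(n) - 1) / fs
    osc <- 0
    for (fm in config$flowmotion) {
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- osc + fm[2] * rest * sin(2 * pi * fm[1] * t_all + phase)
    }
    noisy <- clean + osc + stats::rnorm(n, sd = config$noise_sd * rest)
    noisy <- pmax(noisy, 0)
    tr <- bf_trace(noisy, fs = fs, subject_id = subject_id,
                   group = config$group,
                   t_release = (n_base + n_occl) / fs)
    attr(tr, "truth") <- list(params = subject_params,
                              step_response = sr,
                              i2_rest = rest,
                              time_to_peak = time_to_peak(sr),
                              post_t = t_post,
                              post_clean = predict(sr, t_post))
    tr
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject circuit parameters log-normally around the config's
#' base parameters (mean-preserving, coefficient of variation
#' `subject_cv`), then generates one trace per subject. For an SCI cohort
#' the drawn compliances are additionally capped at the control group's
#' base values, reflecting the reduced vessel compliance after SCI.
#'
#' @param config a [synth_config()].
#' @param n_subjects cohort size.
#' @param seed RNG seed for the whole cohort.
#' @return A list with `traces` (list of [bf_trace()]) and `truth`
#'   (data frame of per-subject parameters and derived quantities).
#' @export
synth_cohort <- function(config, n_subjects = 6, seed = NULL) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    base <- config$base_params
    cv <- config$subject_cv
    sdlog <- sqrt(log(1 + cv^2))
    draw <- function(mu) {
      if (cv == 0) return(rep(mu, n_subjects))
      stats::rlnorm(n_subjects, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }
    pars <- lapply(c(r1 = "r1", r2 = "r2", r3 = "r3", r4 = "r4",
                     c1 = "c1", c2 = "c2"),
                   function(f) draw(base[[f]]))
    if (config$group == "SCI") {
      cc <- control_circuit()
      pars$c1 <- pmin(pars$c1, cc$c1)
      pars$c2 <- pmin(pars$c2, cc$c2)
    }
    traces <- vector("list", n_subjects)
    truth <- vector("list", n_subjects)
    for (j in seq_len(n_subjects)) {
      pj <- suppressWarnings(
        circuit_params(pars$r1[j], pars$r2[j], pars$r3[j], pars$r4[j],
                       pars$c1[j], pars$c2[j], base$v0))
      id <- sprintf("%s%02d", if (config$group == "CTRL") "C" else "A", j)
      traces[[j]] <- synth_trace(config, pj, seed = NULL, subject_id = id)
      tt <- attr(traces[[j]], "truth")
      truth[[j]] <- data.frame(subject_id = id, group = config$group,
                               r1 = pj$r1, r2 = pj$r2, r3 = pj$r3, r4 = pj$r4,
                               c1 = pj$c1, c2 = pj$c2, v0 = pj$v0,
                               i2_rest = tt$i2_rest,
                               time_to_peak = tt$time_to_peak)
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}
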