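#' Run one hybrid simulation
#'
#' Advances a freshly initialized world under a cyclic pressure schedule,
#' recording the mean epithelial health (dead cells count as 0) every tick.
#' "Substantial tissue damage" is the death of at least `n_deaths`
#' epithelial agents within the run.
#'
#' @param circuit a [circuit_params()].
#' @param abm an [abm_params()].
#' @param schedule a [pressure_schedule()].
#' @param n_steps number of ticks to simulate.
#' @param seed world RNG seed.
#' @param grid a [grid_config()].
#' @param n_deaths epithelial deaths that constitute substantial damage.
#' @param stop_on_death stop early once substantial damage has occurred
#'   (the health curve is then truncated).
#' @return A list with `world` (final state), `health` (data frame
#'   `tick`, `mean_health`), `damage_flag`, `n_dead` and `tp`.
#' @export
run_simulation <- function(circuit, abm, schedule, n_steps = 2000, seed = 1,
                           grid = grid_config(), n_deaths = 1,
                           stop_on_death = FALSE) {
  world <- init_world(grid, abm, circuit, seed = seed)
  ncell <- length(world$health)
  mh <- numeric(n_steps)
  steps_run <- n_steps
  for (i in seq_len(n_steps)) {
    world <- step_world(world, schedule)
    mh[i] <- sum(world$health) / ncell
    if (stop_on_death && (ncell - sum(world$alive)) >= n_deaths) {
      steps_run <- i
      break
    }
  }
  n_dead <- ncell - sum(world$alive)
  list(world = world,
       health = data.frame(tick = seq_len(steps_run),
                           mean_health = mh[seq_len(steps_run)]),
       damage_flag = n_dead >= n_deaths,
       n_dead = n_dead,
       tp = schedule$tp)
}

#' Minimal damaging pressure interval
#'
#' For each seed, finds the smallest pressure interval `tp` in `tp_range`
#' for which at least `n_deaths` epithelial agents die within `n_steps`
#' ticks: an ascending coarse scan brackets the threshold, then bisection
#' (valid under the monotone-harm property) refines it to one tick. Seeds
#' where no interval in range causes damage are reported as right-censored
#' (`NA`). The median of the per-seed minima is the headline value.
#'
#' @param circuit a [circuit_params()].
#' @param abm an [abm_params()].
#' @param v_min,v_max schedule pressures (mmHg); `v_max` defaults to the
#'   circuit's `v0`.
#' @param n_steps ticks per run.
#' @param seeds integer vector of replicate seeds.
#' @param tp_range `c(lo, hi)` bounds of the interval search (ticks).
#' @param coarse_step step of the ascending scan before bisection.
#' @param grid a [grid_config()].
#' @param n_deaths damage threshold (deaths).
#' @return A `sweep_result` list: `group` (from `v_max`), `min_tp`
#'   (per seed), `median_min_tp`, `seeds`, `n_steps`, `censored`.
#' @export
find_min_interval <- function(circuit, abm, v_min = 40, v_max = circuit$v0,
                              n_steps = 2000, seeds = 1:5,
                              tp_range = c(5, 400), coarse_step = 50,
                              grid = grid_config(), n_deaths = 1) {
  stopifnot(length(tp_range) == 2, tp_range[1] >= 1,
            tp_range[2] >= tp_range[1])
  damaging <- function(tp, seed) {
    sch <- pressure_schedule(v_max = v_max, v_min = v_min, tp = tp)
    run_simulation(circuit, abm, sch, n_steps = n_steps, seed = seed,
                   grid = grid, n_deaths = n_deaths,
                   stop_on_death = TRUE)$damage_flag
  }
  per_seed <- vapply(seeds, function(seed) {
    lo <- tp_range[1]
    if (damaging(lo, seed)) return(as.numeric(lo))
    # ascending scan to bracket the threshold
    hi <- NA_real_
    last_ok <- lo
    for (tp in seq(lo + coarse_step, tp_range[2], by = coarse_step)) {
      if (damaging(tp, seed)) { hi <- tp; break }
      last_ok <- tp
    }
    if (is.na(hi)) {
      if (last_ok < tp_range[2] && damaging(tp_range[2], seed)) {
        hi <- tp_range[2]
      } else return(NA_real_)  # right-censored
    }
    lo <- last_ok
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (damaging(mid, seed)) hi <- mid else lo <- mid
    }
    as.numeric(hi)
  }, numeric(1))
  structure(list(group = if (v_max >= 80) "CTRL" else "SCI",
                 min_tp = per_seed,
                 median_min_tp = stats::median(per_seed, na.rm = TRUE),
                 seeds = seeds,
                 n_steps = n_steps,
                 censored = is.na(per_seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: median minimal interval %s ticks\n",
              x$group, format(x$median_min_tp)))
  cat("  per seed:", paste(ifelse(is.na(x$min_tp), "censored", x$min_tp),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Subject-specific minimal-interval table
#'
#' Runs the minimal-interval search for each subject's fitted circuit and
#' tabulates the per-subject values with per-group arithmetic means
#' (rounded to the nearest integer in the summary attribute).
#'
#' @param fit_results named list of per-subject `fit_result` objects (or
#'   bare [circuit_params()]); names are subject ids.
#' @param groups character vector of group labels, one per subject.
#' @param abm an [abm_params()].
#' @param ... passed to [find_min_interval()] (seeds, n_steps, grid, ...).
#' @return A data frame `subject`, `group`, `min_tp` with attribute
#'   `group_means`.
#' @export
subject_table <- function(fit_results, groups, abm, ...) {
  stopifnot(length(fit_results) == length(groups))
  ids <- names(fit_results) %||% sprintf("S%d", seq_along(fit_results))
  rows <- lapply(seq_along(fit_results), function(j) {
    fr <- fit_results[[j]]
    circ <- if (inherits(fr, "fit_result")) fr$params else fr
    sw <- find_min_interval(circ, abm, ...)
    data.frame(subject = ids[j], group = groups[j],
               min_tp = sw$median_min_tp)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_means") <- interval_group_means(out)
  out
}

#' Group means of per-subject minimal intervals
#'
#' The reporting arithmetic: the per-group arithmetic mean of the
#' per-subject minimal pressure intervals, rounded to the nearest integer.
#'
#' @param table data frame with columns `group` and `min_tp`.
#' @return Named numeric vector of rounded group means.
#' @export
interval_group_means <- function(table) {
  stopifnot(all(c("group", "min_tp") %in% names(table)))
  means <- tapply(table$min_tp, table$group, mean)
  stats::setNames(as.numeric(round(means)), names(means))
}

#' Read the packaged printed per-subject minimal intervals
#'
#' The published per-subject minimal damaging pressure intervals
#' (six control, six SCI subjects), shipped as a small fixture for the
#' reporting path.
#'
#' @return Data frame `subject`, `group`, `min_tp`.
#' @export
printed_subject_intervals <- function() {
  path <- system.file("extdata", "printed_subject_intervals.csv",
                      package = "ulcersim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Health-curve report
#'
#' Writes all health curves to one long CSV and, optionally, an overlay
#' plot of mean epithelial health versus tick, one line per pressure
#' interval.
#'
#' @param curves list of health data frames as returned in
#'   `run_simulation()$health`, each with an associated `tp` (taken from
#'   list names or a `tp` column).
#' @param csv_path output CSV path.
#' @param png_path optional output PNG path for the overlay plot.
#' @return The combined long data frame, invisibly.
#' @export
health_report <- function(curves, csv_path, png_path = NULL) {
  stopifnot(length(curves) >= 1)
  labs <- names(curves) %||% as.character(seq_along(curves))
  long <- do.call(rbind, lapply(seq_along(curves), function(j) {
    cv <- curves[[j]]
    data.frame(tp = labs[j], tick = cv$tick, mean_health = cv$mean_health)
  }))
  utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 600, type = "cairo")
    on.exit(grDevices::dev.off())
    cols <- grDevices::hcl.colors(length(curves), "Dark 3")
    plot(NULL, xlim = range(long$tick), ylim = c(0, 1.02),
         xlab = "tick", ylab = "mean epithelial health")
    for (j in seq_along(curves))
      graphics::lines(curves[[j]]$tick, curves[[j]]$mean_health,
                      col = cols[j], lwd = 2)
    graphics::legend("bottomleft", legend = paste("tp =", labs),
                     col = cols, lwd = 2, bty = "n")
  }
  invisible(long)
}
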