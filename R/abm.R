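#' Square-wave external-pressure schedule
#'
#' Cyclic loading: external pressure applied for `tp` ticks (input pressure
#' driven to `v_min`), then released for `tp` ticks (`v_max`), repeated.
#' The pressure-on phase comes first.
#'
#' @param v_max input pressure with external pressure released (mmHg);
#'   normally the circuit's `v0`.
#' @param v_min input pressure with external pressure applied (mmHg).
#' @param tp the pressure interval: half-period in ticks (integer, >= 1).
#' @return An object of class `pressure_schedule`.
#' @export
pressure_schedule <- function(v_max = 85, v_min = 40, tp = 210) {
  tp <- as.integer(tp)
  if (!(v_max >= v_min && v_min > 0))
    stop("need v_max >= v_min > 0", call. = FALSE)
  if (tp < 1) stop("tp must be a positive integer", call. = FALSE)
  structure(list(v_max = v_max, v_min = v_min, tp = tp),
            class = "pressure_schedule")
}

#' Input pressure at a simulation tick
#'
#' @param schedule a [pressure_schedule()].
#' @param tick tick index (vectorized, `tick >= 0`).
#' @return Pressure in mmHg (`v_min` during pressure-on half-periods).
#' @export
pressure_at <- function(schedule, tick) {
  ifelse(tick %% (2 * schedule$tp) < schedule$tp,
         schedule$v_min, schedule$v_max)
}

#' Grid configuration
#'
#' @param width,height grid size in cells (>= 8).
#' @param vessel_spacing lattice spacing of blood vessels in cells (>= 2).
#' @param wrap toroidal edges (Moore neighborhoods wrap around).
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(width = 40, height = 40, vessel_spacing = 4,
                        wrap = TRUE) {
  if (width < 8 || height < 8) stop("grid must be at least 8x8", call. = FALSE)
  if (vessel_spacing < 2) stop("vessel_spacing must be >= 2", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 vessel_spacing = as.integer(vessel_spacing),
                 wrap = isTRUE(wrap)),
            class = "grid_config")
}

#' Agent-rule rate constants
#'
#' All per-tick rates of the tissue model. Health is on a 0--1 scale;
#' fields are in arbitrary concentration units normalized so that the
#' resting spatial means of oxygen and TGF-beta are near 1 on the default
#' 40x40 grid. One tick corresponds to `dt_ode` seconds of circuit time.
#'
#' @param kd_pressure epithelial health lost per tick under sustained
#'   external pressure (after `t_damage_lag` contiguous pressure ticks).
#' @param t_damage_lag contiguous pressure ticks tolerated before pressure
#'   damage begins: brief ischemic bouts do not injure tissue, which is
#'   the physiological basis of turning schedules.
#' @param k_tnf_secrete TNF-alpha deposited per tick by a damaged
#'   epithelial cell.
#' @param theta_tnf local TNF-alpha level above which epithelium takes
#'   inflammatory damage.
#' @param kt_tnf health lost per unit of TNF-alpha above `theta_tnf`.
#' @param kh_heal healing gain: health recovered per tick per unit of
#'   (local TGF-beta x local oxygen).
#' @param theta_damaged health level below which a cell counts as damaged
#'   and secretes TNF-alpha.
#' @param mac_lifespan macrophage lifespan in ticks.
#' @param mac_tnf_rate,mac_tgf_rate TNF-alpha / TGF-beta deposited per tick
#'   by each macrophage.
#' @param k_oxygen oxygen released per tick by a vessel at normalized
#'   flow 1 (flow is normalized by the released-pressure resting flow).
#' @param theta_perfusion perfusion threshold for oxygen delivery, as a
#'   fraction of resting flow: below it capillaries derecruit and a vessel
#'   releases no usable oxygen; above it release grows linearly, reaching
#'   `k_oxygen` at resting flow.
#' @param sat_perfusion ceiling on oxygen release, as a multiple of the
#'   resting release: delivery saturates during the hyperemic overshoot.
#' @param k_spawn macrophage spawn probability per vessel per tick at
#'   normalized flow 1 (clamped to \[0, 1\] after scaling by flow).
#' @param theta_chemotaxis minimum local TNF-alpha a macrophage can sense:
#'   below it the cell performs an unbiased random walk. Without this
#'   floor, macrophages climb the gradients of their own secretion trails
#'   and self-aggregate even in resting tissue.
#' @param dt_ode seconds of circuit-ODE time integrated per tick.
#' @param diff_oxygen,diff_tnf,diff_tgf per-tick diffusion fractions
#'   (share of a cell's content spread equally over its 8 Moore neighbors).
#' @param evap_oxygen,evap_tnf,evap_tgf per-tick evaporation fractions.
#' @return An object of class `abm_params`.
#' @export
abm_params <- function(kd_pressure = 0.006,
                       t_damage_lag = 41,
                       k_tnf_secrete = 0.05,
                       theta_tnf = 1.0,
                       kt_tnf = 0.02,
                       kh_heal = 0.0042,
                       theta_damaged = 0.9,
                       mac_lifespan = 120,
                       mac_tnf_rate = 0.01,
                       mac_tgf_rate = 0.0532,
                       k_oxygen = 0.8,
                       theta_perfusion = 0.75,
                       sat_perfusion = 3,
                       k_spawn = 0.05,
                       theta_chemotaxis = 0.5,
                       dt_ode = 1,
                       diff_oxygen = 0.8, evap_oxygen = 0.05,
                       diff_tnf = 0.8, evap_tnf = 0.10,
                       diff_tgf = 0.8, evap_tgf = 0.02) {
  p <- list(kd_pressure = kd_pressure, t_damage_lag = t_damage_lag,
            k_tnf_secrete = k_tnf_secrete,
            theta_tnf = theta_tnf, kt_tnf = kt_tnf, kh_heal = kh_heal,
            theta_damaged = theta_damaged,
            mac_lifespan = as.integer(mac_lifespan),
            mac_tnf_rate = mac_tnf_rate, mac_tgf_rate = mac_tgf_rate,
            k_oxygen = k_oxygen, theta_perfusion = theta_perfusion,
            sat_perfusion = sat_perfusion, k_spawn = k_spawn,
            theta_chemotaxis = theta_chemotaxis, dt_ode = dt_ode,
            diff_oxygen = diff_oxygen, evap_oxygen = evap_oxygen,
            diff_tnf = diff_tnf, evap_tnf = evap_tnf,
            diff_tgf = diff_tgf, evap_tgf = evap_tgf)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all rate constants must be finite and non-negative", call. = FALSE)
  if (p$theta_damaged <= 0 || p$theta_damaged >= 1)
    stop("theta_damaged must lie in (0, 1)", call. = FALSE)
  if (p$theta_perfusion >= 1)
    stop("theta_perfusion must lie in [0, 1)", call. = FALSE)
  if (p$sat_perfusion < 1)
    stop("sat_perfusion must be at least 1", call. = FALSE)
  fr <- c(p$diff_oxygen, p$diff_tnf, p$diff_tgf,
          p$evap_oxygen, p$evap_tnf, p$evap_tgf)
  if (any(fr > 1))
    stop("diffusion and evaporation fractions must lie in [0, 1]",
         call. = FALSE)
  structure(p, class = "abm_params")
}

# 8-neighbor (Moore) linear index table for a width x height grid.
moore_table <- function(width, height, wrap = TRUE) {
  ix <- rep(seq_len(width), times = height)
  iy <- rep(seq_len(height), each = width)
  shifts <- rbind(c(-1, -1), c(0, -1), c(1, -1),
                  c(-1, 0), c(1, 0),
                  c(-1, 1), c(0, 1), c(1, 1))
  nbr <- matrix(0L, width * height, 8)
  for (k in 1:8) {
    nx <- ix + shifts[k, 1]; ny <- iy + shifts[k, 2]
    if (wrap) {
      nx <- ((nx - 1) %% width) + 1
      ny <- ((ny - 1) %% height) + 1
    } else {
      nx <- pmin(pmax(nx, 1L), width)
      ny <- pmin(pmax(ny, 1L), height)
    }
    nbr[, k] <- (ny - 1L) * width + nx
  }
  nbr
}

rng_restore <- function(world) {
  if (!is.null(world$rng))
    assign(".Random.seed", world$rng, envir = globalenv())
}
rng_save <- function(world) {
  world$rng <- get(".Random.seed", envir = globalenv())
  world
}

#' Initialize the tissue world at homeostasis
#'
#' Builds the grid with one full-health epithelial agent per cell and
#' vessels on a regular lattice, every vessel's flow at the
#' released-pressure steady state. The macrophage population is seeded at
#' its resting expected size (ages spread uniformly over the lifespan) and
#' the three fields are brought to their resting profiles by a burn-in of
#' full update steps under a constant (zero-amplitude) pressure, so that
#' simulations start from tissue at rest rather than from an empty,
#' unhealing grid.
#'
#' @param grid a [grid_config()].
#' @param abm an [abm_params()].
#' @param circuit a [circuit_params()]; `v0` is taken as the
#'   released-pressure level.
#' @param seed RNG seed; the world carries its own generator state and
#'   evolves reproducibly.
#' @param burn_in burn-in ticks for field equilibration.
#' @return A `world_state` list.
#' @export
init_world <- function(grid, abm, circuit, seed = 1, burn_in = 150) {
  w <- grid$width; h <- grid$height
  ncell <- w * h
  sp <- grid$vessel_spacing
  vx <- seq(sp %/% 2 + 1, w, by = sp)
  vy <- seq(sp %/% 2 + 1, h, by = sp)
  vpos <- as.integer(outer(vx, (vy - 1L) * w, `+`))
  set.seed(seed)
  rest <- steady_state(circuit)
  ss <- steady_flow_state(circuit)
  n_mac0 <- round(length(vpos) * min(abm$k_spawn, 1) * abm$mac_lifespan)
  world <- structure(class = "world_state", list(
    tick = 0L,
    grid = grid,
    abm = abm,
    circuit = circuit,
    nbr = moore_table(w, h, grid$wrap),
    health = matrix(1, w, h),
    alive = matrix(TRUE, w, h),
    fields = list(oxygen = matrix(0, w, h),
                  tnf = matrix(0, w, h),
                  tgf = matrix(0, w, h)),
    vessel_pos = vpos,
    vessel_alive = rep(TRUE, length(vpos)),
    flow = c(i1 = ss$i1, i2 = ss$i2),
    i2_rest = rest,
    mac_pos = sample.int(ncell, n_mac0, replace = TRUE),
    mac_age = if (n_mac0 > 0)
      sample.int(abm$mac_lifespan, n_mac0, replace = TRUE) - 1L
      else integer(0),
    on_streak = 0L,
    seed = seed))
  world <- rng_save(world)
  flat <- pressure_schedule(v_max = circuit$v0, v_min = circuit$v0, tp = 1)
  for (i in seq_len(burn_in)) world <- step_world(world, flat)
  world$tick <- 0L
  world
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("<world_state> tick %d, %dx%d grid\n", x$tick,
              x$grid$width, x$grid$height))
  cat(sprintf("  epithelium: %d alive / %d (mean health %.3f)\n",
              sum(x$alive), length(x$alive), mean(x$health)))
  cat(sprintf("  vessels: %d alive / %d (i2 = %.3f, rest %.3f)\n",
              sum(x$vessel_alive), length(x$vessel_alive),
              x$flow[["i2"]], x$i2_rest))
  cat(sprintf("  macrophages: %d\n", length(x$mac_pos)))
  invisible(x)
}

#' Diffuse and evaporate the three fields
#'
#' Each cell retains `1 - diffusion_frac` of its content and spreads
#' `diffusion_frac` equally over its 8 Moore neighbors; all cells are then
#' scaled by `1 - evaporation_frac`. Mass is conserved exactly under zero
#' evaporation; values stay non-negative.
#'
#' @param world a `world_state`.
#' @return The updated world.
#' @export
step_fields <- function(world) {
  nbr <- world$nbr
  p <- world$abm
  spec <- list(oxygen = c(p$diff_oxygen, p$evap_oxygen),
               tnf = c(p$diff_tnf, p$evap_tnf),
               tgf = c(p$diff_tgf, p$evap_tgf))
  for (nm in names(spec)) {
    f <- world$fields[[nm]]
    df <- spec[[nm]][1]; ev <- spec[[nm]][2]
    v <- as.numeric(f)
    inflow <- v[nbr[, 1]] + v[nbr[, 2]] + v[nbr[, 3]] + v[nbr[, 4]] +
      v[nbr[, 5]] + v[nbr[, 6]] + v[nbr[, 7]] + v[nbr[, 8]]
    out <- ((1 - df) * v + (df / 8) * inflow) * (1 - ev)
    world$fields[[nm]] <- matrix(out, nrow(f), ncol(f))
  }
  world
}

#' Advance the epithelial agents by one tick
#'
#' Per living cell, in order: pressure damage (once external pressure has
#' been applied for more than `t_damage_lag` contiguous ticks),
#' inflammatory damage from TNF-alpha above threshold, TNF-alpha secretion
#' if damaged, healing proportional to local TGF-beta x oxygen, clamping
#' to \[0, 1\], and death (irreversible) at health 0.
#'
#' @param world a `world_state`.
#' @param v_applied logical: is external pressure currently applied?
#' @return The updated world.
#' @export
step_epithelium <- function(world, v_applied) {
  p <- world$abm
  al <- world$alive
  h <- world$health
  tnf <- world$fields$tnf
  streak <- world$on_streak %||% 0L
  if (isTRUE(v_applied) && streak > p$t_damage_lag)
    h[al] <- h[al] - p$kd_pressure
  excess <- pmax(tnf[al] - p$theta_tnf, 0)
  h[al] <- h[al] - p$kt_tnf * excess
  damaged <- al & (h < p$theta_damaged)
  if (any(damaged)) {
    tnf[damaged] <- tnf[damaged] + p$k_tnf_secrete
    world$fields$tnf <- tnf
  }
  heal <- p$kh_heal * world$fields$tgf[al] * world$fields$oxygen[al]
  h[al] <- pmin(pmax(h[al] + heal, 0), 1)
  died <- al & (h <= 0)
  if (any(died)) {
    world$alive <- al & !died
    h[died] <- 0
  }
  world$health <- h
  world
}

#' Advance the macrophages by one tick
#'
#' Each macrophage moves to the Moore-neighbor cell with the highest
#' TNF-alpha if that strictly exceeds both its current cell and the
#' sensitivity floor `theta_chemotaxis` (ties broken uniformly at random);
#' otherwise it moves to a uniformly random neighbor. It then deposits TNF-alpha and TGF-beta at
#' the new cell and ages; macrophages at the end of their lifespan are
#' removed.
#'
#' @param world a `world_state`.
#' @return The updated world.
#' @export
step_macrophages <- function(world) {
  n <- length(world$mac_pos)
  if (n == 0) return(world)
  rng_restore(world)
  p <- world$abm
  tnf <- as.numeric(world$fields$tnf)
  nb <- world$nbr[world$mac_pos, , drop = FALSE]
  tn <- matrix(tnf[nb], n, 8)
  best <- tn[, 1]
  for (k in 2:8) best <- pmax(best, tn[, k])
  greedy <- best > pmax(tnf[world$mac_pos], p$theta_chemotaxis)
  col <- integer(n)
  if (any(greedy))
    col[greedy] <- max.col(tn[greedy, , drop = FALSE], ties.method = "random")
  if (any(!greedy))
    col[!greedy] <- sample.int(8, sum(!greedy), replace = TRUE)
  newpos <- nb[cbind(seq_len(n), col)]
  ncell <- length(tnf)
  dep <- tabulate(newpos, nbins = ncell)
  world$fields$tnf <- world$fields$tnf + p$mac_tnf_rate *
    matrix(dep, nrow(world$fields$tnf))
  world$fields$tgf <- world$fields$tgf + p$mac_tgf_rate *
    matrix(dep, nrow(world$fields$tgf))
  age <- world$mac_age + 1L
  keep <- age < p$mac_lifespan
  world$mac_pos <- newpos[keep]
  world$mac_age <- age[keep]
  rng_save(world)
}

#' Advance the blood vessels by one tick
#'
#' The circuit state is advanced by one RK4 step of `dt_ode` seconds under
#' the instantaneous input pressure `v` and its rate `dv`. Every living
#' vessel then releases oxygen in proportion to the part of the normalized
#' flow `max(i2, 0) / i2_rest` above the perfusion threshold
#' `theta_perfusion` (no usable oxygen is delivered below it; delivery
#' saturates at `sat_perfusion` times the resting release), and spawns
#' a macrophage with probability `k_spawn` times the normalized flow
#' (clamped to \[0, 1\]). A vessel
#' whose 8 surrounding epithelial agents are all dead dies and is inert
#' thereafter.
#'
#' @param world a `world_state`.
#' @param v input pressure (mmHg) this tick.
#' @param dv input-pressure rate (mmHg/s) this tick.
#' @return The updated world.
#' @export
step_vessels <- function(world, v, dv) {
  p <- world$abm
  world$flow <- rk4_step(world$circuit, v, dv,
                         unname(world$flow), p$dt_ode)
  names(world$flow) <- c("i1", "i2")
  fnorm <- max(world$flow[["i2"]], 0) / world$i2_rest
  odep <- p$k_oxygen * min(max(fnorm - p$theta_perfusion, 0) /
                             (1 - p$theta_perfusion), p$sat_perfusion)
  vpos <- world$vessel_pos[world$vessel_alive]
  if (length(vpos) > 0) {
    rng_restore(world)
    world$fields$oxygen[vpos] <- world$fields$oxygen[vpos] + odep
    prob <- min(max(p$k_spawn * fnorm, 0), 1)
    born <- stats::runif(length(vpos)) < prob
    if (any(born)) {
      world$mac_pos <- c(world$mac_pos, vpos[born])
      world$mac_age <- c(world$mac_age, integer(sum(born)))
    }
    world <- rng_save(world)
  }
  # a vessel dies when all 8 surrounding epithelial agents are dead
  if (any(world$vessel_alive)) {
    av <- which(world$vessel_alive)
    nb <- world$nbr[world$vessel_pos[av], , drop = FALSE]
    alive_nb <- matrix(world$alive[nb], length(av), 8)
    world$vessel_alive[av[rowSums(alive_nb) == 0]] <- FALSE
  }
  world
}

#' Advance the world by one tick
#'
#' One full scheduler step: the input pressure and its forward-difference
#' rate are read from the schedule, the contiguous-pressure counter is
#' updated, then vessels, macrophages, epithelium and fields are updated
#' in that fixed order and the tick counter advances. External pressure counts as applied during the schedule's
#' "on" half-period provided the schedule has a nonzero amplitude.
#'
#' @param world a `world_state`.
#' @param schedule a [pressure_schedule()].
#' @return The updated world.
#' @export
step_world <- function(world, schedule) {
  tick <- world$tick
  v <- pressure_at(schedule, tick)
  dv <- (pressure_at(schedule, tick + 1) - v) / world$abm$dt_ode
  v_applied <- (tick %% (2 * schedule$tp) < schedule$tp) &&
    (schedule$v_min < schedule$v_max)
  world$on_streak <- if (v_applied) (world$on_streak %||% 0L) + 1L else 0L
  world <- step_vessels(world, v, dv)
  world <- step_macrophages(world)
  world <- step_epithelium(world, v_applied)
  world <- step_fields(world)
  world$tick <- tick + 1L
  world
}
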