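#' Vascular circuit parameters
#'
#' Constructs the seven-constant lumped circuit describing skin blood flow:
#' four vascular resistances, two vessel compliances and the input (aortic)
#' pressure. `r1` is the arterial inflow resistance, `r2`/`r3` the capillary
#' branch resistances, `r4` a large shunt resistance, `c1`/`c2` the
#' compliances of the two storage compartments, and `v0` the input pressure
#' in mmHg. Flow is in arbitrary perfusion units consistent with mmHg and
#' the fitted R/C scales.
#'
#' @param r1,r2,r3,r4 vascular resistances (mmHg per flow unit), positive.
#' @param c1,c2 vessel compliances (flow x time per mmHg), positive.
#' @param v0 input pressure (mmHg), positive.
#' @return An object of class `circuit_params`.
#' @examples
#' control_circuit()
#' @export
circuit_params <- function(r1, r2, r3, r4, c1, c2, v0) {
  p <- list(r1 = r1, r2 = r2, r3 = r3, r4 = r4, c1 = c1, c2 = c2, v0 = v0)
  vals <- unlist(p)
  if (length(vals) != 7 || !all(is.finite(vals)))
    stop("all seven circuit constants must be finite numbers", call. = FALSE)
  if (any(vals <= 0))
    stop("all seven circuit constants must be strictly positive", call. = FALSE)
  if (r4 < 10 * max(r1, r2, r3))
    warning("r4 is not much larger than r1..r3; the shunt approximation is weak",
            call. = FALSE)
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  R1=%.4g R2=%.4g R3=%.4g R4=%.4g\n", x$r1, x$r2, x$r3, x$r4))
  cat(sprintf("  C1=%.4g C2=%.4g V0=%.4g mmHg\n", x$c1, x$c2, x$v0))
  cat(sprintf("  I2,rest=%.4g (flow units)\n", steady_state(x)))
  invisible(x)
}

#' Best-fit circuit for the non-injured control group
#'
#' The fitted group parameterization for able-bodied subjects
#' (input pressure 85 mmHg).
#' @return A `circuit_params` object.
#' @export
control_circuit <- function() {
  circuit_params(r1 = 0.10, r2 = 7.49, r3 = 13.83, r4 = 191.10,
                 c1 = 69.28, c2 = 14.45, v0 = 85)
}

#' Best-fit circuit for the spinal-cord-injured group
#'
#' The fitted group parameterization for subjects with chronic SCI
#' (input pressure 75 mmHg): larger arterial resistance, smaller
#' compliances than the control group.
#' @return A `circuit_params` object.
#' @export
sci_circuit <- function() {
  circuit_params(r1 = 1.19, r2 = 0.80, r3 = 8.28, r4 = 210,
                 c1 = 50, c2 = 10, v0 = 75)
}

#' Circuit state
#'
#' The two state currents of the circuit. All other branch currents are
#' algebraic functions of `(i1, i2)` and the instantaneous input pressure.
#'
#' @param i1,i2 state currents (flow units); finite, may be transiently
#'   negative.
#' @param t time in seconds attached to the state.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(i1, i2, t = 0) {
  if (!all(is.finite(c(i1, i2, t))))
    stop("non-finite flow state", call. = FALSE)
  structure(list(i1 = i1, i2 = i2, t = t), class = "flow_state")
}

#' Algebraically eliminated branch currents
#'
#' Computes the four derived branch currents from the state currents and the
#' instantaneous input pressure. The Kirchhoff identities
#' `i5 = i1 - i2 - i4` and `i6 = i2 - i3` hold exactly by construction.
#'
#' @param params a [circuit_params()] object.
#' @param v input pressure (mmHg).
#' @param state a [flow_state()] (vector-valued `i1`, `i2` are accepted).
#' @return A list with components `i3`, `i4`, `i5`, `i6`.
#' @export
branch_currents <- function(params, v, state) {
  if (!all(is.finite(c(v, state$i1, state$i2))))
    stop("non-finite inputs to branch_currents", call. = FALSE)
  i4 <- (v - params$r1 * state$i1) / params$r4
  i3 <- (v - params$r1 * state$i1 - params$r2 * state$i2) / params$r3
  list(i3 = i3, i4 = i4,
       i5 = state$i1 - state$i2 - i4,
       i6 = state$i2 - i3)
}

#' Time derivatives of the state currents
#'
#' The two-equation dynamical system. `dv` is the time derivative of the
#' input pressure; a pressure step enters the system as a large `dv` over one
#' integration step, producing the physical jump `dV/r1` in `i1` in the
#' small-step limit (the capacitor node voltages are continuous, so the
#' current through `r1` jumps when `v` does).
#'
#' @inheritParams branch_currents
#' @param dv rate of change of the input pressure (mmHg/s).
#' @return Numeric vector `c(di1, di2)` (per-second rates).
#' @export
flow_derivatives <- function(params, v, dv, state) {
  b <- branch_currents(params, v, state)
  c((dv - b$i5 / params$c1) / params$r1,
    (b$i5 / params$c1 - b$i6 / params$c2) / params$r2)
}

#' Resting skin blood flow
#'
#' Closed-form steady flow `i2` under a constant input pressure: the fixed
#' point of the dynamical system, linear in `v`.
#'
#' @param params a [circuit_params()] object.
#' @param v input pressure; defaults to the circuit's `v0`.
#' @return The steady flow `i2_rest` (flow units).
#' @export
steady_state <- function(params, v = params$v0) {
  v / (params$r2 + params$r3 +
         params$r1 * (1 + (params$r2 + params$r3) / params$r4))
}

#' Full steady state (both currents) under constant pressure
#'
#' @inheritParams steady_state
#' @return A [flow_state()] at the fixed point.
#' @export
steady_flow_state <- function(params, v = params$v0) {
  i2 <- steady_state(params, v)
  # at steady state i5 = 0, so i1 = i2 + i4 with i4 = (v - r1*i1)/r4
  i1 <- (i2 + v / params$r4) / (1 + params$r1 / params$r4)
  flow_state(i1, i2)
}

# Coefficient matrix of the homogeneous part of the system (constant v).
system_matrix <- function(params) {
  r1 <- params$r1; r2 <- params$r2; r3 <- params$r3; r4 <- params$r4
  c1 <- params$c1; c2 <- params$c2
  a11 <- -(1 + r1 / r4) / (c1 * r1)
  a12 <- 1 / (c1 * r1)
  a21 <- ((1 + r1 / r4) / c1 - r1 / (r3 * c2)) / r2
  a22 <- (-1 / c1 - (1 + r2 / r3) / c2) / r2
  matrix(c(a11, a12, a21, a22), 2, 2, byrow = TRUE)
}

#' Closed-form post-release step response
#'
#' The explicit solution for the skin blood flow `i2(t)` after an occluding
#' pressure is released: the input pressure steps from 0 to `v0` at `t = 0`
#' with both capacitor compartments drained. Since the compartment voltages
#' are continuous, the inflow current jumps to `v0/r1` at the release
#' instant while `i2(0) = 0`; the response is the bi-exponential
#' \deqn{i_2(t) = i_{2,rest} + a e^{p_1 t} + b e^{p_2 t}}
#' with `p1`, `p2` the (negative, distinct) eigenvalues of the system
#' matrix. For a compliant, low-resistance inflow the solution overshoots
#' `i2_rest` before settling -- the reactive hyperemia peak.
#'
#' @param params a [circuit_params()] object.
#' @return An object of class `step_response` with fields `i2_rest`, `a`,
#'   `b`, `p1`, `p2` satisfying `i2_rest + a + b = 0`.
#' @seealso [predict.step_response()], [integrate_flow()]
#' @export
step_response <- function(params) {
  A <- system_matrix(params)
  ev <- eigen(A, only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-9 * max(abs(Re(ev))))
      stop("oscillatory circuit response is out of scope", call. = FALSE)
    ev <- Re(ev)
  }
  p1 <- ev[1]; p2 <- ev[2]
  if (abs(p1 - p2) < 1e-9 * abs(p1))
    stop("degenerate step response: nearly repeated eigenvalues", call. = FALSE)
  i2_rest <- steady_state(params)
  # initial conditions at t = 0+: i1 = v0/r1 (post-release jump), i2 = 0
  d0 <- flow_derivatives(params, params$v0, 0,
                         flow_state(params$v0 / params$r1, 0))[2]
  # a + b = -i2_rest ; p1 a + p2 b = d0
  b <- (d0 + p1 * i2_rest) / (p2 - p1)
  a <- -i2_rest - b
  structure(list(i2_rest = i2_rest, a = a, b = b, p1 = p1, p2 = p2),
            class = "step_response")
}

#' Evaluate a step response
#'
#' @param object a [step_response()] object.
#' @param t times in seconds (vector).
#' @param ... unused.
#' @return `i2(t)` at the requested times.
#' @export
predict.step_response <- function(object, t, ...) {
  object$i2_rest + object$a * exp(object$p1 * t) + object$b * exp(object$p2 * t)
}

#' @export
print.step_response <- function(x, ...) {
  cat("<step_response>  i2(t) = i2_rest + a*exp(p1 t) + b*exp(p2 t)\n")
  cat(sprintf("  i2_rest=%.5g  a=%.5g  b=%.5g\n", x$i2_rest, x$a, x$b))
  cat(sprintf("  p1=%.5g  p2=%.5g  (1/s)\n", x$p1, x$p2))
  tp <- time_to_peak(x)
  cat(sprintf("  peak %.5g at t=%.4g s\n", predict(x, tp), tp))
  invisible(x)
}

#' Time of the hyperemic peak of a step response
#'
#' Solves `i2'(t) = 0` for the bi-exponential response. Returns 0 when the
#' response is monotone non-increasing from the origin.
#'
#' @param sr a [step_response()] object.
#' @return Peak time in seconds.
#' @export
time_to_peak <- function(sr) {
  ratio <- -(sr$b * sr$p2) / (sr$a * sr$p1)
  if (!is.finite(ratio) || ratio <= 0) return(0)
  t <- log(ratio) / (sr$p1 - sr$p2)
  max(t, 0)
}

#' Fixed-step RK4 integration of the circuit
#'
#' Integrates the two-state system under a time-varying pressure schedule.
#' The pressure is sampled at the left endpoint of every step and held; its
#' derivative is supplied as the forward finite difference
#' `(v(t+dt) - v(t))/dt`, so a step change `dV` in the schedule produces the
#' physically required jump `dV/r1` in `i1` as `dt -> 0` (first order at the
#' discontinuity, fourth order on constant segments).
#'
#' @param params a [circuit_params()] object.
#' @param v_schedule a function of time returning pressure (mmHg), or a
#'   single number for a constant pressure.
#' @param state0 initial [flow_state()].
#' @param t_end end time (s), positive.
#' @param dt step size (s), positive.
#' @return A data frame with columns `t`, `i1`, `i2`, `i3`, `i4`, `i5`,
#'   `i6`, one row per emitted sample (including `t = 0`).
#' @export
integrate_flow <- function(params, v_schedule, state0, t_end, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  vf <- if (is.function(v_schedule)) v_schedule else function(t) rep_len(v_schedule, length(t))
  n <- ceiling(t_end / dt)
  ts <- (0:n) * dt
  i1 <- numeric(n + 1); i2 <- numeric(n + 1)
  s <- c(state0$i1, state0$i2)
  i1[1] <- s[1]; i2[1] <- s[2]
  for (k in seq_len(n)) {
    t0 <- ts[k]
    v <- vf(t0)
    dv <- (vf(t0 + dt) - v) / dt
    s <- rk4_step(params, v, dv, s, dt)
    if (!all(is.finite(s)))
      stop(sprintf("integration diverged at step %d (t = %.6g s)", k, ts[k + 1]),
           call. = FALSE)
    i1[k + 1] <- s[1]; i2[k + 1] <- s[2]
  }
  b <- branch_currents(params, vf(ts), list(i1 = i1, i2 = i2))
  data.frame(t = ts, i1 = i1, i2 = i2, i3 = b$i3, i4 = b$i4, i5 = b$i5, i6 = b$i6)
}

# One classical RK4 step with held pressure v and constant dv.
rk4_step <- function(params, v, dv, s, dt) {
  f <- function(x) flow_derivatives(params, v, dv, list(i1 = x[1], i2 = x[2]))
  k1 <- f(s)
  k2 <- f(s + dt / 2 * k1)
  k3 <- f(s + dt / 2 * k2)
  k4 <- f(s + dt * k3)
  s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}
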