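test_that("the square-wave schedule applies pressure first", {
  sch <- pressure_schedule(v_max = 85, v_min = 40, tp = 210)
  expect_equal(pressure_at(sch, 0), 40)
  expect_equal(pressure_at(sch, 209), 40)
  expect_equal(pressure_at(sch, 210), 85)
  expect_equal(pressure_at(sch, 419), 85)
  expect_equal(pressure_at(sch, 420), 40)

  one <- pressure_schedule(85, 40, 1)
  expect_equal(pressure_at(one, 0:5), c(40, 85, 40, 85, 40, 85))

  expect_error(pressure_schedule(40, 85, 10), "v_max")
  expect_error(pressure_schedule(85, 40, 0), "positive")
})

test_that("field updates conserve mass and apply the stated kernel", {
  w <- init_world(small_grid(),
                  abm_params(evap_oxygen = 0, evap_tnf = 0, evap_tgf = 0,
                             diff_oxygen = 0.8, k_oxygen = 0),
                  control_circuit(), seed = 1, burn_in = 0)

  # single point mass, diffusion 0.8: centre keeps 0.2, neighbours 0.1 each
  w$fields$oxygen[,] <- 0
  centre <- 8 + 16 * 7          # an interior cell
  w$fields$oxygen[centre] <- 1
  w2 <- step_fields(w)
  expect_equal(w2$fields$oxygen[centre], 0.2)
  nb <- w$nbr[centre, ]
  expect_equal(unname(w2$fields$oxygen[nb]), rep(0.1, 8))
  expect_equal(sum(w2$fields$oxygen), 1, tolerance = 1e-12)

  # random field: mass conserved without evaporation
  set.seed(5)
  w$fields$tnf[,] <- runif(256)
  m0 <- sum(w$fields$tnf)
  w3 <- step_fields(w)
  expect_equal(sum(w3$fields$tnf), m0, tolerance = 1e-12)
  expect_true(all(w3$fields$tnf >= 0))

  # uniform field stays uniform and decays by the evaporation factor
  wE <- init_world(small_grid(), abm_params(evap_tgf = 0.25, k_oxygen = 0),
                   control_circuit(), seed = 1, burn_in = 0)
  wE$fields$tgf[,] <- 2
  wE2 <- step_fields(wE)
  expect_equal(unname(as.numeric(wE2$fields$tgf)), rep(2 * 0.75, 256))
})

test_that("epithelial rules damage, secrete, heal and kill in order", {
  ab <- abm_params(kd_pressure = 0.05, t_damage_lag = 0, kh_heal = 0.1,
                   theta_tnf = 1, kt_tnf = 0.1, k_tnf_secrete = 0.2)
  w <- init_world(small_grid(), ab, control_circuit(), seed = 1, burn_in = 0)
  w$fields$tnf[,] <- 0; w$fields$tgf[,] <- 0; w$fields$oxygen[,] <- 0
  w$on_streak <- 10L

  # full health, no pressure, no TNF: unchanged
  w1 <- step_epithelium(w, v_applied = FALSE)
  expect_true(all(w1$health == 1))

  # pressure damage after the tolerated lag
  w2 <- step_epithelium(w, v_applied = TRUE)
  expect_true(all(abs(w2$health - 0.95) < 1e-12))

  # but not within the lag
  w$on_streak <- 0L
  w3 <- step_epithelium(w, v_applied = TRUE)
  expect_true(all(w3$health == 1))

  # TNF above threshold damages; damaged cells secrete TNF
  w$fields$tnf[,] <- 1.5
  w$health[,] <- 0.85
  w4 <- step_epithelium(w, v_applied = FALSE)
  expect_true(all(abs(w4$health - (0.85 - 0.1 * 0.5)) < 1e-12))
  expect_true(all(w4$fields$tnf >= 1.5 + 0.2 - 1e-12))

  # healing requires oxygen: TGF alone does nothing
  w$fields$tnf[,] <- 0
  w$fields$tgf[,] <- 10; w$fields$oxygen[,] <- 0
  w5 <- step_epithelium(w, v_applied = FALSE)
  expect_true(all(w5$health == 0.85))
  w$fields$oxygen[,] <- 1
  w6 <- step_epithelium(w, v_applied = FALSE)
  expect_true(all(w6$health > 0.85))

  # a cell at the brink dies this tick and death is irreversible
  w$health[,] <- 0.01
  w$fields$tgf[,] <- 0
  w$on_streak <- 10L
  w7 <- step_epithelium(w, v_applied = TRUE)
  expect_true(all(!w7$alive))
  expect_true(all(w7$health == 0))
  w$fields$tgf[,] <- 100; w$fields$oxygen[,] <- 100
  w8 <- step_epithelium(w7, v_applied = FALSE)
  expect_true(all(!w8$alive))   # the dead never heal back
})

test_that("macrophages climb strong TNF gradients and age out", {
  ab <- abm_params(mac_lifespan = 1, k_spawn = 0)
  w <- init_world(small_grid(), ab, control_circuit(), seed = 2, burn_in = 0)
  w$mac_pos <- c(10L, 20L); w$mac_age <- c(0L, 0L)
  w1 <- step_macrophages(w)
  expect_length(w1$mac_pos, 0)   # lifespan 1: gone after one step

  # chemotaxis toward a strong point source
  ab2 <- abm_params(mac_lifespan = 10000, k_spawn = 0,
                    theta_chemotaxis = 0.5, mac_tnf_rate = 0)
  dist_after <- vapply(1:30, function(s) {
    w <- init_world(small_grid(), ab2, control_circuit(),
                    seed = s, burn_in = 0)
    # steep radial TNF profile, well above the sensing floor
    ix <- (seq_len(256) - 1) %% 16 + 1
    iy <- (seq_len(256) - 1) %/% 16 + 1
    d <- pmax(abs(ix - 8), abs(iy - 8))
    w$fields$tnf <- matrix(10 - d, 16, 16)
    w$mac_pos <- (12L - 1L) * 16L + 13L   # 5 cells away
    w$mac_age <- 0L
    for (i in 1:6) w <- step_macrophages(w)
    ix2 <- (w$mac_pos - 1) %% 16 + 1
    iy2 <- (w$mac_pos - 1) %/% 16 + 1
    max(abs(ix2 - 8), abs(iy2 - 8))
  }, numeric(1))
  expect_lte(stats::median(dist_after), 1)

  # with no sensible TNF the walk is unbiased: zero mean displacement
  w <- init_world(small_grid(), ab2, control_circuit(), seed = 3,
                  burn_in = 0)
  w$fields$tnf[,] <- 0
  n <- 400
  w$mac_pos <- rep((8L - 1L) * 16L + 8L, n)
  w$mac_age <- rep(0L, n)
  for (i in 1:10) w <- step_macrophages(w)
  dx <- ((w$mac_pos - 1) %% 16 + 1) - 8
  # wrap-aware displacement on the torus
  dx <- ifelse(dx > 8, dx - 16, dx)
  se <- stats::sd(dx) / sqrt(n)
  expect_lt(abs(mean(dx)), 3 * se + 0.3)
})

test_that("vessels integrate flow, deliver gated oxygen, spawn and die", {
  ab <- abm_params(k_spawn = 1, k_oxygen = 2, theta_perfusion = 0.5,
                   sat_perfusion = 10)
  w <- init_world(small_grid(), ab, control_circuit(), seed = 4,
                  burn_in = 0)
  w$mac_pos <- integer(0); w$mac_age <- integer(0)
  w$fields$oxygen[,] <- 0

  # at rest (fnorm = 1) every vessel spawns with probability min(k_spawn,1)
  w1 <- step_vessels(w, control_circuit()$v0, 0)
  expect_length(w1$mac_pos, length(w$vessel_pos))
  # gated release: (1 - 0.5)/(1 - 0.5) = 1 times k_oxygen at each vessel
  expect_equal(unname(w1$fields$oxygen[w1$vessel_pos]),
               rep(2, length(w1$vessel_pos)))

  # zero flow: no oxygen, no spawning
  w$flow <- c(i1 = 0, i2 = 0)
  w2 <- step_vessels(w, 0, 0)
  expect_length(w2$mac_pos, 0)
  expect_equal(sum(w2$fields$oxygen), 0)

  # a vessel whose surrounding epithelium is dead dies and stays dead
  w3 <- w
  ring <- w$nbr[w$vessel_pos[1], ]
  w3$alive[ring] <- FALSE
  w3 <- step_vessels(w3, control_circuit()$v0, 0)
  expect_false(w3$vessel_alive[1])
  expect_true(all(w3$vessel_alive[-1]))
  w4 <- step_vessels(w3, control_circuit()$v0, 0)
  expect_false(w4$vessel_alive[1])
  # dead vessels deposit nothing
  w3$fields$oxygen[,] <- 0
  w5 <- step_vessels(w3, control_circuit()$v0, 0)
  expect_equal(unname(w5$fields$oxygen[w5$vessel_pos[1]]), 0)
})

test_that("world initialization is a healthy lattice at rest", {
  w <- init_world(grid_config(40, 40, 4), abm_params(), control_circuit(),
                  seed = 1)
  expect_equal(length(w$health), 1600)
  expect_equal(length(w$vessel_pos), 100)
  expect_equal(mean(w$health), 1)
  expect_true(all(w$alive))
  expect_equal(unname(w$flow[["i2"]]), steady_state(control_circuit()),
               tolerance = 1e-9)

  # oxygen pre-equilibrated near its analytic resting mean
  p <- abm_params()
  target <- 100 * p$k_oxygen * (1 - p$evap_oxygen) /
    (p$evap_oxygen * 1600)
  expect_lt(abs(mean(w$fields$oxygen) - target) / target, 0.01)
})

test_that("full steps are deterministic and harmless without insult", {
  ab <- abm_params()
  sch <- pressure_schedule(85, 40, 50)
  w1 <- init_world(small_grid(), ab, control_circuit(), seed = 7)
  w2 <- init_world(small_grid(), ab, control_circuit(), seed = 7)
  for (i in 1:120) { w1 <- step_world(w1, sch); w2 <- step_world(w2, sch) }
  expect_identical(w1$health, w2$health)
  expect_identical(w1$mac_pos, w2$mac_pos)
  expect_identical(w1$fields, w2$fields)
  expect_identical(w1$flow, w2$flow)

  # no damage sources: nothing can die even under long pressure
  safe <- abm_params(kd_pressure = 0, theta_tnf = 1e9)
  w <- init_world(small_grid(), safe, control_circuit(), seed = 8)
  sch2 <- pressure_schedule(85, 40, 200)
  for (i in 1:500) w <- step_world(w, sch2)
  expect_true(all(w$alive))

  # zero-amplitude schedule: homeostasis
  w <- init_world(small_grid(), ab, control_circuit(), seed = 9)
  flat <- pressure_schedule(85, 85, 100)
  for (i in 1:500) w <- step_world(w, flat)
  expect_gte(mean(w$health), 0.99)
})
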