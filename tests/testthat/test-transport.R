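test_that("Darcy-Forchheimer coefficients match hand arithmetic", {
  hand <- darcy_coefficients(porous_medium(Dp = 1, eps = 0.5))
  expect_equal(hand$alpha, 1 / 300, tolerance = 1e-12)  # 0.125/37.5
  expect_equal(hand$C2, 14, tolerance = 1e-12)          # 3.5*0.5/0.125

  paper <- darcy_coefficients(porous_medium(Dp = 1.1e-5, eps = 0.707))
  expect_equal(paper$alpha, 3.3206e-12, tolerance = 1e-4)
  expect_equal(paper$C2, 2.6381e5, tolerance = 1e-4)

  expect_error(porous_medium(eps = 1), "porosity")
  expect_error(porous_medium(eps = 0), "porosity")
})

test_that("zero inlet flow gives a quiescent uniform-pressure field", {
  ch <- channel_model(nx = 30, ny = 4, inlet_flow = 0)
  fl <- solve_flow(ch, porous_medium(), fluid_props())
  expect_equal(max(abs(fl$u)), 0)
  expect_equal(max(abs(fl$w)), 0)
  expect_equal(max(abs(fl$p)), 0)
})

test_that("1D pressure drop matches the analytic Darcy solution", {
  ch <- channel_model(nx = 80, ny = 1)
  pm <- porous_medium(); fp <- fluid_props()
  fl <- solve_flow(ch, pm, fp, forchheimer = FALSE)
  u <- ch$inlet_flow / (ch$width * ch$thickness)
  dp_analytic <- fp$mu / darcy_coefficients(pm)$alpha * u * ch$length
  expect_equal(fl$delta_p, dp_analytic, tolerance = 0.01)
  expect_lt(fl$max_div_rel, 1e-10)

  # Darcy regime is linear: doubling the flow doubles the pressure drop
  ch2 <- channel_model(nx = 80, ny = 1, inlet_flow = 2 * ch$inlet_flow)
  fl2 <- solve_flow(ch2, pm, fp, forchheimer = FALSE)
  expect_equal(fl2$delta_p / fl$delta_p, 2, tolerance = 1e-9)
})

test_that("Forchheimer term is negligible at sub-uL/min paper flows", {
  # 1 uL/min, the flow above which convective effects start to matter
  q <- 1e-9 / 60
  ch <- channel_model(nx = 60, ny = 5, inlet_flow = q)
  with_f <- solve_flow(ch, porous_medium(), fluid_props())
  without <- solve_flow(ch, porous_medium(), fluid_props(),
                        forchheimer = FALSE)
  expect_lt(abs(with_f$delta_p - without$delta_p) / without$delta_p, 1e-3)
})

test_that("species field stays zero without any inlet glucose", {
  ch <- channel_model(nx = 40, ny = 3, Y_in = 0)
  fl <- solve_flow(ch, porous_medium(), fluid_props())
  sp <- advance_species(fl, dt = 10, t_end = 100)
  expect_equal(max(abs(sp$Y)), 0)
})

test_that("an advected front travels at the interstitial velocity", {
  ch <- channel_model(nx = 200, ny = 1, D_species = 0)
  pm <- porous_medium()
  fl <- solve_flow(ch, pm, fluid_props())
  station <- 0.01
  sp <- advance_species(fl, dt = 2, t_end = 700, record_x = station)
  bt <- breakthrough_time(sp, threshold = 0.5)
  u <- ch$inlet_flow / (ch$width * ch$thickness)
  t_char <- station / (u / pm$eps)
  cell_time <- (ch$length / ch$nx) / (u / pm$eps)
  expect_lt(abs(bt - t_char), cell_time)
})

test_that("pure diffusion of a step matches the 1D erfc solution", {
  # short pre-wetted strip, no flow, step initial condition at mid-length
  L <- 0.002; nx <- 200; D <- 1e-9; Ymax <- 1.8e-4
  ch <- channel_model(length = L, nx = nx, ny = 1, inlet_flow = 0,
                      Y_in = Ymax, D_species = D)
  fl <- solve_flow(ch, porous_medium(), fluid_props())
  x <- (seq_len(nx) - 0.5) * L / nx
  Y0 <- matrix(ifelse(x < L / 2, Ymax, 0), nx, 1)
  t_end <- 10
  sp <- advance_species(fl, dt = 0.05, t_end = t_end, Y0 = Y0)
  z <- (x - L / 2) / (2 * sqrt(D * t_end))
  exact <- Ymax / 2 * 2 * pnorm(-z * sqrt(2))   # (Ymax/2) * erfc(z)
  l2_err <- sqrt(sum((sp$Y[, 1] - exact)^2) / sum(exact^2))
  expect_lt(l2_err, 0.02)
})

test_that("mass fraction stays bounded and species mass balances close", {
  ch <- channel_model(nx = 200, ny = 20)
  fl <- solve_flow(ch, porous_medium(), fluid_props())
  sp <- advance_species(fl, dt = 10, t_end = 300, record_x = 0.005)
  expect_gte(min(sp$Y), 0)
  expect_lte(max(sp$Y), ch$Y_in * (1 + 1e-9))
  expect_lt(sp$max_mass_resid, 1e-6)
})

test_that("breakthrough time behaves physically", {
  pm <- porous_medium(); fp <- fluid_props()
  run_bt <- function(flow, nx = 100, threshold = 0.5) {
    ch <- channel_model(nx = nx, ny = 1, inlet_flow = flow)
    fl <- solve_flow(ch, pm, fp)
    sp <- advance_species(fl, dt = 5, t_end = 2500,
                          record_x = c(1e-4, 0.01))
    c(inlet = breakthrough_time(sp, station = 1, threshold = threshold),
      mid = breakthrough_time(sp, station = 2, threshold = threshold))
  }
  q0 <- 300e-9 / 60 * 1e-3
  bt <- run_bt(q0)
  expect_lt(bt["inlet"], 30)            # station at the inlet breaks ~immediately
  expect_true(is.finite(bt["mid"]))

  # monotone decreasing in inlet flow
  bt_half <- run_bt(q0 / 2)
  bt_double <- run_bt(q0 * 2)
  expect_gt(bt_half["mid"], bt["mid"])
  expect_gt(bt["mid"], bt_double["mid"])

  # monotone increasing in threshold
  ch <- channel_model(nx = 100, ny = 1)
  fl <- solve_flow(ch, pm, fp)
  sp <- advance_species(fl, dt = 5, t_end = 1500, record_x = 0.01)
  expect_gt(breakthrough_time(sp, threshold = 0.9),
            breakthrough_time(sp, threshold = 0.1))

  # never-crossing stations yield the no-breakthrough sentinel
  sp_short <- advance_species(fl, dt = 5, t_end = 50, record_x = 0.03)
  expect_warning(nb <- breakthrough_time(sp_short, threshold = 0.99),
                 "no breakthrough")
  expect_true(is.na(nb))
})

test_that("breakthrough time is grid-converged at default settings", {
  pm <- porous_medium(); fp <- fluid_props()
  bt_for <- function(nx) {
    ch <- channel_model(nx = nx, ny = 1)
    fl <- solve_flow(ch, pm, fp)
    sp <- advance_species(fl, dt = 2, t_end = 800, record_x = 0.01)
    breakthrough_time(sp, threshold = 0.5)
  }
  coarse <- bt_for(100)
  fine <- bt_for(200)
  expect_lt(abs(fine - coarse) / fine, 0.05)
})
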