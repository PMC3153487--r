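test_that("uniform fields are stationary under diffusion", {
  g <- small_isolated(nodes = 60)
  f <- rep(3.7, 60)
  for (theta in c(0.5, 1))
    expect_equal(diffusion_step(f, D = 600, dt = 5, g, theta = theta), f,
                 tolerance = 1e-12)
})

test_that("diffusion conserves total solute to high precision", {
  g <- small_clump(nodes = 150)
  set.seed(42)
  f <- runif(150, 0, 10)
  mass0 <- sum(f * g$vol)
  for (i in 1:50) f <- diffusion_step(f, D = 600, dt = 2, g)
  expect_equal(sum(f * g$vol), mass0, tolerance = 1e-8)
  expect_true(all(f >= 0))
})

test_that("a narrow pulse far from boundaries spreads at the free-diffusion
           rate (variance + 2 D dt per step)", {
  p <- test_params()
  g <- build_geometry("isolated", params = p, grid_nodes = 1200,
                      grid_spacing = "linear")
  # u = r C obeys the 1-D heat equation away from the boundaries
  r0 <- 1500; s0 <- 120; D <- 600; dt <- 2; nst <- 50
  f <- exp(-(g$r - r0)^2 / (2 * s0^2)) / g$r
  moments <- function(u) {
    w <- u * g$r * diff(g$faces)
    mu <- sum(w * g$r) / sum(w)
    sum(w * (g$r - mu)^2) / sum(w)
  }
  v0 <- moments(f)
  for (i in seq_len(nst)) f <- diffusion_step(f, D, dt, g, theta = 0.5)
  expect_equal(moments(f) - v0, 2 * D * dt * nst, tolerance = 0.01)
})

test_that("reaction step conserves molecules with exact 1:1 stoichiometry", {
  p <- test_params()
  g <- small_clump(nodes = 100)
  st <- reaction_step(sim_state(g, 8), dt = 1, g, p)
  conv <- MOLEC_PER_UM3_PER_MM
  consumed <- sum((8 - st$sucrose_field) * g$vol) * conv
  expect_equal(consumed, st$hydrolyzed_molecules, tolerance = 1e-10)
  free <- sum(st$glucose_field * g$vol) * conv
  expect_equal(st$hydrolyzed_molecules, free + st$imported_molecules,
               tolerance = 1e-10)
  expect_true(all(st$sucrose_field >= 0) && all(st$glucose_field >= 0))
})

test_that("saturated hydrolysis creates ~ dt * Vmax molecules per step", {
  p <- test_params()
  g <- small_isolated(nodes = 60)
  dt <- 0.2
  st <- reaction_step(sim_state(g, 11000), dt = dt, g, p)  # S >> Km
  expect_equal(st$hydrolyzed_molecules, dt * p$vmax_hydrolysis,
               tolerance = 5e-3)
})

test_that("an invertase deletion produces no glucose and no intake", {
  p <- kinetic_params(vmax_hydrolysis = 0)
  g <- small_clump(nodes = 60, params = p)
  r <- run_simulation(g, p, sucrose_mM = 8, duration_h = 0.25, dt = 5)
  expect_equal(max(abs(r$final_profiles$glucose_mM)), 0)
  expect_equal(max(abs(r$timeseries$intake_molecules_per_s)), 0)
  expect_equal(r$final_intake, 0)
  expect_false(classify_growth(r, p))
})

test_that("the R reaction step matches the compiled driver exactly", {
  p <- test_params()
  g <- small_clump(nodes = 60)
  st <- reaction_step(sim_state(g, 8), dt = 1, g, p)
  sh <- clumpshare:::promoter_shape(p)
  kp <- c(unclass(p),
          list(prom_ki = sh$ki, prom_kr = sh$kr, prom_fstar = sh$fstar,
               conv = clumpshare:::.molecules_per_um3_per_mM,
               constitutive = FALSE, decay = TRUE))
  out <- clumpshare:::run_core_cpp(rep(8, 60), rep(0, 60), rep(1, 60),
                                   g$cells, g$vol, g$gface, 0, 0, 1, 1L, 1L,
                                   1, kp)
  expect_equal(st$sucrose_field, out$sucrose_final, tolerance = 1e-12)
  expect_equal(st$glucose_field, out$glucose_final, tolerance = 1e-12)
  expect_equal(st$induction, out$induction_final, tolerance = 1e-12)
  expect_equal(st$imported_molecules, out$imported_molecules,
               tolerance = 1e-12)
})

test_that("zero-duration runs return the initial state and zero intake", {
  g <- small_clump(nodes = 60)
  r <- run_simulation(g, test_params(), 8, duration_h = 0)
  expect_equal(r$final_intake, 0)
  expect_equal(r$final_profiles$sucrose_mM, rep(8, 60))
  expect_equal(r$final_profiles$glucose_mM, rep(0, 60))
})

test_that("full runs balance mass to better than 1e-6 and never exceed the
           diffusion-limited ceiling", {
  p <- test_params()
  for (cfg in list(list(sc = "clump", n = 30), list(sc = "dispersed", n = 30))) {
    g <- build_geometry(cfg$sc, n_cells = cfg$n, params = p,
                        grid_nodes = 200)
    r <- run_simulation(g, p, sucrose_mM = 8, duration_h = 2, dt = 2)
    expect_lt(max(r$mass_balance), 1e-6)
    # Smoluchowski bound 4 pi D a C_inf on the sucrose-equivalent supply
    ceiling <- 4 * pi * p$d_glucose * p$cell_radius *
      8 * MOLEC_PER_UM3_PER_MM
    expect_true(all(r$timeseries$intake_molecules_per_s <= ceiling))
  }
})

test_that("the central clump cell always out-collects an isolated cell", {
  p <- test_params()
  h <- 2
  rc <- run_simulation(build_geometry("clump", 30, params = p,
                                      grid_nodes = 200), p, 8, h, dt = 2)
  ri <- run_simulation(build_geometry("isolated", params = p,
                                      grid_nodes = 200), p, 8, h, dt = 2)
  rd <- run_simulation(build_geometry("dispersed", 30, params = p,
                                      grid_nodes = 200), p, 8, h, dt = 2)
  expect_true(all(rc$timeseries$intake_molecules_per_s >=
                    ri$timeseries$intake_molecules_per_s))
  expect_true(all(rc$timeseries$intake_molecules_per_s >=
                    rd$timeseries$intake_molecules_per_s))
})

test_that("halving dt and doubling the grid changes the result by < 2%", {
  p <- test_params()
  base <- run_simulation(build_geometry("clump", 30, params = p,
                                        grid_nodes = 300), p, 8, 2, dt = 1)
  fine <- run_simulation(build_geometry("clump", 30, params = p,
                                        grid_nodes = 600), p, 8, 2, dt = 0.5)
  expect_lt(abs(fine$final_intake - base$final_intake) / base$final_intake,
            0.02)
})

test_that("growth classification applies the minimum-intake threshold with
           the boundary counting as growth", {
  p <- test_params()
  g <- small_clump(nodes = 60)
  r <- run_simulation(g, p, 8, duration_h = 0.5, dt = 5)
  # synthetic boundary case
  r$converged <- TRUE
  r$equilibrium_intake <- p$min_growth_intake
  expect_true(classify_growth(r, p))
  r$equilibrium_intake <- p$min_growth_intake * (1 - 1e-9)
  expect_false(classify_growth(r, p))
})

test_that("a single-cell 'clump' reproduces the isolated scenario exactly", {
  p <- test_params()
  sw <- sweep_clump_size(p, sucrose_mM = 8, duration_h = 0.5, sizes = 1,
                         grid_nodes = 100, dt = 5)
  iso <- run_simulation(build_geometry("isolated", params = p,
                                       grid_nodes = 100), p, 8, 0.5, dt = 5)
  expect_equal(sw$intake_molecules_per_s[1], iso$final_intake,
               tolerance = 1e-12)
})
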