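test_that("unit conversion mM <-> molecules/um^3 round-trips exactly", {
  x <- c(0, 1e-6, 0.25, 8, 128)
  expect_equal(molecules_um3_to_mM(mM_to_molecules_um3(x)), x,
               tolerance = 1e-12)
  expect_equal(mM_to_molecules_um3(1), 6.022e5, tolerance = 1e-3)
})

test_that("promoter activity is basal at zero, unimodal with peak in the
           window, and repressed monotonically above it", {
  p <- test_params()
  expect_equal(promoter_activity(0, p), p$promoter_basal)
  g <- seq(0.001, 40, length.out = 4000)
  a <- promoter_activity(g, p)
  expect_true(all(a >= 0 & a <= 1 + 1e-12))
  peak <- g[which.max(a)]
  expect_gte(peak, p$promoter_peak_lo)
  expect_lte(peak, p$promoter_peak_hi)
  # single interior maximum: rises then falls
  d <- diff(a)
  expect_true(all(d[g[-1] <= peak] >= -1e-12))
  above <- g[-1] >= p$promoter_peak_hi
  expect_true(all(d[above] <= 1e-12))
  # repression ordering at specific concentrations
  expect_gte(promoter_activity(0.5, p), promoter_activity(16, p))
  expect_gte(promoter_activity(16, p), promoter_activity(32, p))
})

test_that("constitutive mode returns 1 for any glucose level", {
  g <- c(0, 0.01, 0.5, 16, 200)
  expect_equal(promoter_activity(g, mode = "constitutive"), rep(1, 5))
})

test_that("promoter activity rejects negative concentrations", {
  expect_error(promoter_activity(-1), "nonnegative")
})

test_that("hydrolysis follows Michaelis-Menten kinetics of the measured
           invertase parameters", {
  p <- test_params()
  expect_equal(hydrolysis_rate(0, 1, p), 0)
  # half saturation at S = Km
  expect_equal(hydrolysis_rate(11, 1, p), 3.6e8 / 2)
  # direct arithmetic at the enzyme-assay concentration
  expect_equal(hydrolysis_rate(128, 1, p), 3.6e8 * 128 / 139,
               tolerance = 1e-12)
  expect_equal(hydrolysis_rate(128, 1, p), 3.315e8, tolerance = 1e-3)
  # scales linearly with induction
  expect_equal(hydrolysis_rate(8, 0.25, p), 0.25 * hydrolysis_rate(8, 1, p))
  expect_error(hydrolysis_rate(-1), "nonnegative")
})

test_that("import follows saturable transporter kinetics", {
  p <- test_params()
  expect_equal(import_rate(0, p), 0)
  expect_equal(import_rate(p$km_hexose, p), p$vmax_import / 2)
  # arithmetic on an alternative transporter parameterisation
  p2 <- kinetic_params(km_hexose = 1, vmax_import = 2e7)
  expect_equal(import_rate(0.1, p2), 2e7 * 0.1 / 1.1, tolerance = 1e-12)
  expect_equal(import_rate(0.1, p2), 1.8e6, tolerance = 0.02)
  expect_error(import_rate(-0.1), "nonnegative")
})

test_that("rates are bounded by their Vmax and monotone in substrate and
           induction", {
  p <- test_params()
  s <- sort(runif_seeded(200, 0, 200, seed = 11))
  e <- seq(0, 1, length.out = 6)
  for (ei in e) {
    h <- hydrolysis_rate(s, ei, p)
    expect_true(all(h <= ei * p$vmax_hydrolysis + 1e-9))
    expect_true(all(diff(h) >= -1e-9))
  }
  im <- import_rate(s, p)
  expect_true(all(im <= p$vmax_import))
  expect_true(all(diff(im) >= -1e-9))
  expect_true(all(diff(hydrolysis_rate(8, e, p)) >= 0))
})

test_that("invertase induction relaxes to the promoter set point with the
           exponential closed form", {
  p <- test_params()
  g_peak <- clumpshare:::promoter_shape(p)$g_peak  # activity exactly 1 here
  # fixed point is unchanged
  a <- promoter_activity(2, p)
  expect_equal(invertase_update(a, 2, dt = 10, p), a)
  # linearisation from zero induction
  dt <- 36  # << tau
  expect_equal(invertase_update(0, g_peak, dt, p), dt / p$invertase_tau,
               tolerance = 1e-9)
  # discrete update tracks 1 - exp(-t/tau) at small dt
  dt <- p$invertase_tau / 2000
  e <- 0
  for (i in 1:2000) e <- invertase_update(e, g_peak, dt, p)
  expect_equal(e, 1 - exp(-1), tolerance = 1e-3)
})

test_that("without decay induction only ratchets upward", {
  p <- test_params()
  # at high glucose the set point is low; decaying dynamics move down,
  # the no-decay variant holds its level
  expect_lt(invertase_update(1, 30, dt = 600, p, decay = TRUE), 1)
  expect_equal(invertase_update(1, 30, dt = 600, p, decay = FALSE), 1)
  # upward moves are identical in both variants
  expect_equal(invertase_update(0.2, 0.5, dt = 600, p, decay = FALSE),
               invertase_update(0.2, 0.5, dt = 600, p, decay = TRUE))
})

test_that("cell_state validates and invertase_update preserves its type", {
  st <- cell_state(induction = 0.5)
  st2 <- invertase_update(st, 0.5, dt = 60)
  expect_s3_class(st2, "cell_state")
  expect_gt(st2$induction, 0.5)
  expect_error(cell_state(induction = -1), "nonnegative")
})

test_that("kinetic_params enforces its invariants with named messages", {
  expect_error(kinetic_params(d_glucose = -5), "d_glucose")
  expect_error(kinetic_params(promoter_basal = 1.5), "promoter_basal")
  expect_error(kinetic_params(packing_fraction = 0), "packing_fraction")
  expect_error(kinetic_params(promoter_peak_lo = 2, promoter_peak_hi = 1),
               "promoter_peak_lo")
  # an invertase deletion is representable
  expect_silent(kinetic_params(vmax_hydrolysis = 0))
})
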