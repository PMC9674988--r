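# solubility-diffusion pipeline: calibration, cleaning, the resistance
# integral, layer scaling and uncertainty propagation

test_that("solvent calibration shifts vacuum-referenced profiles and re-tags them", {
  z <- seq(0, 2, by = 0.1)
  pmf <- pmf_profile(z, rep(-4, length(z)), reference = "vacuum")

  p0 <- calibrate_relative_to_solvent(pmf, 0)
  expect_equal(p0$dG, pmf$dG)
  expect_identical(attr(p0, "reference_tag"), "solvent")
  expect_error(calibrate_relative_to_solvent(p0, 0), "already")

  # toy whose membrane region equals the solvent: calibrated profile ~ 0
  land <- flat_landscape(level = -4, n_lambda = 3)
  ref <- reference_pmf(land, 1, z = z, anchor = "vacuum")
  cal <- calibrate_relative_to_solvent(ref, reference_solvation(land))
  expect_lt(max(abs(cal$dG)), 1e-9)
})

test_that("non-negativity offset anchors the minimum at zero and shifts resistance by exp(beta c)", {
  z <- seq(0, 1, by = 0.05)
  p <- pmf_profile(z, sin(z * 4) - 2)
  p2 <- offset_nonnegative(p)
  expect_equal(min(p2$dG), 0)
  expect_equal(offset_nonnegative(p2)$dG, p2$dG)

  # a common additive shift c multiplies the resistance by exp(beta c)
  dp <- diffusion_profile(z, rep(0.01, length(z)))
  p3 <- p2; p3$dG <- p2$dG + 1.7
  expect_equal(resistance(p3, dp) / resistance(p2, dp), exp(TH$beta * 1.7),
               tolerance = 1e-12)
})

test_that("edge trimming replaces boundary spikes by inner neighbours only", {
  # grid mirroring the production output coordinates: spikes at the two
  # lowest (0.005, 0.015 nm) and highest (5.200, 5.210 nm) points get the
  # values of their neighbours at 0.025 and 5.19 nm
  z <- seq(0.005, 5.205, by = 0.01)
  z <- c(z, 5.210)
  dG <- rep(1, length(z)); dG[z > 4] <- 3
  dG[1:2] <- c(40, 30); dG[length(z) - 1:0] <- c(25, 35)
  p <- pmf_profile(z, dG)
  pt <- trim_edges(p, 2)
  expect_equal(pt$dG[1:2], rep(pt$dG[3], 2))
  n <- length(z)
  expect_equal(pt$dG[c(n - 1, n)], rep(pt$dG[n - 2], 2))
  expect_equal(pt$dG[3:(n - 2)], dG[3:(n - 2)])
  expect_equal(pt$z, p$z)

  flat <- pmf_profile(1:10, rep(2, 10))
  expect_equal(trim_edges(flat, 2)$dG, flat$dG)
  expect_equal(trim_edges(flat, 0)$dG, flat$dG)
  expect_error(trim_edges(pmf_profile(1:4, 1:4), 2), "too short")
})

test_that("the resistance integral is exact for flat profiles and matches adaptive quadrature", {
  # flat profile: R = L / D0 exactly
  z <- seq(0, 2, by = 0.02)
  pmf <- pmf_profile(z, rep(0, length(z)))
  dp <- diffusion_profile(z, rep(0.005, length(z)))
  expect_equal(resistance(pmf, dp), 2 / 0.005, tolerance = 1e-14)

  # smooth Gaussian barrier at fine native spacing vs an independent
  # adaptive quadrature of the analytic integrand
  G <- function(z) 3 * exp(-((z - 1)^2) / (2 * 0.3^2))
  Dfun <- function(z) 0.005 * (1 + 0.2 * cos(z))
  zf <- seq(0, 2, by = 5e-4)
  R <- resistance(pmf_profile(zf, G(zf)), diffusion_profile(zf, Dfun(zf)))
  oracle <- integrate(function(z) exp(TH$beta * G(z)) / Dfun(z), 0, 2,
                      rel.tol = 1e-12)$value
  expect_equal(R, oracle, tolerance = 1e-6)

  # Simpson agrees with trapezoid at fine spacing
  R_s <- resistance(pmf_profile(zf, G(zf)), diffusion_profile(zf, Dfun(zf)),
                    method = "simpson")
  expect_equal(R_s, oracle, tolerance = 1e-6)

  # raising the PMF anywhere strictly raises the resistance
  bumped <- G(zf); bumped[1500] <- bumped[1500] + 0.5
  R_b <- resistance(pmf_profile(zf, bumped), diffusion_profile(zf, Dfun(zf)))
  expect_gt(R_b, R)

  # validation: missing diffusion bins and unspanned grids are errors
  expect_error(resistance(pmf, diffusion_profile(z, c(NA, rep(0.005, length(z) - 1)))),
               "missing diffusion")
  expect_error(suppressWarnings(
    resistance(pmf, diffusion_profile(z[z <= 1], rep(0.005, sum(z <= 1))))),
    "span")
  vac <- pmf_profile(z, rep(0, length(z)), reference = "vacuum")
  expect_error(resistance(vac, dp), "solvent-calibrated")
})

test_that("the layer count is a delta-method product: 12 +/- 0.4 x 2.5 +/- 0.5 = 30 +/- 6", {
  lc <- layer_count(layer_model())
  expect_equal(lc$mean, 30)
  expect_equal(lc$se, sqrt((2.5 * 0.4)^2 + (12 * 0.5)^2), tolerance = 1e-12)
  expect_equal(round(lc$se), 6)
  expect_equal(layer_count(layer_model(12, 0, 2.5, 0))$se, 0)
})

test_that("layer scaling is exactly logarithmic and units convert consistently", {
  # unit resistance in h/cm through a single layer: K_P = 1 cm/h
  r1 <- total_permeability(1, layer_model(1, 0, 1, 0), units = "cm_h")
  expect_equal(r1$K_P, 1)
  expect_equal(r1$log10_KP, 0)

  # 80 layers instead of 1 subtract log10(80) ~ 1.9 from the log value
  r80 <- total_permeability(1, layer_model(80, 0, 1, 0), units = "cm_h")
  expect_equal(r1$log10_KP - r80$log10_KP, log10(80), tolerance = 1e-12)
  expect_equal(round(log10(80), 1), 1.9)

  # linearity for a spread of layer counts
  base <- total_permeability(500, layer_model(1, 0, 1, 0))
  for (N in c(2, 5, 30, 80, 1000)) {
    rN <- total_permeability(500, layer_model(N, 0, 1, 0))
    expect_equal(rN$log10_KP - base$log10_KP, -log10(N), tolerance = 1e-12)
  }

  # native units: 1 nm/ps = 3.6e8 cm/h
  z <- seq(0, 2, by = 0.02)
  R_native <- resistance(pmf_profile(z, rep(0, length(z))),
                         diffusion_profile(z, rep(0.005, length(z))))
  res <- total_permeability(R_native, layer_model(1, 0, 1, 0))
  expect_equal(res$K_P, 0.005 / 2 * 3.6e8, tolerance = 1e-12)
})

test_that("independent sets combine to a mean profile with standard errors", {
  z <- seq(0, 1, by = 0.1)
  f <- sin(z * 3) + 1
  s1 <- pmf_profile(z, f); s2 <- pmf_profile(z, f + 1)

  cmb <- combine_sets(list(s1, s2))
  expect_equal(cmb$dG, f + 0.5)
  expect_equal(cmb$se, rep(0.5, length(z)))

  expect_equal(combine_sets(list(s1, s1))$se, rep(0, length(z)))

  sets <- lapply(1:5, function(i) pmf_profile(z, f + i * 0.3))
  cmb5 <- combine_sets(sets)
  m <- sapply(sets, function(p) p$dG)
  expect_equal(cmb5$dG, rowMeans(m))
  expect_equal(cmb5$se, apply(m, 1, sd) / sqrt(5))

  expect_warning(combine_sets(list(s1)), "single")
  bad <- pmf_profile(z + 0.01, f)
  expect_error(combine_sets(list(s1, bad)), "common grid")
})

test_that("the full pipeline chains calibration, cleaning and scaling; MC propagation widens the error", {
  land <- desk_membrane_landscape()
  z <- seq(0, land$L, by = 0.02)
  base <- reference_pmf(land, 1, z = z, anchor = "vacuum")
  sets <- lapply(1:3, function(i) {
    p <- base
    p$dG <- p$dG + 0.2 * sin(i + z * 5)  # set-to-set variation
    p
  })
  dp <- diffusion_profile(z, rep(0.004, length(z)))
  res <- permeability_pipeline(sets, dp, dG_solv = reference_solvation(land))
  expect_s3_class(res, "permeability_result")
  expect_equal(res$K_P, 1 / res$R, tolerance = 1e-12)
  expect_equal(res$log10_KP, log10(res$K_P), tolerance = 1e-12)
  expect_identical(attr(attr(res, "pmf"), "reference_tag"), "solvent")

  res_mc <- permeability_pipeline(sets, dp, dG_solv = reference_solvation(land),
                                  uncertainty = "mc", n_mc = 100, seed = 2)
  expect_gte(res_mc$se_log10_KP, res$se_log10_KP)

  td <- tidy(res); gl <- glance(res)
  expect_identical(td$term, c("n_layers", "R_total", "K_P", "log10_KP"))
  expect_equal(gl$log10_KP, res$log10_KP)
})
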