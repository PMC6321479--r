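test_that("spectral mass centre: delta spectra, uniform grid, invariances", {
  wl <- 300:400
  i <- rep(0, length(wl)); i[wl == 307] <- 5
  expect_equal(spectral_mass_center(wl, i), 307)

  # uniform intensities: harmonic mean of the wavelength grid
  u <- rep(1, length(wl))
  oracle <- length(wl) / sum(1 / wl)
  expect_equal(spectral_mass_center(wl, u), oracle)
  expect_equal(oracle, 348.3, tolerance = 0.05)

  set.seed(4)
  ri <- runif(length(wl))
  m <- spectral_mass_center(wl, ri)
  expect_equal(spectral_mass_center(wl, 7.3 * ri), m)
  expect_gte(m, min(wl)); expect_lte(m, max(wl))
  # the two conventions differ but both stay inside the support
  md <- spectral_mass_center(wl, ri, method = "direct")
  expect_gte(md, min(wl)); expect_lte(md, max(wl))
  expect_error(spectral_mass_center(wl, rep(0, length(wl))), "all-zero")
})

test_that("mean residue ellipticity follows the per-bond normalization", {
  # 10 uM of the 12,449.89 Da construct, 0.1 cm path, -10 mdeg
  expect_equal(mean_residue_ellipticity(-10, 0.1249, 0.1, 12449.89, 109),
               -9230, tolerance = 5)
  expect_equal(mean_residue_ellipticity(0, 0.1, 0.1, 12449.89, 109), 0)
  v1 <- mean_residue_ellipticity(-10, 0.1, 0.1, 12449.89, 109)
  expect_equal(mean_residue_ellipticity(-10, 0.2, 0.1, 12449.89, 109), v1 / 2)
  expect_error(mean_residue_ellipticity(-10, 0.1, 0.1, 120, 1), "2 residues")
})

test_that("chemical two-state fit recovers synthetic sigmoids", {
  # noiseless: near-exact recovery; fraction unfolded 0.5 at the midpoint
  cv0 <- gen_denaturation("two_state", "chemical", noise = 0)
  f0 <- fit_chemical_two_state(cv0)
  expect_true(f0$physical)
  expect_equal(coef(f0)[["m"]], 2.0, tolerance = 1e-4)
  expect_equal(coef(f0)[["midpoint"]], 2.0, tolerance = 1e-4)
  expect_equal(fraction_unfolded(f0, coef(f0)[["midpoint"]]), 0.5)

  cv <- gen_denaturation("two_state", "chemical", noise = 0.01, seed = 11)
  f <- fit_chemical_two_state(cv)
  expect_true(f$physical)
  expect_lt(abs(coef(f)[["m"]] - 2.0) / 2.0, 0.1)
  expect_lt(abs(coef(f)[["midpoint"]] - 2.0) / 2.0, 0.1)
})

test_that("linear chemical traces are flagged non-physical", {
  cv <- gen_denaturation("linear", "chemical", noise = 0.01, seed = 12)
  f <- fit_chemical_two_state(cv)
  expect_false(f$physical)
  expect_true(f$linear_preferred)
})

test_that("thermal two-state fit recovers sigmoids and rejects drifts", {
  cv <- gen_denaturation("two_state", "thermal", noise = 0.01,
                         n_points = 61, seed = 13)
  f <- fit_thermal_two_state(cv)
  expect_true(f$physical)
  expect_lt(abs(coef(f)[["m"]] - 60) / 60, 0.1)
  expect_lt(abs(coef(f)[["midpoint"]] - 55), 0.1 * 55)

  lin <- gen_denaturation("linear", "thermal", noise = 0.01, seed = 14)
  fl <- fit_thermal_two_state(lin)
  expect_false(fl$physical)

  flat <- fit_thermal_two_state(
    denaturation_curve(seq(25, 85, length.out = 13), rep(0, 13)))
  expect_false(flat$physical)
  expect_true("no_transition" %in% flat$flags)
})

test_that("classification combines probes into the disorder verdict", {
  lin_c <- fit_chemical_two_state(
    gen_denaturation("linear", "chemical", noise = 0.01, seed = 15))
  lin_t <- fit_thermal_two_state(
    gen_denaturation("linear", "thermal", noise = 0.01, probe = "cd222",
                     seed = 16))
  expect_equal(classify_denaturation(list(lin_c, lin_t))$verdict,
               "non-cooperative (IDP-like)")

  sig <- fit_chemical_two_state(
    gen_denaturation("two_state", "chemical", noise = 0.01, seed = 17))
  expect_equal(classify_denaturation(list(sig))$verdict, "cooperative")
  expect_equal(classify_denaturation(list(lin_c, sig))$verdict, "cooperative")
  expect_error(classify_denaturation(list()), "at least one")
})

test_that("the straight line wins model selection on linear data", {
  n_rep <- 200
  wins <- 0
  for (i in seq_len(n_rep)) {
    cv <- gen_denaturation("linear", "chemical", noise = 0.01, seed = 3000 + i)
    f <- fit_chemical_two_state(cv)
    if (f$linear_preferred) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})
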