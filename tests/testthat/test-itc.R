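test_that("monomer fraction satisfies its mass-action quadratic", {
  expect_equal(monomer_fraction(1e-4, 1e-4), 0.5)
  expect_equal(monomer_fraction(0, 1e-4), 1)
  expect_gt(monomer_fraction(1e-6, 1), 0.999)   # kd >> c: dissociated
  expect_lt(monomer_fraction(1, 1e-9), 1e-3)    # kd -> 0: dimeric
  for (kd in c(1e-6, 1e-4, 1e-2)) for (c in c(1e-6, 1e-4, 1e-2, 1)) {
    f <- monomer_fraction(c, kd)
    expect_equal((f * c)^2 / ((1 - f) * c / 2), kd, tolerance = 1e-6)
  }
})

test_that("dilution forward model: baselines, limits, attenuation", {
  proto <- dilution_protocol(n_injections = 12)
  expect_equal(as.numeric(simulate_dilution(proto, 1e-4, 0, baseline = 0.7)),
               rep(0.7, 12))
  # syringe already monomeric: nothing to dissociate
  h <- as.numeric(simulate_dilution(proto, kd = 1e3, dh = 5, baseline = 0.2))
  expect_equal(h, rep(0.2, 12), tolerance = 1e-4)
  # heats attenuate across injections for kd comparable to the stock
  for (kd in c(2e-5, 1e-4, 5e-4)) for (dh in c(-4, 6)) {
    hh <- as.numeric(simulate_dilution(proto, kd, dh, baseline = 0))
    expect_gt(abs(hh[1]), abs(hh[12]))
    expect_true(all(diff(abs(hh)) < 0))
  }
})

test_that("displacement bookkeeping conserves protomer moles", {
  proto <- dilution_protocol(n_injections = 20)
  h <- simulate_dilution(proto, 1e-4, 5)
  injected <- attr(h, "moles_injected")
  expect_equal(injected, 20 * proto$injection_volume * proto$syringe_conc)
  expect_equal(attr(h, "moles_in_cell") + attr(h, "moles_displaced"),
               injected, tolerance = 1e-12)
})

test_that("dissociation heats sum to dh times the net dimer converted", {
  # exact heat balance: the summed heats equal dh times (dimer delivered
  # minus dimer displaced minus dimer left in the cell)
  for (kd in c(2e-5, 1e-4, 0.5)) {
    proto <- dilution_protocol(n_injections = 30)
    dh <- 5
    h <- simulate_dilution(proto, kd, dh, baseline = 0)
    convertible <- attr(h, "dimer_injected") - attr(h, "dimer_displaced") -
      attr(h, "dimer_in_cell")
    expect_equal(sum(h), dh * 1e9 * convertible, tolerance = 1e-9)
  }
  # in the near-complete-dissociation limit (kd far above cell
  # concentrations, short dilution) the sum approaches dh times the
  # dimer delivered from the syringe
  proto <- dilution_protocol(n_injections = 10)
  h <- simulate_dilution(proto, kd = 0.5, dh = 5, baseline = 0)
  expect_equal(sum(h), 5 * 1e9 * attr(h, "dimer_injected"), tolerance = 0.1)
})

test_that("dimer-model fit round-trips seeded synthetic heats", {
  proto <- dilution_protocol()
  h <- gen_itc("dimer", kd = 1e-4, dh = 5, baseline = 0.5, noise = 0.02,
               seed = 21)
  f <- fit_dimer_dissociation(h, proto, sigma = attr(h, "sigma"))
  expect_lt(abs(f$kd_dis - 1e-4) / 1e-4, 0.2)
  expect_lt(abs(f$dh_dis - 5) / 5, 0.1)
  expect_true(f$adequate)
})

test_that("higher-order cascade data defeat the dimer-only model", {
  proto <- dilution_protocol()
  h <- gen_itc("dimer_tetramer", seed = 22)
  f <- fit_dimer_dissociation(h, proto, sigma = attr(h, "sigma"))
  expect_false(f$adequate)
})

test_that("zero heats give a degenerate but flagged fit", {
  proto <- dilution_protocol()
  f <- fit_dimer_dissociation(rep(0, 28), proto)
  expect_true("no_signal" %in% f$flags)
  expect_true(f$adequate)
  expect_lt(abs(f$dh_dis), 1e-6)
})
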