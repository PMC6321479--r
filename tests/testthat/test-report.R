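# evidence bundles assembled from the default synthetic study conditions

idp_bundle <- function() {
  sr <- sequence_report(construct_seq())
  den <- classify_denaturation(list(
    fit_chemical_two_state(
      gen_denaturation("linear", "chemical", noise = 0.01, seed = 31)),
    fit_thermal_two_state(
      gen_denaturation("linear", "thermal", noise = 0.01, probe = "cd222",
                       seed = 32))))
  rs <- rs_from_reference(fit_decay(gen_dosy(seed = 33))$d_coefficient)
  saxs <- fit_ggc(gen_saxs(seed = 34))
  tr <- ksv_trend(lapply(gen_quenching(seed = 35), stern_volmer_fit))
  cal <- anchor_calibration()
  oligos <- list(
    oligomer_order(as.numeric(apparent_mw(cal, 11.98)), MONOMER_KDA, "SEC"),
    oligomer_order(66, MONOMER_KDA, "BN-PAGE"))
  h <- gen_itc("dimer_tetramer", seed = 36)
  itc <- fit_dimer_dissociation(h, dilution_protocol(),
                                sigma = attr(h, "sigma"))
  list(seq_report = sr, denaturation = den, dosy_rs = rs, saxs = saxs,
       quenching = tr, oligomers = oligos, itc = itc)
}

test_that("the default synthetic bundle is IDP-like and self-associating", {
  b <- idp_bundle()
  rep <- build_report(seq_report = b$seq_report, denaturation = b$denaturation,
                      dosy_rs = b$dosy_rs, saxs = b$saxs,
                      quenching = b$quenching, oligomers = b$oligomers,
                      itc = b$itc)
  expect_equal(rep$disorder_verdict, "IDP-like")
  expect_equal(rep$oligomer_verdict, "self-associating")
  verdicts <- vapply(rep$evidence, `[[`, character(1), "verdict")
  expect_true(all(verdicts[1:3] == "supports_disorder"))
})

test_that("a folded-control bundle is folded-like", {
  sr <- sequence_report(construct_seq())
  den <- classify_denaturation(list(
    fit_chemical_two_state(
      gen_denaturation("two_state", "chemical", noise = 0.01, seed = 41))))
  # measured Rs at the folded-scaling prediction, below the unfolded band
  rep <- build_report(seq_report = sr, denaturation = den, dosy_rs = 15.0)
  expect_equal(rep$disorder_verdict, "folded-like")
})

test_that("contradictory evidence yields a mixed verdict, never silence", {
  sr <- sequence_report(construct_seq())
  den <- classify_denaturation(list(
    fit_chemical_two_state(
      gen_denaturation("linear", "chemical", noise = 0.01, seed = 42))))
  rep <- build_report(seq_report = sr, denaturation = den, dosy_rs = 15.0)
  expect_equal(rep$disorder_verdict, "mixed evidence")
})

test_that("aggregation is monotone in supporting evidence", {
  b <- idp_bundle()
  base <- build_report(seq_report = b$seq_report,
                       denaturation = b$denaturation)
  expect_equal(base$disorder_verdict, "IDP-like")
  more <- build_report(seq_report = b$seq_report,
                       denaturation = b$denaturation, dosy_rs = b$dosy_rs,
                       saxs = b$saxs)
  expect_equal(more$disorder_verdict, "IDP-like")

  one <- build_report(oligomers = list(oligomer_order(66, MONOMER_KDA,
                                                      "BN-PAGE")))
  expect_equal(one$oligomer_verdict, "self-associating")
  two <- build_report(oligomers = list(oligomer_order(66, MONOMER_KDA,
                                                      "BN-PAGE")),
                      quenching = b$quenching)
  expect_equal(two$oligomer_verdict, "self-associating")
})

test_that("degenerate report inputs are rejected or neutral", {
  expect_error(build_report(), "no module reports")
  mono <- build_report(oligomers = list(oligomer_order(12.45, 12.45, "SEC")))
  expect_equal(mono$oligomer_verdict, "monomeric")
  expect_error(build_report(dosy_rs = 36), "sequence_report")
})
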