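test_that("generators are pure functions of their seed", {
  md5 <- function(writer, obj, ...) {
    tf <- withr::local_tempfile(fileext = ".csv")
    writer(obj, tf, ...)
    unname(tools::md5sum(tf))
  }
  expect_identical(md5(write_pfg_csv, gen_dosy(seed = 5)),
                   md5(write_pfg_csv, gen_dosy(seed = 5)))
  expect_false(identical(md5(write_pfg_csv, gen_dosy(seed = 5)),
                         md5(write_pfg_csv, gen_dosy(seed = 6))))
  expect_identical(md5(write_quench_csv, gen_quenching(seed = 5)[[1]]),
                   md5(write_quench_csv, gen_quenching(seed = 5)[[1]]))
  expect_identical(md5(write_scattering_csv, gen_saxs(seed = 5)),
                   md5(write_scattering_csv, gen_saxs(seed = 5)))
  expect_identical(
    md5(write_denaturation_csv, gen_denaturation(seed = 5)),
    md5(write_denaturation_csv, gen_denaturation(seed = 5)))
  proto <- dilution_protocol()
  wh <- function(h, path) write_heats_csv(h, proto, path)
  expect_identical(md5(wh, gen_itc(seed = 5)), md5(wh, gen_itc(seed = 5)))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_dosy(seed = 1))
  invisible(gen_saxs(seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("noiseless generator output is fit exactly by its analyzer", {
  d <- gen_dosy(noise = 0)
  expect_equal(fit_decay(d)$d_coefficient, attr(d, "truth")$d,
               tolerance = 1e-9)

  qs <- gen_quenching(noise = 0)
  for (j in seq_along(qs))
    expect_equal(stern_volmer_fit(qs[[j]])$ksv, attr(qs, "truth")$ksv[j],
                 tolerance = 1e-9)

  sc <- gen_saxs(noise = 0)
  expect_equal(sc$intensity,
               attr(sc, "truth")$scale *
                 ggc_intensity(sc$q, attr(sc, "truth")$rg,
                               attr(sc, "truth")$nu),
               tolerance = 1e-12)

  gm <- gen_sec_markers(jitter_sd = 0)
  cal <- fit_sec_calibration(gm$markers)
  expect_equal(as.numeric(apparent_mw(cal, gm$sample_volumes)),
               c(100, 31.6), tolerance = 0.01)

  h0 <- gen_itc("dimer", noise = 0, baseline = 0)
  tr <- attr(h0, "truth")
  expect_equal(as.numeric(h0),
               as.numeric(simulate_dilution(dilution_protocol(), tr$kd, tr$dh)),
               tolerance = 1e-12)
})

test_that("CSV round trips preserve data and metadata", {
  tf <- withr::local_tempfile(fileext = ".csv")

  d <- gen_dosy(seed = 8)
  write_pfg_csv(d, tf)
  d2 <- read_pfg_csv(tf)
  expect_equal(d2$gradient_strengths, d$gradient_strengths, tolerance = 1e-12)
  expect_equal(d2$intensities, d$intensities, tolerance = 1e-12)
  expect_equal(d2$delta, d$delta)

  q <- gen_quenching(seed = 8)[[2]]
  write_quench_csv(q, tf)
  q2 <- read_quench_csv(tf)
  expect_equal(q2$protein_conc, 20)
  expect_equal(q2$f0_over_f, q$f0_over_f, tolerance = 1e-12)

  s <- gen_saxs(seed = 8)
  write_scattering_csv(s, tf)
  s2 <- read_scattering_csv(tf)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(s2$sigma, s$sigma, tolerance = 1e-12)

  cv <- gen_denaturation("linear", "thermal", probe = "cd222", seed = 8)
  write_denaturation_csv(cv, tf)
  cv2 <- read_denaturation_csv(tf)
  expect_equal(cv2$probe, "cd222")
  expect_equal(cv2$axis, "thermal")
  expect_equal(cv2$y, cv$y, tolerance = 1e-12)

  gm <- gen_sec_markers()
  write_markers_csv(gm$markers, tf)
  expect_equal(read_markers_csv(tf)$mass_kda, gm$markers$mass_kda)

  proto <- dilution_protocol()
  h <- gen_itc(seed = 8)
  write_heats_csv(h, proto, tf)
  r <- read_heats_csv(tf)
  expect_equal(r$heats, as.numeric(h), tolerance = 1e-10)
  expect_equal(r$protocol$syringe_conc, proto$syringe_conc)
  expect_equal(r$sigma, attr(h, "sigma"), tolerance = 1e-10)
})

test_that("JSON reports serialize fits without raw data payloads", {
  tf <- withr::local_tempfile(fileext = ".json")
  f <- fit_decay(gen_dosy(seed = 9))
  write_json_report(f, tf)
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$d_coefficient, f$d_coefficient, tolerance = 1e-9)
  expect_null(parsed$series)

  rep <- sequence_report(construct_seq())
  write_json_report(rep, tf)
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$length, 109)
  expect_equal(parsed$radii$folded$value, 18.5, tolerance = 0.1)
})
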