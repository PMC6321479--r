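test_that("FASTA reading validates residues and record count", {
  s <- construct_seq()
  expect_s3_class(s, "protein_sequence")
  expect_equal(length(s), 109L)

  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "G"), tf)
  expect_equal(length(read_fasta(tf)), 1L)

  writeLines(c(">x", "MGB"), tf)
  expect_error(read_fasta(tf), "position 3")

  writeLines(c(">a", "MG", ">b", "GG"), tf)
  expect_error(read_fasta(tf), "single")

  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("average mass matches hand sums and the construct reference", {
  expect_equal(average_mass(protein_sequence("G"))$average_mass, 75.07,
               tolerance = 0.01)
  # two glycine residues (57.05 each) plus one water
  expect_equal(average_mass(protein_sequence("GG"))$average_mass, 132.12,
               tolerance = 0.01)
  mp <- average_mass(construct_seq())
  expect_equal(mp$residue_count, 109L)
  expect_equal(mp$average_mass, 12449.89, tolerance = 0.5)
  expect_gt(mp$average_mass, 109 * 57)
})

test_that("isoelectric point: construct value, charge zero, monotone in K", {
  s <- construct_seq()
  pi_hat <- isoelectric_point(s)
  expect_equal(pi_hat, 5.72, tolerance = 0.1)
  expect_lt(abs(net_charge(s, pi_hat)), 1e-3)

  expect_gt(isoelectric_point(protein_sequence("KKKK")), 10)

  # property: zero net charge at the returned pI; appending K never lowers pI
  set.seed(101)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    res <- paste(sample(aas, sample(5:60, 1), replace = TRUE), collapse = "")
    sq <- protein_sequence(res)
    p <- isoelectric_point(sq)
    expect_lt(abs(net_charge(sq, p)), 1e-3)
    expect_gte(isoelectric_point(protein_sequence(paste0(res, "K"))) + 1e-6, p)
  }
})

test_that("concentration from absorbance follows the two-band correction", {
  expect_equal(concentration_from_absorbance(1, 0), 1.55)
  expect_equal(concentration_from_absorbance(1, 1), 0.80)
  expect_error(concentration_from_absorbance(0.1, 0.5), "nucleic")
})

test_that("sphere radii reproduce the reference arithmetic and scaling", {
  r <- anhydrous_sphere_radius(12449.89, 0.721)
  expect_equal(r$value, 15.3, tolerance = 0.05)
  # exact cube-root scaling in mass and in specific volume
  expect_equal(anhydrous_sphere_radius(8 * 12449.89, 0.721)$value,
               2 * r$value, tolerance = 1e-12)
  expect_equal(anhydrous_sphere_radius(12449.89, 0.721 * 8)$value,
               2 * r$value, tolerance = 1e-12)
  set.seed(7)
  for (m in runif(10, 5e3, 5e5))
    expect_equal(anhydrous_sphere_radius(8 * m)$value,
                 2 * anhydrous_sphere_radius(m)$value, tolerance = 1e-12)

  expect_equal(hydrated_radius(r)$value, 18.5, tolerance = 0.05)
  expect_equal(hydrated_radius(r, shell = 0)$value, r$value)
  expect_equal(hydrated_radius(10.0, 3.2)$value, 13.2)
  expect_error(hydrated_radius(r, shell = -1), "non-negative")
})

test_that("Stokes-radius scaling laws match the printed coefficients", {
  f <- rs_folded(109)
  expect_equal(f$value, 18.5, tolerance = 0.1)
  expect_equal(c(f$lower, f$upper), c(14.2, 22.9), tolerance = 0.05)
  expect_equal(rs_folded(1)$value, 4.75)

  u <- rs_unfolded(109)
  expect_equal(u$value, 32.0, tolerance = 0.1)
  expect_equal(rs_unfolded(1)$value, 2.21)
  expect_equal(rs_unfolded(218)$value, 47.6, tolerance = 0.05)

  # strictly increasing; brute force locates the crossing of the two laws
  # at N = 16 (4.75 N^0.29 = 2.21 N^0.57 at N ~ 15.4), above which the
  # unfolded-chain prediction always exceeds the folded one
  n <- 1:1000
  fv <- vapply(n, function(k) rs_folded(k)$value, numeric(1))
  uv <- vapply(n, function(k) rs_unfolded(k)$value, numeric(1))
  expect_true(all(diff(fv) > 0))
  expect_true(all(diff(uv) > 0))
  expect_equal(min(n[uv > fv]), 16L)
  expect_true(all(uv[n >= 16] > fv[n >= 16]))
})

test_that("oligomer order rounds with residual reporting", {
  expect_equal(oligomer_order(66, MONOMER_KDA, "BN-PAGE")$order, 5L)
  expect_equal(oligomer_order(100, MONOMER_KDA, "SEC")$order, 8L)
  id <- oligomer_order(12.45, 12.45)
  expect_equal(id$order, 1L)
  expect_equal(id$residual_fraction, 0)
  # exact integer multiples recover exactly
  for (k in 1:10)
    expect_equal(oligomer_order(k * 3.7, 3.7)$order, k)
  # ambiguous ratio flagged, not silently assigned
  amb <- oligomer_order(31.6, MONOMER_KDA, "SEC")
  expect_true(amb$ambiguous)
  expect_gt(amb$residual_fraction, 0.4)
  expect_error(oligomer_order(5, 12.45), "sub-monomeric")
})

test_that("sequence report collects the full property set", {
  rep <- sequence_report(construct_seq())
  expect_equal(rep$length, 109L)
  expect_named(rep$radii, c("anhydrous", "hydrated", "folded", "unfolded"))
  expect_lt(rep$radii$anhydrous$value, rep$radii$hydrated$value)
})
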