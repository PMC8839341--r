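test_that("repeat units are acid+diol pairs and hydroxyacids, isobar-collapsed", {
  units <- candidate_repeat_units(lib_sub(c("PA", "NPG")))
  expect_equal(nrow(units), 1L)
  expect_equal(units$mass, 234.0892, tolerance = 1e-4)
  cl <- candidate_repeat_units(lib_sub("CL"))
  expect_equal(cl$mass, 114.0681, tolerance = 1e-4)
  # PA/IPA/TPA+NPG collapse to one unit; the label keeps the alternatives
  iso <- candidate_repeat_units(lib_sub(c("PA", "IPA", "TPA", "NPG")))
  expect_equal(nrow(iso), 1L)
  expect_match(iso$unit, "PA/IPA/TPA\\+NPG")
  expect_equal(nrow(candidate_repeat_units(lib_default[0, ])), 0L)
})

test_that("planted progressions are recovered in full", {
  pk <- peaklist(c(469.19, 703.27, 937.36, 1171.45))
  hits <- detect_series(pk, 234.0892)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_members, 4L)
  expect_equal(hits$base_mz, 469.19)
  # arbitrary bases and lengths, any library pair
  set.seed(21)
  units <- candidate_repeat_units(lib_sub(c("PA", "AA", "NPG", "HD", "CL")))
  for (i in 1:10) {
    u <- units$mass[sample(nrow(units), 1)]
    L <- sample(3:7, 1)
    base <- runif(1, 360, 900)
    pk <- peaklist(base + (0:(L - 1)) * u)
    got <- detect_series(pk, u, tol = 0.2, min_length = 3)
    expect_equal(nrow(got), 1L)
    expect_equal(got$n_members, L)
  }
})

test_that("the printed caprolactone triplet matches its unit in tolerance mode", {
  # printed values sit ~0.1 Da above sodiated monoisotopic arithmetic
  # (calibration drift), so they chain in Da tolerance only
  pk <- peaklist(c(593.4, 707.5, 821.6))
  hits <- detect_series(pk, 114.0681, tol = 0.2, min_length = 3)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_members, 3L)
})

test_that("random spectra rarely chain and never crash", {
  set.seed(7)
  for (i in 1:5) {
    pk <- peaklist(sort(runif(20, 350, 3000)))
    got <- detect_series(pk, 234.0892, tol = 0.2, min_length = 3)
    expect_true(nrow(got) <= 2L)
  }
})

test_that("noisy planted series keep at least 95 percent of members", {
  u <- 234.0892; tol <- 0.2; L <- 5
  recovered <- 0L; total <- 0L
  for (s in 1:100) {
    withr::with_seed(s, {
      mz <- 469.19 + (0:(L - 1)) * u + rnorm(L, 0, tol / 3)
    })
    got <- detect_series(peaklist(sort(mz)), u, tol = tol, min_length = 3)
    total <- total + L
    recovered <- recovered + if (nrow(got) > 0) max(got$n_members) else 0L
  }
  expect_gte(recovered / total, 0.95)
})

test_that("series with repeat masses apart by more than twice the tolerance never merge", {
  u1 <- 234.0892; u2 <- 234.9892  # 0.9 Da apart, tol 0.2
  p1 <- 400 + (0:4) * u1
  p2 <- 520 + (0:4) * u2
  pk <- peaklist(sort(c(p1, p2)))
  got <- detect_series(pk, u1, tol = 0.2, min_length = 3)
  for (i in seq_len(nrow(got))) {
    members <- got$member_mz[[i]]
    expect_true(all(vapply(members, function(m) any(abs(m - p1) < 1e-6),
                           logical(1))))
  }
})

test_that("exchange deltas reproduce the diol substitution mass shifts", {
  lib <- lib_sub(c("PA", "NPG", "HD", "CHDM", "EG"))
  pk <- peaklist(c(491.17, 505.19, 531.20, 449.12))
  ex <- detect_exchange_deltas(pk, lib, tol = 0.05)
  d <- function(out, into) ex$delta[ex$monomer_out == out & ex$monomer_in == into]
  expect_equal(d("NPG", "HD"), 14.0157, tolerance = 1e-4)
  expect_equal(d("NPG", "CHDM"), 40.0313, tolerance = 1e-4)
  expect_equal(d("NPG", "EG"), -42.0470, tolerance = 1e-4)
  # identical-mass pairs are excluded entirely
  ex_iso <- detect_exchange_deltas(pk, lib_sub(c("BD", "MPO", "NPG")))
  expect_false(any(abs(ex_iso$delta) < 1e-9))
  # the planted +14 spacing is counted
  expect_gte(ex$n_pairs[ex$monomer_out == "NPG" & ex$monomer_in == "HD"], 1L)
})

test_that("a single-unit spectrum infers exactly that acid+diol pair", {
  pk <- peaklist(469.19 + (0:3) * 234.0892)
  inf <- infer_monomer_set(pk, lib_sub(c("PA", "NPG", "AA", "EG")))
  expect_gte(nrow(inf), 1L)
  expect_setequal(inf$monomers[[1]], c("PA", "NPG"))
})

test_that("a mixed formulation spectrum is inferred with the dominant diol first", {
  lib <- default_monomer_library()
  sim <- simulate_maldi_peaklist(
    formulation_cm1(mass_error = list(value = 0, unit = "da")), seed = 42)
  inf <- infer_monomer_set(sim$peaks, lib)
  expect_true(all(c("PA", "NPG", "HD", "BD", "CL") %in% inf$monomers[[1]]))
  expect_equal(inf$diol_ranking[[1]][1], "NPG")
})

test_that("a CHDM/EG formulation shows the +40 and -42 exchange evidence", {
  lib <- default_monomer_library()
  sim <- simulate_maldi_peaklist(
    formulation_cm2(mass_error = list(value = 0, unit = "da")), seed = 7)
  ex <- detect_exchange_deltas(sim$peaks, lib, tol = 0.1)
  up <- ex[ex$monomer_out == "NPG" & ex$monomer_in == "CHDM", ]
  dn <- ex[ex$monomer_out == "NPG" & ex$monomer_in == "EG", ]
  expect_equal(up$delta, 40.0313, tolerance = 1e-4)
  expect_equal(dn$delta, -42.0470, tolerance = 1e-4)
  expect_gte(up$n_pairs, 3L)
  expect_gte(dn$n_pairs, 3L)
  inf <- infer_monomer_set(sim$peaks, lib)
  expect_true(all(c("PA", "NPG", "CHDM", "EG") %in% inf$monomers[[1]]))
})
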