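test_that("the same seed reproduces the same spectrum exactly", {
  f <- formulation_cm1(n_noise = 10)
  a <- simulate_maldi_peaklist(f, seed = 123)
  b <- simulate_maldi_peaklist(f, seed = 123)
  expect_identical(a$peaks$mz, b$peaks$mz)
  expect_identical(a$peaks$intensity, b$peaks$intensity)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_maldi_peaklist(f, seed = 124)
  expect_false(identical(a$peaks$mz, c2$peaks$mz))
})

test_that("a noiseless error-free spectrum contains the sodiated repeat series", {
  f <- formulation_cm1(mass_error = list(value = 0, unit = "da"))
  sim <- simulate_maldi_peaklist(f, seed = 1)
  na_pa_npg <- sim$truth[sim$truth$adduct == "M+Na" &
                           sim$truth$topology == "cyclic" &
                           grepl("^\\dPA\\+\\dNPG$", sim$truth$composition), ]
  expect_gte(nrow(na_pa_npg), 3L)
  spacing <- diff(sort(na_pa_npg$mz))
  expect_true(all(abs(spacing - 234.0892) < 1e-3))
  # every signal peak is inside the MALDI window
  expect_true(all(sim$peaks$mz >= 350 & sim$peaks$mz <= 4000))
})

test_that("a caprolactone-only formulation gives the 114.07 sodiated ladder", {
  f <- synthetic_formulation(c(CL = 1), unit_range = c(4L, 8L),
                             adducts = c("M+Na" = 1),
                             mass_error = list(value = 0, unit = "da"))
  sim <- simulate_maldi_peaklist(f, seed = 2)
  cyc <- sim$truth[sim$truth$topology == "cyclic", ]
  expect_gte(nrow(cyc), 3L)
  expect_true(all(abs(diff(sort(cyc$mz)) - 114.0681) < 1e-3))
})

test_that("msn simulation is seeded, keeps top candidates, and respects the adduct rule", {
  a <- simulate_msn_spectrum("2PA+2NPG", "cyclic", seed = 9)
  b <- simulate_msn_spectrum("2PA+2NPG", "cyclic", seed = 9)
  expect_identical(a$products, b$products)
  cand <- enumerate_fragments("2PA+2NPG", "cyclic")
  top3 <- sort(cand$mz, decreasing = TRUE)[1:3]
  expect_true(all(top3 %in% a$products$mz))
  expect_true(all(a$products$mz %in% cand$mz))
  na <- simulate_msn_spectrum("2PA+2NPG", "cyclic", precursor_adduct = "M+Na",
                              seed = 9)
  expect_equal(nrow(na$products), 0L)
  expect_equal(na$precursor$mz, 491.1677, tolerance = 1e-4)
})

test_that("formulation validation catches bad inputs", {
  expect_error(synthetic_formulation(c(XX = 1)), "not in the library")
  expect_error(simulate_maldi_peaklist(formulation_cm1()), "seed")
  f <- synthetic_formulation(c(PA = 2, NPG = 2))
  expect_equal(sum(f$monomers$proportion), 1)
})

test_that("end-to-end annotation recovers all signal peaks at zero error", {
  flib <- lib_sub(c("PA", "NPG", "HD", "BD", "CL"))
  cfg <- annotation_config(max_mass = 4000)
  f <- formulation_cm1(mass_error = list(value = 0, unit = "da"))
  sim <- simulate_maldi_peaklist(f, seed = 3)
  ann <- annotate_run(sim$peaks, flib, cfg)
  m <- tidy(ann)
  truth <- sim$truth
  correct <- vapply(seq_len(nrow(truth)), function(i) {
    any(m$peak_idx == i & m$composition == truth$composition[i] &
          m$adduct == truth$adduct[i] & m$topology == truth$topology[i])
  }, logical(1))
  expect_true(all(correct))
})
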