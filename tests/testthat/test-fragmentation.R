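test_that("ester-cleavage candidates include the interpreted fragments", {
  frs <- enumerate_fragments("2PA+2NPG", "cyclic")
  near <- function(x, target, tol = 0.01) any(abs(x - target) <= tol)
  expect_true(near(frs$mz, 149.0233))  # protonated dehydrated aromatic acid
  expect_true(near(frs$mz, 235.0965))  # protonated acid+diol ester
  expect_true(near(frs$mz, 383.1125))  # precursor minus (NPG - H2O)
  eg <- enumerate_fragments("2PA+2EG", "cyclic")
  expect_true(near(eg$mz, 193.0495))
  expect_true(near(eg$mz, 359.0761))
  hd <- enumerate_fragments("2PA+NPG+HD", "cyclic")
  expect_true(near(hd$mz, 415.1387))
})

test_that("sodiated and ammoniated precursors do not fragment", {
  for (ad in c("M+Na", "M+NH4", "M+K")) {
    frs <- enumerate_fragments("2PA+2NPG", "cyclic", precursor_adduct = ad)
    expect_equal(nrow(frs), 0L)
    expect_match(attr(frs, "note"), "no fragmentation")
  }
})

test_that("all candidates sit strictly below the precursor", {
  for (case in list(c("2PA+2NPG", "cyclic"), c("2PA+2EG", "cyclic"),
                    c("2PA+NPG", "linear"), c("3CL", "cyclic"))) {
    pre <- adduct_mz(neutral_mass(case[1], case[2]), "M+H")
    frs <- enumerate_fragments(case[1], case[2])
    expect_true(all(frs$mz < pre), label = case[1])
  }
})

test_that("the water-loss ladder off the precursor is present", {
  pre <- adduct_mz(neutral_mass("2PA+2NPG", "cyclic"), "M+H")
  frs <- enumerate_fragments("2PA+2NPG", "cyclic")
  for (k in 1:2) {
    expect_true(any(abs(frs$mz - (pre - k * 18.010565)) < 1e-6), label = k)
  }
})

test_that("candidates are deduplicated and deterministic", {
  a <- enumerate_fragments("2PA+NPG+HD", "cyclic")
  b <- enumerate_fragments("2PA+NPG+HD", "cyclic")
  expect_identical(a, b)
  key <- paste(a$fragment, a$n_water_lost)
  expect_false(any(duplicated(key)))
  # no two rows share both m/z and description
  expect_false(any(duplicated(paste(sprintf("%.6f", a$mz), a$description))))
})

test_that("observed product ions annotate against the candidates", {
  frs <- enumerate_fragments("2PA+NPG+HD", "cyclic")
  ann <- annotate_product_ions(c(415, 231, 149), frs)
  expect_equal(nrow(ann), 3L)
  m415 <- ann[ann$observed_mz == 415, ]
  expect_true(m415$matched)
  expect_equal(m415$mz, 415.1387, tolerance = 1e-3)
  expect_equal(m415$fragment, "2PA+HD")
  m149 <- ann[ann$observed_mz == 149, ]
  expect_true(m149$matched)
  expect_equal(m149$fragment, "PA")
  expect_equal(m149$n_water_lost, 1L)
  expect_equal(nrow(annotate_product_ions(numeric(0), frs)), 0L)
  out_of_range <- annotate_product_ions(999.9, frs)
  expect_false(out_of_range$matched)
})
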