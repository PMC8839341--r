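test_that("a sodiated cyclic dimer peak is matched at rank 1", {
  ions <- build_ion_table(enumerate_oligomers(lib_sub(c("PA", "NPG")),
                                              max_units = 4))
  m <- match_peaks(peaklist(491.17, instrument = "ion_trap"), ions)
  top <- m[m$rank == 1L, ]
  expect_equal(top$composition, "2PA+2NPG")
  expect_equal(top$topology, "cyclic")
  expect_equal(top$adduct, "M+Na")
  expect_equal(top$error_da, 491.17 - 491.1677, tolerance = 1e-2)
})

test_that("mixed-diol peak matches against the full default database", {
  ions <- build_ion_table(default_db())
  m <- match_peaks(peaklist(427.14, instrument = "ion_trap"), ions,
                   tol = 0.3, tol_unit = "da")
  expect_true(any(m$composition == "2PA+NPG+EG" & m$topology == "cyclic" &
                    m$adduct == "M+H"))
  # isobaric acid isomers are reported, not hidden
  hit <- m[m$composition == "2PA+NPG+EG" & m$adduct == "M+H", ]
  expect_match(hit$isobaric_note[1], "IPA")
})

test_that("empty peak lists give empty matches and unsorted input warns", {
  ions <- build_ion_table(enumerate_oligomers(lib_sub(c("PA", "NPG")),
                                              max_units = 4))
  empty <- match_peaks(peaklist(numeric(0)), ions)
  expect_equal(nrow(empty), 0L)
  raw <- data.frame(mz = c(491.17, 469.19), intensity = c(1, 1))
  expect_warning(m <- match_peaks(raw, ions, tol = 0.3), "not sorted")
  expect_true(all(c(469.19, 491.17) %in% m$peak_mz))
})

test_that("shrinking the tolerance never adds matches", {
  ions <- build_ion_table(enumerate_oligomers(lib_sub(c("PA", "NPG", "EG")),
                                              max_units = 6))
  pk <- peaklist(c(385.15, 469.21, 491.10), instrument = "ion_trap")
  tols <- c(0.5, 0.3, 0.1, 0.05, 0.01)
  counts <- vapply(tols, function(tl) nrow(match_peaks(pk, ions, tol = tl)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  wide <- match_peaks(pk, ions, tol = 0.5)
  narrow <- match_peaks(pk, ions, tol = 0.05)
  key <- function(m) paste(m$peak_idx, m$composition, m$topology, m$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("reported error is observed minus theoretical with sign", {
  ions <- build_ion_table(enumerate_oligomers(lib_sub(c("PA", "NPG")),
                                              max_units = 4))
  m_hi <- match_peaks(peaklist(469.20, instrument = "ion_trap"), ions)
  expect_gt(m_hi$error_da[m_hi$rank == 1], 0)
  m_lo <- match_peaks(peaklist(469.17, instrument = "ion_trap"), ions)
  expect_lt(m_lo$error_da[m_lo$rank == 1], 0)
})

test_that("planted ions at zero error are all matched at rank 1", {
  lib <- lib_sub(c("PA", "NPG", "HD"))
  db <- enumerate_oligomers(lib, max_units = 6)
  ions <- build_ion_table(db)
  set.seed(5)
  planted <- ions[sample(nrow(ions), 25), ]
  planted <- planted[order(planted$mz), ]
  m <- match_peaks(tibble::tibble(mz = planted$mz, intensity = 1), ions,
                   tol = 1e-6)
  expect_equal(attr(m, "unassigned"), integer(0))
  top <- m[m$rank == 1L, ]
  # rank-1 theoretical m/z equals the planted ion's m/z exactly
  expect_equal(top$theoretical_mz, planted$mz, tolerance = 1e-9)
})

test_that("annotate_run summarises assignments and flags the unassigned", {
  pk <- peaklist(c(469.19, 491.17, 800.00), instrument = "ion_trap")
  ann <- annotate_run(pk, lib_sub(c("PA", "NPG")))
  expect_s3_class(ann, "oligomer_annotation")
  g <- glance(ann)
  expect_equal(g$n_peaks, 3L)
  expect_equal(g$n_assigned, 2L)
  expect_equal(g$assignment_rate, 2 / 3, tolerance = 1e-9)
  expect_equal(nrow(ann$unassigned), 1L)
  expect_equal(ann$unassigned$mz, 800)
  expect_true(all(c("composition", "rank", "error_da") %in% names(tidy(ann))))
})

test_that("pure-noise spectra are handled without crashing", {
  set.seed(99)
  pk <- peaklist(sort(runif(30, 360, 990)), instrument = "ion_trap")
  ann <- annotate_run(pk, lib_sub(c("PA", "NPG")))
  expect_true(glance(ann)$assignment_rate >= 0)
  expect_equal(glance(ann)$n_peaks, 30L)
})
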