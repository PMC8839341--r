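test_that("ester-bond count follows topology", {
  expect_equal(ester_bond_count("2PA+2NPG", "cyclic"), 4L)
  expect_equal(ester_bond_count("2PA+CHDM", "linear"), 2L)
  expect_equal(ester_bond_count("PA", "linear"), 0L)
})

test_that("feasibility encodes the alternation rules", {
  expect_true(is_feasible("2PA+2NPG", "cyclic"))
  f <- is_feasible("2PA+NPG", "cyclic")
  expect_false(f)
  expect_match(attr(f, "reason"), "imbalance")
  expect_true(is_feasible("5CL", "cyclic"))        # hydroxyacid self-ring
  expect_true(is_feasible("2PA+NPG", "linear"))    # diacid-terminated
  expect_true(is_feasible("PA+2CHDM", "linear"))   # diol-terminated
  expect_false(is_feasible("3PA+NPG", "linear"))
  expect_false(is_feasible("TMA+2NPG", "cyclic"))  # no branched rings
  expect_true(is_feasible("TMA+2NPG", "linear"))
  expect_error(is_feasible("2XX+NPG", "linear"), "unknown monomer")
})

test_that("neutral mass and formula follow water-loss arithmetic", {
  expect_equal(neutral_mass("2PA+2NPG", "cyclic"), 468.1784, tolerance = 1e-4)
  expect_equal(neutral_mass("2PA+2NPG", "linear") -
                 neutral_mass("2PA+2NPG", "cyclic"), 18.010565,
               tolerance = 1e-6)
  expect_identical(format_formula(oligomer_formula("2TPA+2NPG", "cyclic")),
                   "C26H28O8")
})

test_that("enumeration finds the reference cyclic dimer and respects bounds", {
  db <- enumerate_oligomers(lib_sub(c("PA", "NPG")), max_units = 4)
  hit <- db[db$composition == "2PA+2NPG" & db$topology == "cyclic", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mass, 468.1784, tolerance = 1e-4)
  expect_equal(hit$n_ester_bonds, 4L)
  expect_true(all(db$mass <= 1000))
  expect_true(all(db$n_units <= 4))
  expect_error(enumerate_oligomers(lib_default[0, ]), "empty")
})

test_that("enumeration equals the brute-force oracle on small libraries", {
  cases <- list(
    list(ids = c("PA", "NPG"), max_units = 5, max_mass = 1500),
    list(ids = c("PA", "NPG", "CL"), max_units = 5, max_mass = 1200),
    list(ids = c("AA", "EG", "TMA"), max_units = 4, max_mass = 1000),
    list(ids = c("TPA", "GLY"), max_units = 4, max_mass = 1000)
  )
  for (cs in cases) {
    lib <- lib_sub(cs$ids)
    got <- enumerate_oligomers(lib, cs$max_units, cs$max_mass)
    want <- oracle_enumerate(lib, cs$max_units, cs$max_mass)
    expect_identical(enum_key(got), enum_key(want),
                     label = paste(cs$ids, collapse = "+"))
  }
})

test_that("raising the mass cutoff only adds compositions", {
  lib <- lib_sub(c("PA", "NPG", "EG"))
  lo <- enumerate_oligomers(lib, max_units = 6, max_mass = 700)
  hi <- enumerate_oligomers(lib, max_units = 6, max_mass = 1000)
  expect_true(all(enum_key(lo) %in% enum_key(hi)))
  expect_true(all(lo$mass <= 700))
  expect_gt(nrow(hi), nrow(lo))
})

test_that("cyclic and linear forms of the same counts differ by one water", {
  db <- enumerate_oligomers(lib_sub(c("PA", "NPG", "HD")), max_units = 6)
  cyc <- db[db$topology == "cyclic", ]
  lin <- db[db$topology == "linear", ]
  shared <- intersect(cyc$composition, lin$composition)
  expect_gt(length(shared), 5L)
  for (comp in shared) {
    expect_equal(lin$mass[lin$composition == comp] -
                   cyc$mass[cyc$composition == comp], 18.010565,
                 tolerance = 1e-6)
  }
})

test_that("isobaric monomers give distinct compositions with equal mass", {
  db <- enumerate_oligomers(lib_sub(c("PA", "TPA", "NPG")), max_units = 4)
  a <- db[db$composition == "2PA+2NPG" & db$topology == "cyclic", ]
  b <- db[db$composition == "2TPA+2NPG" & db$topology == "cyclic", ]
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(a$mass, b$mass, tolerance = 1e-9)
})

test_that("every published composition is in the default database", {
  db <- default_db()
  for (r in seq_len(nrow(table4))) {
    hit <- db[db$composition == table4$composition[r] &
                db$topology == table4$topology[r], ]
    expect_equal(nrow(hit), 1L, label = table4$composition[r])
  }
})
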