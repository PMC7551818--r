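test_that("packaged fixture loads with the published frontier energies", {
  rec <- load_record(system.file("extdata", "theopapuamide_A.json",
                                 package = "cdftkit"))
  expect_s3_class(rec, "esr")
  expect_equal(rec$eps_homo, -6.3114)
  expect_equal(rec$eps_lumo, -0.8210)
  expect_identical(rec$unit, "eV")
})

test_that("validation rejects degenerate gaps and broken sum rules by name", {
  expect_error(
    electronic_structure_record("bad", eps_homo = -5, eps_lumo = -5),
    "eps_homo must lie strictly below eps_lumo"
  )
  # three atoms whose neutral charges sum to 0.5 while total charge is 0
  expect_error(
    atom_record(q_neutral = c(0.5, 0.1, -0.1),
                q_cation = c(1, 0.25, -0.25), q_anion = c(-0.6, 0, -0.4)),
    "sum rule broken: sum\\(q_neutral\\)"
  )
  expect_error(
    atom_record(q_neutral = c(0, 0), q_cation = c(0.5, 0.2),
                q_anion = c(-1, 0)),
    "sum rule broken: sum\\(q_cation\\)"
  )
  # partial charge sets must come as a group, naming the absent species
  rec <- atom_record(q_neutral = c(0, 0), q_cation = c(1, 0),
                     q_anion = c(-1, 0))
  rec$atoms$q_anion <- NULL
  expect_error(validate_record(rec), "q_anion")
  # non-contiguous atom indices
  rec2 <- atom_record(q_neutral = c(0, 0), q_cation = c(1, 0),
                      q_anion = c(-1, 0))
  rec2$atoms$index <- c(1L, 3L)
  expect_error(validate_record(rec2), "contiguous")
})

test_that("sum-rule tolerance is configurable", {
  rec <- atom_record(q_neutral = c(0.0004, 0), q_cation = c(1, 0.0004),
                     q_anion = c(-1, 0.0004), validate = FALSE)
  expect_silent(validate_record(rec, sum_tolerance = 1e-3))
  expect_error(validate_record(rec, sum_tolerance = 1e-5), "sum rule broken")
})

test_that("unit conversion uses the pinned constant, is idempotent and invertible", {
  rec <- electronic_structure_record("h", eps_homo = -1, eps_lumo = 1,
                                     unit = "hartree")
  ev <- convert_units(rec, "eV")
  expect_equal(ev$eps_lumo, 27.211386)
  expect_identical(convert_units(ev, "eV"), ev)
  back <- convert_units(ev, "hartree")
  expect_equal(back$eps_homo, rec$eps_homo, tolerance = 1e-12)
  rec$unit <- "kcal/mol"
  expect_error(convert_units(rec, "eV"), "unknown unit tag")
})

test_that("record write -> read round trip is lossless", {
  rec <- generate_synthetic_record(seed = 11, n_atoms = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_record(rec, path)
  back <- load_record(path)
  for (f in c("molecule_id", "unit", "eps_homo", "eps_lumo",
              "eps_somo_anion", "e_n", "e_nm1", "e_np1")) {
    expect_equal(back[[f]], rec[[f]], info = f)
  }
  expect_equal(as.data.frame(back$atoms), as.data.frame(rec$atoms))
})

test_that("unknown top-level fields survive a round trip as metadata", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version":"1.0","molecule_id":"m","unit":"eV",
              "eps_homo":-6,"eps_lumo":-1,"lab_notes":"run 42"}', path)
  rec <- load_record(path)
  expect_identical(rec$extra$lab_notes, "run 42")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_record(rec, path2)
  expect_identical(load_record(path2)$extra$lab_notes, "run 42")
})

test_that("generator is deterministic, valid across seeds, and leaves the RNG alone", {
  expect_identical(generate_synthetic_record(3, n_atoms = 7),
                   generate_synthetic_record(3, n_atoms = 7))
  for (seed in 1:25) {
    rec <- generate_synthetic_record(seed, n_atoms = 1 + seed %% 12)
    expect_silent(validate_record(rec))
  }
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_synthetic_record(1))
  expect_identical(runif(1), before)
})

test_that("Koopmans-exact generation zeroes the KID descriptors", {
  rec <- generate_synthetic_record(seed = 1, n_atoms = 5, delta_max = 0)
  kid <- compute_kid(rec)
  expect_equal(kid$j_i, 0)
  expect_equal(kid$j_a, 0)
  expect_equal(kid$j_hl, 0)
})

test_that("unit conversion commutes with descriptor computation", {
  for (seed in c(2, 5, 8)) {
    rec <- generate_synthetic_record(seed, n_atoms = 4)
    hart <- convert_units(rec, "hartree")
    g_ev <- compute_global(rec)
    g_hart <- compute_global(hart)
    for (f in c("chi", "eta", "omega", "omega_minus", "omega_plus",
                "net_electrophilicity")) {
      expect_equal(g_hart[[f]], g_ev[[f]], tolerance = 1e-9, info = f)
    }
    expect_equal(compute_kid(hart)$j_hl, compute_kid(rec)$j_hl,
                 tolerance = 1e-9)
  }
})

test_that("the quantum-chemistry log converter is a documented stub", {
  expect_error(convert_qc_log("any.log"), "not implemented")
})
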