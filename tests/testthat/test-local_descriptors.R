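test_that("a fully localised frontier electron condenses onto one atom", {
  rec <- atom_record(q_neutral = c(0, 0), q_cation = c(1, 0),
                     q_anion = c(-1, 0))
  tab <- condensed_fukui(rec)
  expect_equal(tab$f_plus, c(1, 0))
  expect_equal(tab$f_minus, c(1, 0))
  expect_equal(tab$f_zero, c(1, 0))
  expect_equal(tab$dual, c(0, 0))
})

test_that("uniform delocalisation gives f = 1/n on every atom", {
  n <- 8
  rec <- atom_record(q_neutral = rep(0, n), q_cation = rep(1 / n, n),
                     q_anion = rep(-1 / n, n))
  tab <- condensed_fukui(rec)
  expect_equal(tab$f_plus, rep(1 / n, n))
  expect_equal(tab$f_minus, rep(1 / n, n))
})

test_that("Fukui and Parr sum rules hold for every generated record", {
  for (seed in 1:30) {
    rec <- generate_synthetic_record(seed, n_atoms = 2 + seed %% 19)
    fuk <- condensed_fukui(rec)
    expect_equal(sum(fuk$f_plus), 1, tolerance = 1e-9)
    expect_equal(sum(fuk$f_minus), 1, tolerance = 1e-9)
    expect_equal(sum(fuk$f_zero), 1, tolerance = 1e-9)
    expect_equal(sum(fuk$dual), 0, tolerance = 1e-9)
    par <- parr_functions(rec)
    expect_equal(sum(par$p_plus), 1, tolerance = 1e-9)
    expect_equal(sum(par$p_minus), 1, tolerance = 1e-9)
    expect_equal(sum(par$parr_diff), 0, tolerance = 1e-9)
    # independent recomputation of the dual descriptor from raw charges
    a <- rec$atoms
    expect_equal(fuk$dual,
                 (a$q_neutral - a$q_anion) - (a$q_cation - a$q_neutral))
  }
})

test_that("condensation is invariant under a uniform shift of all charge sets", {
  rec <- generate_synthetic_record(5, n_atoms = 9)
  shifted <- rec
  for (col in c("q_neutral", "q_cation", "q_anion")) {
    shifted$atoms[[col]] <- shifted$atoms[[col]] + 0.37
  }
  # the shifted sets break the absolute sum rules but not the differences
  expect_equal(condensed_fukui(shifted)[, c("f_plus", "f_minus", "dual")],
               condensed_fukui(rec)[, c("f_plus", "f_minus", "dual")])
})

test_that("Parr functions map spin populations through unchanged", {
  rec <- atom_record(q_neutral = rep(0, 3), q_cation = c(1, 0, 0),
                     q_anion = c(-1, 0, 0),
                     spin_cation = c(0.2, 0.3, 0.5),
                     spin_anion = c(0.9, 0.1, 0))
  par <- parr_functions(rec)
  expect_equal(par$p_plus, c(0.9, 0.1, 0))
  expect_equal(par$p_minus, c(0.2, 0.3, 0.5))
  expect_equal(par$parr_diff, c(0.7, -0.2, -0.5))
  expect_equal(sum(par$parr_diff), 0)
})

test_that("missing inputs raise errors naming what is absent", {
  rec <- atom_record(q_neutral = c(0, 0), q_cation = c(1, 0),
                     q_anion = c(-1, 0))
  rec$atoms$q_cation <- NULL
  expect_error(condensed_fukui(rec), "q_cation")
  expect_error(parr_functions(rec), "no atomic spin populations")
  bare <- electronic_structure_record("b", eps_homo = -6, eps_lumo = -1)
  expect_error(condensed_fukui(bare), "no per-atom data")
  expect_error(local_site_table(bare), "neither Fukui nor Parr")
})

test_that("site ranking is by descending value with index tie-break", {
  tab <- site_table(f_plus = c(0.1, 0.5, 0.4))
  expect_equal(rank_sites(tab, "f_plus", k = 1)$index, 2L)
  ties <- site_table(f_plus = c(0.5, 0.5))
  expect_equal(rank_sites(ties, "f_plus", k = 1)$index, 1L)
  expect_warning(out <- rank_sites(tab, "f_plus", k = 10), "exceeds")
  expect_equal(nrow(out), 3L)
  hv <- site_table(f_plus = c(0.6, 0.4), element = c("H", "C"))
  expect_equal(rank_sites(hv, "f_plus", k = 1, heavy_only = TRUE)$index, 2L)
  expect_error(rank_sites(tab, "nope", k = 1), "not present")
})

test_that("ranking matches an exhaustive sort oracle on random tables", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    tab <- site_table(dual = runif(n, -1, 1))
    got <- rank_sites(tab, "dual", k = n)$index
    oracle <- tab$index[order(-tab$dual, tab$index)]
    expect_identical(got, oracle)
  }
})

test_that("Fukui/Parr agreement reports overlap and concentration", {
  same <- site_table(f_plus = c(0.5, 0.3, 0.2), f_minus = c(0.2, 0.3, 0.5),
                     p_plus = c(0.6, 0.3, 0.1), p_minus = c(0.1, 0.3, 0.6))
  cmp <- compare_fukui_parr(same, k = 3)
  expect_equal(cmp$overlap_plus, 1)
  expect_equal(cmp$overlap_minus, 1)
  disjoint <- site_table(f_plus = c(1, 0), f_minus = c(1, 0),
                         p_plus = c(0, 1), p_minus = c(0, 1))
  cmp2 <- compare_fukui_parr(disjoint, k = 1)
  expect_equal(cmp2$overlap_plus, 0)
  expect_equal(cmp2$overlap_minus, 0)
})

test_that("generated records give perfect channel agreement with sharper Parr maps", {
  # the generator builds spin populations as renormalised powers of the
  # Fukui weights: rankings survive, maxima grow
  for (seed in c(7, 21, 33)) {
    tab <- local_site_table(generate_synthetic_record(seed, n_atoms = 15))
    cmp <- compare_fukui_parr(tab, k = 3)
    expect_equal(cmp$overlap_plus, 1)
    expect_equal(cmp$overlap_minus, 1)
    expect_gt(cmp$concentration_plus, 1)
    expect_gt(cmp$concentration_minus, 1)
  }
})

test_that("site tables export to CSV in the appendix shape", {
  tab <- local_site_table(generate_synthetic_record(2, n_atoms = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_site_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("index", "element", "f_plus", "f_minus",
                              "f_zero", "dual", "p_minus", "p_plus",
                              "parr_diff"))
  expect_equal(back$f_plus, tab$f_plus)
})
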