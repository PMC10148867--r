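base_lookup <- function() build_aa_lookup(compile_mod_sets(), 1)

test_that("peptide masses sum residues plus water plus modifications", {
  lk <- base_lookup()
  expect_equal(peptide_mass("PEPTIDE", lk), 799.35997, tolerance = 1e-5)

  rm <- setNames(residue_masses()$mass, residue_masses()$residue)
  expect_equal(peptide_mass("M", lk), rm[["M"]] + 18.010565,
               tolerance = 1e-4)

  ox <- build_aa_lookup(compile_mod_sets(variable = "Oxidation (M)"), 2)
  expect_equal(
    peptide_mass("MAMK", ox, mod_positions = 1L, mod_titles = "Oxidation"),
    peptide_mass("MAMK", ox) + 15.99491,
    tolerance = 1e-4
  )
  expect_error(peptide_mass("PXP", lk), "position 2")
})

test_that("peptide mass is invariant to modification application order", {
  ox <- compile_mod_sets(variable = c("Oxidation (M)", "Phospho (S)"))
  lk <- build_aa_lookup(ox, nrow(ox))
  m1 <- peptide_mass("MSAMSK", lk, c(1L, 2L), c("Oxidation", "Phospho"))
  m2 <- peptide_mass("MSAMSK", lk, c(2L, 1L), c("Phospho", "Oxidation"))
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("assignment enumeration matches combinatorial counts", {
  sets <- compile_mod_sets(variable = "Oxidation (M)")
  a <- enumerate_assignments("MAMK", sets, 2)
  expect_equal(nrow(a), 4L)
  expect_setequal(
    vapply(a$mod_positions, paste, character(1), collapse = ","),
    c("", "1", "3", "1,3")
  )

  # for n modifiable sites the count is sum_{j=0..min(3,n)} choose(n, j)
  setsP <- compile_mod_sets(variable = "Phospho (S)")
  for (n_sites in 1:6) {
    pep <- paste0(paste(rep("AS", n_sites), collapse = ""), "K")
    a <- enumerate_assignments(pep, setsP, 2,
                               caps = list(max_sites = 5L, max_per_mod = 3L,
                                           max_perms = 1000L))
    expect_equal(nrow(a),
                 sum(choose(n_sites, 0:min(3, n_sites))))
  }
})

test_that("the 64-permutation cap truncates deterministically", {
  setsP <- compile_mod_sets(variable = "Phospho (S)")
  pep <- "ASSSSASSSSAK"  # 8 S sites: 1 + 8 + 28 + 56 = 93 raw assignments
  raw <- enumerate_assignments(pep, setsP, 2,
                               caps = list(max_sites = 5L, max_per_mod = 3L,
                                           max_perms = 1000L))
  expect_equal(nrow(raw), 93L)
  capped <- enumerate_assignments(pep, setsP, 2)
  expect_equal(nrow(capped), 64L)
  # simplest explanations first: retained assignments are ordered by the
  # number of modified sites, and the cap keeps the head of that order
  expect_equal(lengths(capped$mod_positions),
               sort(lengths(raw$mod_positions))[1:64])
  # unmodified assignment always survives
  expect_true(any(lengths(capped$mod_positions) == 0L))
  # truncation is reproducible
  again <- enumerate_assignments(pep, setsP, 2)
  expect_identical(capped$mod_positions, again$mod_positions)
})

test_that("primary b/y series reproduce residue arithmetic", {
  lk <- base_lookup()
  io <- ion_series("AG", lk, charge = 2)
  expect_equal(io$mz[io$channel == "b"], 72.04439, tolerance = 1e-4)
  expect_equal(io$mz[io$channel == "y"], 76.03930, tolerance = 1e-4)

  # mass conservation: b_i + y_{n-i} = neutral mass + 2 protons
  set.seed(21)
  for (i in 1:10) {
    pep <- paste(sample(residue_masses()$residue, 12, replace = TRUE),
                 collapse = "")
    io <- ion_series(pep, lk, charge = 2)
    b <- io$mz[io$channel == "b"]
    y <- io$mz[io$channel == "y"]
    nm <- peptide_mass(pep, lk)
    expect_equal(b + rev(y), rep(nm + 2 * 1.007276, length(b)),
                 tolerance = 1e-5)
  }
})

test_that("a fixed N-terminal label shifts b ions only", {
  plain <- base_lookup()
  tmt <- build_aa_lookup(
    compile_mod_sets(fixed = "TMT10plex (N-term)"), 1
  )
  io0 <- ion_series("PEPTIDEK", plain, charge = 2)
  io1 <- ion_series("PEPTIDEK", tmt, charge = 2)
  label <- 229.162932
  expect_equal(io1$mz[io1$channel == "b"],
               io0$mz[io0$channel == "b"] + label, tolerance = 1e-5)
  expect_equal(io1$mz[io1$channel == "y"],
               io0$mz[io0$channel == "y"], tolerance = 1e-9)
})

test_that("satellite channels sit at fixed offsets from their primaries", {
  lk <- base_lookup()
  io <- ion_series("NESTLAKDR", lk, charge = 3)
  prim <- io[io$primary, ]
  key <- function(ch, idx) paste(ch, idx)
  pmz <- setNames(prim$mz, key(prim$channel, prim$idx))
  sat <- io[!io$primary, ]
  for (r in seq_len(nrow(sat))) {
    parent_mz <- pmz[[key(sat$parent[r], sat$idx[r])]]
    got <- sat$mz[r]
    ch <- sat$channel[r]
    expected <- switch(
      sub("\\^2$", "", ch),
      "b*" = , "y*" = parent_mz - 17.026549,
      "b0" = , "y0" = parent_mz - 18.010565,
      "b" = , "y" = parent_mz
    )
    if (grepl("\\^2$", ch)) expected <- (expected + 1.007276) / 2
    expect_equal(got, expected, tolerance = 1e-5)
  }
})

test_that("loss channels are gated on fragment residue content", {
  lk <- base_lookup()
  set.seed(22)
  for (i in 1:15) {
    pep <- paste(sample(residue_masses()$residue, 9, replace = TRUE),
                 collapse = "")
    res <- strsplit(pep, NULL)[[1]]
    n <- length(res)
    io <- ion_series(pep, lk, charge = 2)
    for (idx in seq_len(n - 1)) {
      bfrag <- res[1:idx]
      yfrag <- res[(n - idx + 1):n]
      expect_equal(any(io$channel == "b*" & io$idx == idx),
                   any(bfrag %in% c("R", "K", "N", "Q")))
      expect_equal(any(io$channel == "y*" & io$idx == idx),
                   any(yfrag %in% c("R", "K", "N", "Q")))
      expect_equal(any(io$channel == "b0" & io$idx == idx),
                   any(bfrag %in% c("S", "T", "E", "D")))
      expect_equal(any(io$channel == "y0" & io$idx == idx),
                   any(yfrag %in% c("S", "T", "E", "D")))
    }
  }
})

test_that("phosphate loss channels follow the modified residue", {
  sets <- compile_mod_sets(variable = "Phospho (S)")
  lk <- build_aa_lookup(sets, 2)
  io <- ion_series("AASAAK", lk, mod_positions = 3L, mod_titles = "Phospho",
                   charge = 2)
  loss <- io[grepl("-98", io$channel), ]
  expect_true(nrow(loss) > 0)
  # b loss only from b3 on, y loss only from y4 on
  expect_true(all(loss$idx[startsWith(loss$channel, "b")] >= 3L))
  expect_true(all(loss$idx[startsWith(loss$channel, "y")] >= 4L))
  bloss <- loss[loss$channel == "b-98" & loss$idx == 3, ]
  b3 <- io$mz[io$channel == "b" & io$idx == 3]
  expect_equal(bloss$mz, b3 - 97.9769, tolerance = 1e-4)

  unmod <- ion_series("AASAAK", lk, charge = 2)
  expect_false(any(grepl("-98", unmod$channel)))
})

test_that("doubly charged channels appear only for charge >= 3 precursors", {
  lk <- base_lookup()
  io2 <- ion_series("PEPTIDEK", lk, charge = 2)
  io3 <- ion_series("PEPTIDEK", lk, charge = 3)
  expect_false(any(grepl("\\^2$", io2$channel)))
  expect_true(any(io3$channel == "b^2"))
  b <- io3$mz[io3$channel == "b"]
  b2 <- io3$mz[io3$channel == "b^2"]
  expect_equal(b2, (b + 1.007276) / 2, tolerance = 1e-5)
})

test_that("monopeptide and MS2 calculators tabulate all assignments", {
  cm <- calc_monopeptide("MAMK", variable = "Oxidation (M)")
  expect_equal(nrow(cm), 5L)  # unmodified set + {none, M1, M3, M1+M3}
  expect_true(all(c("mz_2", "mz_3") %in% names(cm)))
  ions <- calc_ms2ionseries("MAMK", variable = "Oxidation (M)", charge = 2)
  expect_true(all(c("b", "y") %in% ions$channel))
  expect_setequal(unique(ions$set_index), 1:2)
})
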