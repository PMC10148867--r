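test_that("composition masses follow elemental arithmetic", {
  expect_equal(composition_mass("H(2) O"), 18.010565, tolerance = 1e-6)
  expect_equal(composition_mass(""), 0)
  expect_equal(composition_mass("H(-1) N(-1) O"), 0.984016, tolerance = 1e-5)
  # isotope labels differ from the base element at the neutron level
  masses <- element_masses()
  m <- function(el) masses$mass[masses$element == el]
  expect_equal(m("13C") - m("C"), 1.00336, tolerance = 1e-5)
  expect_true(all(masses$mass > 0))
  expect_error(composition_mass("H(2) Xq"), "Xq")
})

test_that("the TMT10plex/TMTzero mass gap comes out of the compositions", {
  reg <- mod_registry()
  tmt10 <- reg$composition[reg$title == "TMT10plex"][1]
  tmt0 <- reg$composition[reg$title == "TMTzero"][1]
  expect_equal(round(composition_mass(tmt10) - composition_mass(tmt0), 5),
               5.01045)
})

test_that("registry masses agree with their compositions", {
  reg <- mod_registry()
  expect_true(all(abs(reg$mono_mass - composition_mass(reg$composition)) <
                    1e-4))
})

test_that("modification specifications parse against the registry", {
  ox <- parse_mod_spec("Oxidation (M)")
  expect_equal(ox$title, "Oxidation")
  expect_equal(ox$site, "M")
  expect_equal(ox$position, "Anywhere")

  tmt <- parse_mod_spec("TMT10plex (N-term)")
  expect_equal(tmt$site, "N-term")
  expect_equal(tmt$position, "Any N-term")

  pyro <- parse_mod_spec("Gln->pyro-Glu (N-term = Q)")
  expect_equal(pyro$site, "Q")
  expect_equal(pyro$position, "Any N-term")

  ac <- parse_mod_spec("Acetyl (Protein N-term)")
  expect_equal(ac$position, "Protein N-term")

  expect_error(parse_mod_spec("Oxidation (Z)"), "no registry entry")
  expect_error(parse_mod_spec("Madeupmod (K)"), "Unknown modification title")
  expect_error(parse_mod_spec("Acetyl (N-term)"), "registered at position")
})

test_that("registry add/remove and plain-text persistence round-trip", {
  reg <- add_mod(mod_registry(), "TMT10plex+pyro-Glu", "Q", "Any N-term",
                 c("H(20) C(8) 13C(4) N 15N O(2)", "H(-3) N(-1)"))
  new <- reg[reg$title == "TMT10plex+pyro-Glu", ]
  expect_equal(new$mono_mass,
               composition_mass("H(20) C(8) 13C(4) N 15N O(2)") +
                 composition_mass("H(-3) N(-1)"))
  expect_error(
    add_mod(reg, "Bad", "K", "Anywhere", "O", mono_mass = 20),
    "more than 1e-4"
  )
  reg2 <- remove_mod(reg, "TMT10plex+pyro-Glu")
  expect_false("TMT10plex+pyro-Glu" %in% reg2$title)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_mod_registry(reg, path)
  back <- read_mod_registry(path)
  expect_equal(back$title, reg$title)
  expect_equal(back$mono_mass, reg$mono_mass, tolerance = 1e-9)
  expect_equal(back$neutral_losses, reg$neutral_losses, tolerance = 1e-6)
})

ts_worked_sets <- function() {
  compile_mod_sets(
    fixed = c("Carbamidomethyl (C)", "TMT10plex (N-term)", "TMT10plex (K)"),
    variable = c("Acetyl (Protein N-term)", "Gln->pyro-Glu (N-term = Q)",
                 "Oxidation (M)", "Deamidated (N)")
  )
}

test_that("the TMT worked specification compiles to 12 factorized sets", {
  sets <- ts_worked_sets()
  expect_equal(nrow(sets), 12L)

  state <- purrr::map_chr(seq_len(12), function(i) {
    all_mods <- dplyr::bind_rows(sets$fixed[[i]], sets$variable[[i]])
    nterm <- all_mods$title[all_mods$site %in% c("N-term", "Q") &
                              grepl("N-term", all_mods$position)]
    paste(
      nterm,
      "Oxidation" %in% all_mods$title,
      "Deamidated" %in% all_mods$title
    )
  })
  # 3 N-terminal states x 2 oxidation states x 2 deamidation states
  expect_equal(length(unique(state)), 12L)
  nterm_states <- unique(purrr::map_chr(strsplit(state, " "), 1))
  expect_setequal(nterm_states, c("TMT10plex", "Acetyl", "Gln->pyro-Glu"))
})

test_that("compilation obeys the structural invariants", {
  sets <- ts_worked_sets()
  for (i in seq_len(nrow(sets))) {
    fx <- sets$fixed[[i]]
    vr <- sets$variable[[i]]
    # no site both fixed and variable
    expect_length(intersect(fx$site, vr$site), 0)
    # at most one modification per terminus
    all_mods <- dplyr::bind_rows(fx, vr)
    nterm <- grepl("N-term", all_mods$position)
    cterm <- grepl("C-term", all_mods$position)
    expect_lte(sum(nterm), 1L)
    expect_lte(sum(cterm), 1L)
  }
})

test_that("compiling the union of emitted sets reproduces the collection", {
  sets <- ts_worked_sets()
  fx_union <- dplyr::distinct(dplyr::bind_rows(sets$fixed),
                              title, site, .keep_all = TRUE)
  vr_union <- dplyr::distinct(dplyr::bind_rows(sets$variable),
                              title, site, .keep_all = TRUE)
  # coercion provenance is an output annotation, not an input
  fx_union$coerced <- NULL
  vr_union$coerced <- NULL
  again <- compile_mod_sets(fx_union, vr_union)
  expect_equal(sort(again$label), sort(sets$label))
})

test_that("fixed/variable conflicts on one site are coerced, not doubled", {
  sets <- compile_mod_sets(fixed = "TMT10plex (K)", variable = "Acetyl (K)")
  labels <- sets$label
  expect_true(any(purrr::map_lgl(seq_len(nrow(sets)), function(i) {
    "TMT10plex" %in% sets$fixed[[i]]$title &&
      nrow(sets$variable[[i]]) == 0L
  })))
  expect_true(any(purrr::map_lgl(seq_len(nrow(sets)), function(i) {
    "Acetyl" %in% sets$variable[[i]]$title
  })))
  # within any one assignment, no K carries two modification masses
  both <- which(purrr::map_lgl(seq_len(nrow(sets)), function(i) {
    nrow(sets$variable[[i]]) == 2L
  }))
  expect_length(both, 1L)
  asg <- enumerate_assignments("AKAKAA", sets, both)
  for (i in seq_len(nrow(asg))) {
    expect_false(anyDuplicated(asg$mod_positions[[i]]) > 0)
  }
})

test_that("degenerate and contradictory specifications are handled", {
  one <- compile_mod_sets(fixed = "Carbamidomethyl (C)")
  expect_equal(nrow(one), 1L)
  expect_equal(nrow(one$variable[[1]]), 0L)
  expect_error(
    compile_mod_sets(fixed = c("TMT10plex (K)", "Acetyl (K)")),
    "Contradictory"
  )
  expect_error(
    compile_mod_sets(fixed = "Oxidation (M)", variable = "Oxidation (M)"),
    "both fixed and variable"
  )
})

test_that("amino-acid lookups carry the reference masses", {
  lk <- build_aa_lookup(compile_mod_sets(variable = "Oxidation (M)"), 2)
  expect_equal(round(lk$mass[lk$key == "M"], 4), 131.0405)
  expect_equal(round(lk$mass[lk$key == "Oxidation (M)"], 4), 147.0354)

  lkc <- build_aa_lookup(compile_mod_sets(fixed = "Carbamidomethyl (C)"), 1)
  expect_equal(lkc$mass[lkc$key == "C"], 103.00919 + 57.02146,
               tolerance = 1e-4)

  empty <- build_aa_lookup(compile_mod_sets(), 1)
  expect_equal(nrow(empty), 20L)
  expect_setequal(empty$key, residue_masses()$residue)
})

test_that("every lookup mass is the residue mass plus its modifications", {
  sets <- ts_worked_sets()
  reg <- mod_registry()
  base <- setNames(residue_masses()$mass, residue_masses()$residue)
  for (i in seq_len(nrow(sets))) {
    lk <- build_aa_lookup(sets, i)
    for (r in seq_len(nrow(lk))) {
      row <- lk[r, ]
      # residue entries build on the residue mass; terminal entries are
      # additive terminal masses
      expected <- if (row$position == "Anywhere" && row$site %in% names(base))
        base[[row$site]] else 0
      if (!is.na(row$title)) {
        expected <- expected +
          reg$mono_mass[reg$title == row$title & reg$site == row$site][1]
      }
      expect_equal(row$mass, expected, tolerance = 1e-4)
    }
  }
})
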