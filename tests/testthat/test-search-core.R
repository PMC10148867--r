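test_that("primary matching is one-to-one, nearest in ppm", {
  lk <- build_aa_lookup(compile_mod_sets(), 1)
  io <- ion_series("PEPTIDEK", lk, charge = 2, satellites = FALSE)
  pk <- tibble::tibble(mz = sort(io$mz), intensity = 100)
  m <- match_primary(pk, io, tol = 20)
  expect_false(anyNA(m))                      # self-match hits everything
  expect_false(anyDuplicated(m) > 0)          # each peak used at most once

  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
  expect_true(all(is.na(match_primary(empty, io, 20))))

  # two peaks inside tolerance of one ion: the closer one wins
  theo <- tibble::tibble(channel = "b", idx = 1L, mz = 1000,
                         primary = TRUE, parent = "b")
  two <- tibble::tibble(mz = c(1000.005, 1000.012), intensity = c(1, 2))
  expect_equal(match_primary(two, theo, 20), 1L)
})

test_that("satellite intensities tally onto the matched primary", {
  # one primary at 1000 m/z with b* and b0 satellites
  ions <- tibble::tibble(
    channel = c("b", "b*", "b0"),
    idx = 1L,
    mz = c(1000, 1000 - 17.026549, 1000 - 18.010565),
    primary = c(TRUE, FALSE, FALSE),
    parent = "b"
  )
  pk <- tibble::tibble(mz = sort(ions$mz), intensity = c(100, 200, 1000))
  pm <- match_primary(pk, ions[ions$primary, ], 20)
  boosted <- tally_satellites(pk, ions, pm, 20)
  expect_equal(boosted[pk$mz == 1000], 1300)  # 1000 + 200 + 100
  expect_equal(boosted[pk$mz != 1000], pk$intensity[pk$mz != 1000])

  # no satellite peaks present: I' = I
  pk2 <- tibble::tibble(mz = 1000, intensity = 1000)
  pm2 <- match_primary(pk2, ions[ions$primary, ], 20)
  expect_equal(tally_satellites(pk2, ions, pm2, 20), 1000)

  # satellites never add matching evidence: matched count is unchanged
  expect_equal(sum(!is.na(pm)), 1L)
})

test_that("progressive enrichment reproduces the exhaustive 1/15 example", {
  # N = 6 features, K = 2 matched, matches occupy intensity ranks 1-2
  sc <- enrichment_score(
    intensity = c(60, 50, 40, 30, 20, 10),
    mz = 1:6,
    matched = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  expect_equal(sc$trace$p[2], 1 / 15, tolerance = 1e-12)
  expect_lte(sc$P, 1 / 15)
  expect_gte(sc$score, 10 * log10(15) - 1e-9)
})

test_that("hypergeometric tails equal exhaustive enumeration for N <= 12", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (k in 1:N) {
        for (x in 0:min(K, k)) {
          expect_equal(
            phyper(x - 1, K, N - K, k, lower.tail = FALSE),
            ts_hyper_tail_oracle(x, K, N, k),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})

test_that("degenerate enrichment gives probability 1 and score 0", {
  # no matches at all
  sc0 <- enrichment_score(c(5, 4, 3), 1:3, c(FALSE, FALSE, FALSE))
  expect_equal(sc0$P, 1)
  expect_equal(sc0$score, 0)
  # everything matched (K = N)
  scN <- enrichment_score(c(5, 4, 3), 1:3, c(TRUE, TRUE, TRUE))
  expect_equal(scN$P, 1)
  expect_equal(scN$score, 0)
  # empty spectrum
  expect_equal(enrichment_score(numeric(0), numeric(0), logical(0))$score, 0)
})

test_that("the score depends only on intensity ranks", {
  set.seed(41)
  intensity <- rlnorm(40, 10, 1)
  mz <- sort(runif(40, 100, 1500))
  matched <- seq_len(40) %in% sample(40, 8)
  s1 <- enrichment_score(intensity, mz, matched)
  s2 <- enrichment_score(intensity * 7.3, mz, matched)
  expect_equal(s1$score, s2$score)
  expect_equal(s1$trace$x, s2$trace$x)
})

test_that("the progressive scan is calibrated under the null", {
  # under random match placement each fixed-k step is a valid
  # (conservative) p-value, and the best-P statistic obeys the union
  # bound P(min_k p_k <= a) <= N * a across the N dependent steps
  set.seed(42)
  N <- 30L
  K <- 8L
  n_shuffle <- 10000L
  mz <- seq_len(N)
  intensity <- N:1
  res <- vapply(seq_len(n_shuffle), function(i) {
    matched <- seq_len(N) %in% sample(N, K)
    sc <- enrichment_score(intensity, mz, matched)
    c(sc$P, sc$trace$p[c(5L, 15L, 30L)])
  }, numeric(4))
  P <- res[1, ]
  for (alpha in c(0.001, 0.01, 0.05)) {
    expect_lte(mean(P <= alpha), N * alpha + 0.02)
    for (row in 2:4) {
      expect_lte(mean(res[row, ] <= alpha), alpha + 0.02)
    }
  }
  # a planted enrichment scores far beyond the null's typical best P
  planted <- enrichment_score(intensity, mz, seq_len(N) <= K)
  expect_lt(planted$P, stats::quantile(P, 0.001))
})

test_that("boosting a primary's satellites never demotes its rank", {
  set.seed(43)
  intensity <- c(100, 90, 80, 70, 60, 50)
  mz <- 1:6
  matched <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  before <- enrichment_score(intensity, mz, matched)
  boosted <- intensity
  boosted[3] <- boosted[3] + 45   # tally raises a matched feature
  after <- enrichment_score(boosted, mz, matched)
  rank_of <- function(int, j) which(order(-int, mz) == j)
  expect_lte(rank_of(boosted, 3), rank_of(intensity, 3))
  expect_gte(after$score, before$score)
})

test_that("searching a spectrum ranks its own peptide first", {
  prots <- ts_proteins()
  sim <- synth_spectra(prots, n_peptides = 8, n_noise = 0L, ppm_jitter = 0,
                       seed = 44)
  sets <- compile_mod_sets()
  cand <- digest(prots)
  asg <- build_assignments(cand, sets)
  binned <- bin_candidates(asg)
  psms <- search_spectra(sim$spectra, binned, sets)
  r1 <- psms[psms$rank == 1L, ]
  expect_equal(nrow(r1), 8L)
  expect_equal(r1$pep[order(r1$scan)], sim$truth$pep[order(sim$truth$scan)])
})

test_that("spectra below the minimum primary-match count yield no PSM", {
  lk <- build_aa_lookup(compile_mod_sets(), 1)
  sets <- compile_mod_sets()
  pep <- "LLLAAAGGGK"
  io <- ion_series(pep, lk, charge = 2, satellites = FALSE)
  # keep only 5 primary peaks; min_primary = 6 discards the PSM
  pk <- tibble::tibble(mz = sort(io$mz[1:5]), intensity = 100)
  nm <- peptide_mass(pep, lk)
  sp <- tibble::tibble(file = "f", scan = 1L, title = NA_character_,
                       premz = (nm + 2 * 1.00727646688) / 2, charge = 2L,
                       rt = NA_real_, n_peaks = 5L, peaks = list(pk))
  cand <- tibble::tibble(sequence = pep, protein_refs = list("P"),
                         missed_cleavages = 0L, is_protein_nterm = FALSE,
                         is_protein_cterm = FALSE, is_decoy = FALSE)
  binned <- bin_candidates(build_assignments(cand, sets))
  expect_equal(nrow(search_spectra(sp, binned, sets)), 0L)

  # precursor outside the configured mass range: no search at all
  sp2 <- sp
  sp2$premz <- 340
  expect_equal(nrow(search_spectra(sp2, binned, sets)), 0L)
})

test_that("targets and decoys travel an identical scoring path", {
  sets <- compile_mod_sets()
  pep <- "LLLAAAGGGK"
  lk <- build_aa_lookup(sets, 1)
  nm <- peptide_mass(pep, lk)
  io <- ion_series(pep, lk, charge = 2, satellites = FALSE)
  pk <- tibble::tibble(mz = sort(io$mz), intensity = rev(seq_along(io$mz)) * 10)
  sp <- tibble::tibble(file = "f", scan = 1L, title = NA_character_,
                       premz = (nm + 2 * 1.00727646688) / 2, charge = 2L,
                       rt = NA_real_, n_peaks = nrow(pk), peaks = list(pk))
  mk <- function(decoy) {
    cand <- tibble::tibble(sequence = pep, protein_refs = list("P"),
                           missed_cleavages = 0L, is_protein_nterm = FALSE,
                           is_protein_cterm = FALSE, is_decoy = decoy)
    bin_candidates(build_assignments(cand, sets))
  }
  as_t <- search_spectra(sp, mk(FALSE), sets)
  as_d <- search_spectra(sp, mk(TRUE), sets)
  expect_equal(as_t$score, as_d$score)
  expect_equal(as_t$n_matched, as_d$n_matched)
  expect_false(as_t$is_decoy)
  expect_true(as_d$is_decoy)
})
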