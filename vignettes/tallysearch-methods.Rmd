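---
title: "Methods: closed DDA search with satellite-ion intensity tally"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed DDA search with satellite-ion intensity tally}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tallysearch)
library(dplyr)
```

## The problem

In data-dependent acquisition (DDA) proteomics, each MS2 spectrum nominally
records the fragments of one selected peptide precursor. A closed database
search explains each spectrum by the best-matching peptide from an in-silico
digest of a protein database, within a predefined space of fixed and
variable modifications. `tallysearch` implements such a search kernel end to
end: modification-set compilation, digestion, theoretical ion generation,
two-stage spectrum matching, enrichment scoring, target-decoy FDR, site
localization and protein grouping — plus a seeded synthetic-spectrum
generator so every stage is testable without instrument data.

## Modification-set compilation

A fixed modification applies to every occurrence of its site; a variable one
may or may not occur. Naively superimposing the two on one site (say, a
fixed TMT label *and* a variable acetyl group on the same lysine) adds both
masses to one residue, which is chemically unsound. Compilation therefore
proceeds in five steps:

1. fixed modifications whose site (or terminus) also carries a variable
   modification are *coerced* into the variable category;
2. all in/out combinations of the variable pool are enumerated;
3. combinations carrying more than one N-terminal (or C-terminal)
   modification are removed — `Protein N-term` and `Any N-term` count as the
   same terminus here, since a peptide has only one physical N-terminus;
4. combinations in which a coerced site or terminus ends up carrying no
   modification at all are removed (the user declared the site always
   modified, so *some* modification must sit there; with several coerced
   Anywhere sites, all must be covered);
5. within each surviving combination, a coerced modification whose conflict
   has disappeared is reverted to fixed.

Step 4 deserves a note: the rule could also be read as "the coerced
modification itself must be present". That reading collapses the classic
TMT benchmark specification (fixed carbamidomethyl-C, TMT10plex at N-term
and K; variable protein N-terminal acetyl, N-terminal pyro-glutamate from
Q, oxidation-M, deamidation-N) to 4 combinations instead of the 12 that the
three N-terminal states (TMT, acetyl, pyro-Glu) times two oxidation states
times two deamidation states should produce, and it would forbid a lysine
from being acetylated *instead of* TMT-labelled. We therefore require only
that the coerced site carry some modification:

```{r}
sets <- compile_mod_sets(
  fixed = c("Carbamidomethyl (C)", "TMT10plex (N-term)", "TMT10plex (K)"),
  variable = c("Acetyl (Protein N-term)", "Gln->pyro-Glu (N-term = Q)",
               "Oxidation (M)", "Deamidated (N)")
)
nrow(sets)
```

Each set materializes as an amino-acid look-up: fixed masses are folded into
the residue entries, variable modifications coexist with the unmodified
entries, and attributes carry positions, coercion provenance and
neutral-loss flags:

```{r}
build_aa_lookup(compile_mod_sets(variable = "Oxidation (M)"), 2) |>
  dplyr::filter(site == "M")
```

## Digestion, decoys and candidate dispatch

Digestion uses trypsin/P (cleavage C-terminal to K/R, no proline exception)
at full, semi or no enzymatic specificity. Defaults follow common TMT
practice: up to 4 missed cleavages, peptide length 7–40, precursor mass
700–4500 Da. Peptides starting at position 2 behind an initiator methionine
keep the protein N-terminal flag so that protein N-terminal acetylation
stays reachable on clipped N-termini — the engine would otherwise never
place `Acetyl (Protein N-term)` on tryptic data. Candidates containing
B/J/O/U/X/Z are dropped (no defined monoisotopic mass) with a logged count.

Decoys are full sequence reversals, tagged `rev_` by default. For entrapment
evaluation a low-homology foreign database is appended to the target
database *before* reversal, so decoys cover the combined space.

A candidate is dispatched to a modification set only if it can express every
variable modification of that set (a set with variable oxidation-M only
retains M-containing sequences, a pyro-Glu set only peptides starting with
Q, a protein N-terminal acetyl set only protein N-terminal peptides). Site
assignments are enumerated under the permutation caps — at most 5 variably
modified positions, at most 3 positions per modification, at most 64
assignments per candidate. The truncation order is "fewest modified
positions, then leftmost positions": deterministic, and it keeps the
simplest explanations, including the unmodified assignment, ahead of exotic
ones. Assignments are binned by neutral mass in constant-ppm bins of twice
the precursor tolerance, so any tolerance window touches at most two bins.

## Two-stage matching and the intensity tally

Primary evidence is the singly charged b/y series. Satellites are the
water/ammonia losses (b⁰/y⁰ at −18.010565 Da, b*/y* at −17.026549 Da),
modification-specific neutral losses (phosphate, −97.9769 Da, from
phosphorylated S/T), and — for precursors of charge ≥ 3 — the doubly
charged variants of all of the above. Loss channels are gated on fragment
content: ammonia loss needs R/K/N/Q in the fragment, water loss S/T/E/D,
a modification loss the modified residue itself. These gates are the
standard chemical readings and are deliberately conservative; they are
configured in code rather than exposed as options.

Matching is two-stage. Primaries are matched first, nearest-in-ppm within
±20 ppm, one peak per ion and one ion per peak. Only when at least
`min_primary` (default 6) primaries match does the satellite stage run: each
matched satellite's intensity is *added to its parent primary's peak
intensity*,

$$I'_{b_i} = I_{b_i} + I_{b_i^*} + I_{b_i^0} + I_{b_i^2} + I_{b_i^{*2}} + I_{b_i^{02}},$$

and symmetrically for y. Satellites never count as independent matching
evidence — they only re-rank the primaries they support. This is the
package's central design: satellite matches are frequent in noisy spectra,
so counting them as evidence inflates scores, but their intensity is real
signal that should make a true primary rank higher.

## Progressive hypergeometric enrichment

After the tally, the N retained peaks (top-100 by intensity, ties to lower
m/z) are ranked by boosted intensity. With K of them matched by primaries,
the scan walks k = 1..N and asks at each prefix: out of k draws from N
features containing K matched ones, how surprising are the x_k matched
features seen so far? That is the upper-tail hypergeometric probability

$$p_k = P(X \ge x_k), \qquad X \sim \mathrm{Hypergeom}(N, K, k),$$

and the peptide score is $-10\log_{10} P$ with $P = \min_k p_k$. If K = 0 or
K = N there is nothing to enrich and the score is 0. The parameterization
(N = retained features, K = matched primaries, scan ordered by boosted
intensity) is a design choice of this package; it rewards matches that
concentrate among the most intense features, which is what the tally is
designed to amplify.

Two honest caveats, both covered by tests:

* $P$ is the minimum of ~N dependent tail probabilities, so it is *not*
  uniformly distributed under the null. Each fixed-k step is a valid
  conservative p-value and the minimum obeys the Bonferroni bound
  $P(\min_k p_k \le \alpha) \le N\alpha$; the score is a ranking statistic,
  not a calibrated p-value, and FDR control comes from the decoys, not
  from $P$.
* equal scores between candidate peptides are broken by smaller absolute
  precursor error, then by set index — determinism over elegance.

## FDR, localization, protein groups

Rank-1 PSMs passing the post-search filters (≥ 6 matched primaries, ±10 ppm
precursor error) enter target-decoy FDR. The score-to-q mapping is
calibrated in the *subclass* of results with the most rank-1 PSMs — keyed
here by modification-set index, since modification complexity shifts score
distributions — and transferred to all subclasses by step-function lookup
(no interpolation; conservative and deterministic). With no decoys in the
calibration subclass all q-values are 0 with a warning; on desk-scale
synthetic runs this is the expected small-n outcome.

Site localization uses a counting statistic rather than a binomial model:
among the primary ions that discriminate two placements of one modification
(present in one theoretical series but not the other), count the matched
ones per placement, and report $n_A / (n_A + n_B)$. Counts 2:1 give 0.67;
any n:0 gives 1 — the 1:0 and 2:0 cases are deliberately equivalent, since
zero counter-evidence is zero counter-evidence. 0:0 is undefined and is
reported as uniform with a flag.

Protein grouping builds the sparse peptide-by-protein incidence matrix,
notes that unique peptides cannot affect grouping (their rows touch one
column), and clusters the shared-peptide block by the dichotomous distance
"0 if two proteins share any peptide else 1" with single-link agglomeration
cut just above 0 — i.e. connected components of the shared-peptide graph.
Within each group, essential proteins come from greedy set cover (largest
uncovered contribution first; ties to more total peptides, then accession).
Greedy is the field's standard choice and is optimal on nested isoform-style
peptide sets, but it is not guaranteed to equal the exact minimum cover on
arbitrary incidence structures — the test suite compares against an exact
solver on small instances and documents where greedy is one protein larger.

## The synthetic-data generator

`synth_spectra()` emulates what the scorer actually consumes: per planted
peptide a spectrum of singly charged primary b/y ions with log-normal
intensities (meanlog log(1e5), sdlog 0.6 — typical HCD dynamic range; y
drawn 1.5× brighter than b, as C-terminal fragments usually dominate in
tryptic HCD data), satellites at 0.3× their parent's intensity for a random
half of the primaries, 30 uniform noise peaks, and Gaussian 3-ppm m/z jitter
on every peak and precursor (comfortably inside the ±20/±10 ppm windows, as
on a well-calibrated Orbitrap). All randomness flows from one seed; the
written MGF is byte-identical across runs.

What it does *not* emulate — and hence what passing tests do not show about
real data: chimeric spectra from co-isolated precursors, isotope envelopes,
charge-reduced species, intensity-dependent m/z error, missing fragments
from poor fragmentation, and retention-time structure. The generator
validates the engine's bookkeeping and statistics, not instrument realism.

Default problem sizes used throughout the tests (5 proteins, 10–50 spectra,
5 entrapment seeds) keep any single check within seconds on one core while
still exercising every stage; they are the scale at which the grouping,
FDR-transfer and tally mechanisms are exactly verifiable against oracles.

## Numerical choices and limitations

* All masses are monoisotopic, built from one element table (including
  ¹³C/¹⁵N labels); modification masses validate against their compositions
  to 1e-4 Da.
* Tolerance boundaries are inclusive (`|error| <= tol`); the denominator of
  a ppm error is always the theoretical mass.
* Tie-breaks are fixed everywhere (ranking: ascending m/z; peak selection:
  lower index; truncation: fewest/leftmost modifications) so reruns are
  byte-identical.
* Spectra missing a charge line default to 2+ with a warning.
* MS2 peaks are matched as converted — no deisotoping or charge
  deconvolution.
* Open/mass-offset searches, spectral libraries, rescoring against
  retention time or predicted spectra, and isobaric reporter quantitation
  are out of scope.
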