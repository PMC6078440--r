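---
title: "Methods: solution-NMR characterization of multidomain proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solution-NMR characterization of multidomain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solnmr)
```

## Scope and scientific setting

`solnmr` implements the analysis chain used to characterize a secreted
multidomain protein in solution: two disulfide-rich folded domains
joined by a long flexible linker, with a dynamic N-terminal tail that
carries a short receptor-binding motif. The motivating system is the
Wnt-pathway inhibitor Dkk4 (mature protein, residues 19–224 numbered
from the initiator methionine): a first cysteine-rich domain (CRD1,
roughly residues 41–97), a flexible linker (98–139), a second
cysteine-rich domain (CRD2, 140–219) that mediates high-affinity
receptor binding, and flexible termini. The package answers four
questions about such a protein:

1. **Which parts are folded?** Combined amide secondary chemical
   shifts against a random-coil reference, segmented into structured
   and flexible regions, corroborated by heteronuclear
   ¹⁵N{¹H}-NOE measurements.
2. **Where does a partner bind?** Minimal-shift chemical-shift
   perturbation (CSP) mapping of the assigned free state against the
   *unassigned* bound-state spectrum, with lost-peak detection
   identifying a tightly bound domain.
3. **How precise is the solution structure?** RMSD-to-mean statistics
   of an NMR ensemble and segment-correspondence RMSDs between
   homologous folds.
4. **How tight is the interaction?** One-site steady-state analysis of
   biosensor (BLI) binding curves.

A synthetic-data generator stands in for the study's raw spectra; it
produces every input with a machine-readable ground truth so the whole
chain is testable end to end.

## Random-coil reference shifts

Secondary shifts require a sequence-specific random-coil baseline. The
package ships a versioned coefficient table
(`inst/extdata/random_coil_amide_coeffs.tsv`) holding, per amino acid,
intrinsic ¹H^N and ¹⁵N^H shifts at 298.15 K, neighbor corrections for
positions *i*−2…*i*+2, temperature coefficients (ppb/K), and
Henderson–Hasselbalch protonation shifts for Asp/Glu/His. The
prediction for residue *i* is

δ_rc(i) = δ₀(aa_i) + Σ_k corr(aa_{i+k}, k) + tc(aa_i)·(T − 298.15)/1000 + pH term,

with terminal residues using only the neighbors that exist and
prolines reported missing (no backbone amide). The design follows the
widely used neighbor-corrected web-server scheme; because no server
version from the study period can be pinned down, the table is an
embedded, versioned coefficient set of our own rather than a copy of
any specific release — its provenance is the file header, and all
downstream analyses depend only on its *structure* (intrinsic +
neighbor + temperature + pH terms), which the tests verify by direct
lookup-and-sum oracles. Cysteines are treated as oxidized (cystine) by
default, appropriate for fully disulfide-bonded proteins; a
`cys_reduced` flag switches to the thiol values.

## Secondary shifts and segmentation

The combined amide shift is `sqrt(d_HN^2 + (d_N * alpha)^2)` with
α = 0.2 compensating for the wider ¹⁵N ppm range; the same scalar
metric is used everywhere a ¹H/¹⁵N distance is needed (secondary
shifts, CSP, peak matching), with a single shared α.

The field's papers state the *conclusion* of segmentation ("close to
random coil" versus dispersed) but not a numeric rule. The package's
rule, chosen once and exposed as parameters: a residue is structured
when the running median over a 5-residue window of its combined
secondary shift exceeds 0.1 ppm. The median window makes the call
robust to single-residue outliers; 0.1 ppm sits well above the
random-coil prediction error for flexible residues and well below the
dispersion of folded-domain amides. Missing residues (prolines,
unassigned) inherit the nearer neighbor's label (tie → preceding), so
contiguous domains are not fragmented by the ~13% of residues a real
assignment typically lacks; segments shorter than `min_len = 4` are
merged into the longer flanking segment. All three parameters are
user-configurable; on emulated data the defaults recover the planted
regions to within ±2 residues.

## Heteronuclear NOE

The ¹⁵N{¹H}-NOE is computed from paired peak heights recorded with
(*I_s*) and without (*I_o*) proton presaturation. Two conventions are
in circulation: the intensity *ratio* *I_s*/*I_o* (rigid limit ≈ 0.8
at high field) and the *difference* form (*I_s* − *I_o*)/*I_o*
(= ratio − 1). Figures in this field typically plot values near 0.8
for folded domains, i.e. the ratio convention, while methods sections
sometimes print the difference formula; the package implements both (`convention = "ratio"` is the default,
`"difference"` is the printed-formula form), reports which one was
used, and defaults the flexibility cutoff to 0.6 in ratio units
(−0.4 in difference units). Uncertainties are first-order propagation
of the spectral noise, `|I_s/I_o|·sqrt((n_s/I_s)^2 + (n_o/I_o)^2)`;
records with |*I_o*| below 3× the noise floor are flagged unreliable.
Pairing of the two spectra with the assignment table is by nearest
position in the combined-shift metric within a configurable radius;
ambiguous pairings (two candidates within the radius) are flagged,
never silently resolved.

## Minimal-shift CSP mapping and lost peaks

When a complex is large and tightly bound, the bound-state spectrum
cannot be assigned; the minimal-shift approach compares each assigned
free-state amide against *all* bound-state peaks and records the
smallest combined shift. This is by construction a lower bound on the
true perturbation — the package's tests assert exactly that
(`min_shift ≤` planted truth, and equality with an exhaustive
double-loop oracle).

Signals of a domain locked into a slowly tumbling complex broaden
beyond detection. `detect_lost_peaks()` flags a residue lost when no
bound peak lies within a combined-shift radius of its free position
(optionally also requiring a minimum peak height). The default radius
is 0.25 ppm — a domain-scale choice reflecting that real data support
domain-level, not per-residue, loss calls. Contiguous lost runs of at
least 5 residues become "tight interaction site" calls; isolated
losses are reported but not interpreted; observable residues with
minimal shift above 0.04 ppm (the package's reading of "slightly
affected") are labeled weak/transient perturbations.

**Exactness on synthetic data.** Exact lost-set recovery requires the
generator's peak-separation guarantee and the detection radius to be
mutually consistent: a lost residue's free position must be at least
*radius* away from every *surviving* bound peak, and
*radius + max displacement* away from peaks that the bound state
displaces. Both folded domains resonate in the same spectral region,
so clearances much larger than ~0.15 ppm between ~80 lost-site peaks
and ~110 surviving peaks cannot be packed at realistic dispersions.
The generator therefore enforces 0.05 ppm separation globally,
0.15 ppm between lost-site and surviving peaks, and 0.25 ppm around
peaks that will be displaced — and the planted-truth tests run
detection at radius 0.15 ppm, where recovery is provably exact. On
real data the 0.25 ppm default with height floors is the appropriate,
more conservative setting; the tests' exactness says nothing about
overlap-ridden real spectra, which is precisely why the package
reports match counts and flags rather than hard assignments.

## Restraint bookkeeping

Structure-calculation restraint manifests are reproduced by expanding
chemistry-level bonds into distance limits with the standard
CYANA-style conventions: each disulfide yields six limits
(Sγ–Sγ 2.0/2.1 Å lower/upper; Cβ–Sγ 3.0/3.1 Å for both orderings),
each backbone hydrogen bond two upper limits (H^N–O 2.3 Å, N–O
3.3 Å). The built-in CRD1 lists (five disulfides: C41–C53, C47–C63,
C66–C80, C73–C85, C79–C90; twelve slow-exchange hydrogen bonds)
expand to 30 and 24 limits, which with 606 NOE upper limits and 90
torsion restraints total a 750-restraint manifest. The counts are the
testable surface; the distance values are documented defaults.

## Ensemble geometry

Superposition is the closed-form Kabsch SVD solution with reflections
excluded; tests verify it against both a numerical optimizer over
rotations and the `bio3d` reference implementation. RMSD-to-mean uses
the standard iterative procedure: superpose all models on the first
over the fit selection, form mean coordinates, re-superpose onto the
mean, and iterate to a 10⁻⁶ Å fixed point; per-model RMSDs to the
converged mean are reported over an independently chosen report
selection. The backbone atom set is N/Cα/C′ (carbonyl O excluded), the
common NMR-ensemble convention, with `backbone_o` and `heavy`
alternatives. For an ensemble built as template + iid Gaussian jitter
σ per coordinate, the expected RMSD-to-mean is σ·√3·√((m−1)/m) for m
models; the estimator reproduces this within 5%, and reproduces
0.90 Å backbone / 1.40 Å heavy-atom precision on a stand-in ensemble
calibrated to those values by construction.

Inter-structure homology RMSDs pair residues sequentially within
equal-length segment lists (the format in which such comparisons are
published); unequal lists require an explicit user-supplied pairing
rather than a guessed alignment — structure-based alignment discovery
is out of scope. Model 1 of each ensemble is the default comparison
model. Reproducing the published values for the deposited ensembles
requires downloading public PDB entries; the test suite validates the
estimators on constructed geometry only, and
`scripts/reproduce_deposited_stats.R` performs the networked
reproduction when internet access is available.

## Binding isotherms

Steady-state biosensor responses follow Req = Rmax·C/(KD + C).
`fit_one_site()` runs Levenberg–Marquardt least squares with
concentrations normalized by their maximum (making the result
invariant to the unit of input), initialized at Rmax₀ = 1.1×max
response and KD₀ = the interpolated half-saturation concentration,
with 10⁻¹⁰ convergence tolerances. Standard errors come from the
curvature of the residual surface. Noiseless synthetic curves invert
to 6 significant figures; with 0.02 nm Gaussian noise on a
1–1000 nM series the median of 500 replicate fits recovers a 64 nM
ground truth within 10% (the check `scripts/acceptance.R` reruns). Fits whose KD estimate exceeds 10× the
largest measured concentration are flagged poorly constrained. Rmax
may be fixed per sensor (`fix_Rmax`) since published fits do not
always float it; no nonspecific-binding term is included by default.

## The synthetic-data generator

`make_dkk4_like()` fixes the study architecture: 206 residues numbered
19–224; flexible 19–40, 98–139, 220–224; structured 41–97 and
140–219; the whole second domain as a "lost"-mode binding site; six
N-terminal residues (19, 25, 27, 29, 30, 32 — around the receptor
motif) as "shifted"-mode weak contacts, chosen once so their
random-coil base positions are mutually ≥ 0.30 ppm apart. The
architecture is identical for every seed; seeds move only the noise.

Free-state shifts are random-coil predictions (308 K, pH 6.5) plus
Gaussian dispersion: σ_H = 0.03 / σ_N = 0.15 ppm for flexible
residues (assignment-noise scale) and σ_H = 0.35 / σ_N = 3.0 ppm for
structured residues (folded-domain dispersion scale). Heteronuclear
NOE ratios are drawn from N(0.8, 0.05) for structured and N(0.2, 0.1)
for flexible residues; binding curves add N(0, σ) response noise;
coordinate ensembles add iid Gaussian jitter to a template and round
to PDB precision (0.001 Å) so written files round-trip exactly.

What the generator does **not** emulate: peak overlap and lineshapes,
spectral artifacts, systematic (non-Gaussian) shift changes, partial
broadening, chemical exchange, or assignment errors. Passing tests
therefore demonstrate the correctness of the estimators under clean,
separable conditions — not robustness to the pathologies of real
spectra, which the configurable radii, floors and flags are there to
manage.

## Problem sizes and determinism

The test suite works at the native problem scale of the study system
(a 206-residue chain, 10–20-model ensembles, 500-replicate fit
simulations) and runs in well under a minute. All generators are
fully reproducible from (parameters, seed); pipeline outputs carry no
timestamps, so reruns with the same configuration are byte-identical.

## Interfaces

Every user-facing function takes a data frame first and returns a
tibble, so analyses chain with the pipe; fitted objects provide
broom-style `tidy()`/`glance()` and `autoplot()` methods. The three
workflow drivers — `run_free_state()`, `run_csp()`, `run_affinity()` —
orchestrate the chain and optionally write deterministic TSV/JSON
reports. The package is function-first: the workflow drivers and
scripts are the entry points, and a shell wrapper would add nothing a
two-line Rscript does not.

## Known limitations

- The random-coil coefficient set is an embedded, versioned table;
  absolute secondary-shift values depend on it, though segmentation
  (which thresholds a robust statistic) is insensitive to small
  coefficient changes.
- Minimal-shift mapping is a lower bound; weak perturbations below
  the bound cannot be distinguished from none.
- Segment correspondences are inputs, not discovered alignments.
- Lost-peak detection assumes losses manifest as absent peaks, not as
  partially broadened ones; height floors approximate the latter.
- Titration-series CSP fitting (fast-exchange KD from shift
  trajectories) is out of scope: the motivating complexes are in slow
  exchange.
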