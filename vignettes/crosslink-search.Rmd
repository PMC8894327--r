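---
title: "Cross-link search for alkyl-bromide ncAA chemistry: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link search for alkyl-bromide ncAA chemistry: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecxms)
```

## The chemistry and the mass model

A genetically encoded amino acid carrying an electrophilic alkyl bromide is
placed at a chosen position of a bait protein. A nucleophilic side chain of
a bound partner — Cys, Asp, Glu, His, Lys, Ser, Thr or Tyr — attacks the
electrophilic carbon and expels bromide. The covalent conjugate of the two
proteolytic peptides therefore weighs

$$ M \;=\; m(\text{bait peptide incl. ncAA}) + m(\text{prey peptide}) - m(\mathrm{HBr}), $$

with $m(\mathrm{HBr}) \approx 79.92616$ Da (monoisotopic ¹H + ⁷⁹Br). All
masses in the package are monoisotopic and derived from elemental
compositions, so the residue table, the water and proton constants, and
modification deltas are mutually consistent by construction; there is no
average-mass mode because the intended instruments are high-resolution
Orbitrap-class machines.

Two configuration values deserve comment:

* **`ncaa_mass`** — the residue mass of the incorporated ncAA. This is
  deliberately a *required* run parameter rather than a built-in constant:
  the engine is generic over alkyl-halide ncAAs, and the user reads the
  value off the structure of the particular ncAA used. The synthetic
  generator defaults to 269.005128 Da, the residue mass of composition
  C₁₁H₁₂BrNO₂ (an O-(2-bromoethyl)-tyrosine-type residue), a realistic
  choice for this chemistry.
* **`leaving_group`** — defaults to HBr; other halides can be configured.

Carbamidomethylation of cysteine (+57.02146 Da, composition C₂H₃NO) is
searched as a variable modification, since the alkylation step in sample
preparation is efficient but not guaranteed on every Cys. A modified Cys
cannot simultaneously be a cross-link site, and the ncAA position can never
carry the modification — both exclusions are enforced at candidate
expansion. Variable-modification expansion is capped at 3 per peptide to
bound combinatorics.

## Digestion

Trypsin is modelled as cleaving after K/R but not before P; the
proline-suppression rule is the dominant convention and can be switched off
(`proline_rule = FALSE`) since published parameter lists rarely state it.
Up to 3 missed cleavages are searched. Peptides are bounded to 5–60 residues
and 500–6000 Da by default — standard search practice; both bounds are
arguments so tests (and unusual experiments) can disable them. The
sequential workflow in which Lys-C releases tag-bearing fragments that are
re-enriched and then digested by trypsin is modelled by `double_digest()`
with an arbitrary retention predicate. The ncAA position is never treated
as a cleavage site, even when the canonical letter it replaced is K or R:
the incorporated residue is not a protease substrate.

Coordinates are 1-based inclusive everywhere, matching the field's residue
naming (e.g. a site written E391 is position 391 of the protein).

## The two-chain fragment model and the score

HCD spectra of conjugates show b/y ladders of both chains. Any fragment
whose residue span covers its chain's link position (the ncAA on the bait,
the reactive site on the prey) carries the entire partner chain minus the
leaving group; its complementary fragment does not. This bookkeeping
guarantees $b_k + y_{n-k} = M$ for every bond of either chain, which the
test suite asserts to $10^{-6}$ Da. Fragments are generated at charges 1–2;
precursors are searched at the acquisition charges 3–7.

No public description exists of the scoring used by the reference software
for this chemistry, so the package defines its own, deliberately simple
score: theoretical ions are matched to peaks greedily and uniquely within
the fragment tolerance (ties broken by smaller ppm error; a peak explains at
most one ion, across both chains), and each chain contributes
$-\log_{10} P(X \ge k)$ where $X \sim \mathrm{Binomial}(N, p)$, $N$ is the
chain's theoretical ion count, $k$ its matched count, and $p$ a per-ion
random-match probability estimated from the spectrum's peak density. The
tail is computed on the log scale because confident matches of long chains
underflow double precision. The chain scores are summed, so a reportable
PSM must carry evidence on *both* chains; PSMs with zero matched fragments
on either chain are discarded outright (configurable). This prevents an
abundant linear peptide from masquerading as a cross-link on the strength
of one chain alone.

Site localization scores every reactive-residue placement of a pair and
reports the best site together with `site_delta_score`, the margin to the
best alternative. A zero margin is reported as an explicit ambiguous set
and such peptides are tallied in a separate "ambiguous" reactivity bucket
rather than being attributed (or fractionally split) to a residue.

Determinism is a design requirement: equal scores are broken by smaller
absolute precursor error and then lexicographic peptide order, and repeated
runs of identical inputs produce byte-identical outputs.

Precursor isotope-error correction is off by default — the conservative
reading when an acquisition description does not state it.

## Target-decoy FDR

Decoys are whole reversed proteins appended to the database — exactly the
scheme named in standard practice for this workflow; peptide-level
pseudo-reversal is not used. With rank-1 PSMs, the estimate at score $s$ is
$\widehat{\mathrm{FDR}}(s) = D(s) / \max(1, T(s))$ and q-values are its
running minimum. The +1 decoy correction is available behind a flag but off
by default, since the target parameterization states only "5% FDR at the
PSM level" and the uncorrected estimator centres the realized false
discovery proportion on the nominal level (the +1 variant is strictly
conservative, which the suite also asserts). Unique cross-linked peptides
are keyed on (bait peptide, prey peptide, site, modifications) — the most
granular reading of "a cross-linked peptide"; coarser keys can be obtained
by re-grouping the tidy output.

## What the simulator emulates — and what it does not

The generator stands in for a deposited raw dataset and reproduces its
statistical structure:

* random proteomes (uniform residue composition by default, configurable
  frequencies), protein lengths uniform on 150–450 residues;
* one bait construct whose ncAA site is placed inside a fully-tryptic
  peptide of searchable length;
* implanted links drawn from a **Cys-dominant reactivity prior**
  (C = 0.7, the other seven nucleophiles uniform at 0.3/7), mirroring the
  observed dominance of cysteine in this chemistry;
* spectra at precursor charges 3–7 (weighted toward 3–4), Gaussian ppm
  errors (2 ppm precursor, 4 ppm fragment — inside the 10/20 ppm search
  tolerances), 10% fragment dropout, Poisson(30) uniform noise peaks,
  exponential intensities with mild rank decay, and a 40% background of
  linear-peptide spectra;
* an optional **entrapment fraction**: shuffled proteins that never receive
  implanted links, giving a false-positive oracle that is independent of
  the reversed-decoy machinery used for estimation.

Everything is integer-seeded; byte-identical outputs under a fixed seed are
part of the test contract. The intensity model is documented rather than
fitted: only relative matching matters to the binomial score. The simulator
does **not** model chromatography or retention time, isotope envelopes,
profile-mode peaks, co-isolation chimeras, or real intensity structure —
so passing benchmarks demonstrate correctness of the search machinery and
calibration of the FDR under the stated noise model, not performance on
real instrument data.

Benchmark problem sizes used by the suite and the acceptance script were
chosen as desk-scale conditions: the noiseless round trip uses 200 proteins
and 150 links; the FDR-calibration experiment uses 10 seeds of 60 proteins,
60 links and a 50% entrapment database (the calibration check pools false
discoveries over seeds and compares them with the central 95% binomial band
around the 5% target); reactivity recovery uses 120 links over 60 proteins.

## Numerical and degenerate-input choices

* Mass window lookups use a sorted index with `findInterval`; the exact ppm
  predicate is re-applied to every hit, so index lookup and linear scan are
  provably identical (tested against a brute-force oracle).
* Empty spectra score 0 with no matches; empty candidate sets, empty FDR
  inputs and zero-row writers all pass through as empty, never as errors.
* Motif windows are ±15 residues, `-`-padded at protein termini, with the
  site at position 16 of 31. Position-frequency columns count only non-pad
  observations; log-odds use a pseudocount of 1 per residue per column to
  avoid log 0, against background frequencies computed from the full prey
  database. Motif *discovery* itself is delegated to external tools via the
  padded-stripped FASTA export.
* The distance bound written to restraint files defaults to 10 Å — a short
  side-chain-to-side-chain conjugate plus backbone flexibility — and is a
  plain argument, since docking protocols differ.

## Known limitations

* Loop-links, mono-links (hydrolyzed ncAA dead ends) and intra-protein
  links are out of scope; the engine searches inter-chain conjugates only.
* Score parity with any specific published search engine is not attempted;
  acceptance rests on synthetic recovery and FDR calibration.
* mzML support is read-only and requires the `mzR` package; MGF is the
  reference interchange format.
* Protein-level FDR and posterior error probabilities are not implemented.
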