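---
title: "Methods: annotating a coral alpha-carbonic anhydrase repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating a coral alpha-carbonic anhydrase repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crucarb)
```

## The problem

Alpha-carbonic anhydrases (alpha-CAs) catalyze CO2 + H2O <-> HCO3- + H+ and
are recruited across metazoans into calcium carbonate biomineralization.
Characterizing a coral's alpha-CA repertoire from assembled transcripts is a
stereotyped analysis: find the ORFs, profile the proteins, classify their
subcellular localization, read their active sites in a common coordinate
frame, identify acatalytic family members (CARPs), quantify tissue-specific
expression by qPCR, and summarize pairwise divergence. Each step is simple;
the value of the package is doing all of them reproducibly, with a
synthetic-data generator that emits ground truth so the whole chain is
testable offline.

## CAII numbering

Every active-site statement is made in the residue numbering of human
carbonic anhydrase II (CAII, UniProt P00918), the field's universal frame:
the zinc-binding triad His94/His96/His119, the proton shuttle His64, and the
gatekeepers Glu106/Thr199. The 260-residue chain ships as a fixture together
with an explicit position index; "CAII numbering" is defined by that fixture,
not recomputed, and its six catalytic positions are asserted on every load.
As a sanity anchor, the bundled chain's computed physicochemistry (pI 6.87,
MW 29.26 kDa) matches the publicly known values for P00918.

Queries are placed into this frame by one pairwise Needleman-Wunsch global
alignment each (BLOSUM62, affine gaps, open 11 / extend 1, end gaps
penalized), rather than by a multiple alignment: a pairwise map is
deterministic, cheap, and sufficient for reading six canonical columns. The
alignment backend is cross-checked in the test suite against an independent
brute-force affine-gap dynamic program on random peptides.

A record is called a CARP when at least one triad slot is not histidine
(an unaligned, i.e. deleted, slot also destroys zinc coordination and counts
as non-His). The disulfide-bridge cysteine pairs are called by column
homology at two bundled anchor pairs in CAII coordinates — (23, 203) for the
canonical extracellular bridge and (99, 227) for the cnidarian-specific
secreted-cluster bridge. These anchors are package estimates (the canonical
pair from the known disulfide of secreted human alpha-CAs, the second from
its offsets relative to the active-site anchors in secreted coral CAs); both
are injectable parameters, and bridge calls use column homology only, never
3D proximity.

## Localization heuristics

The three detectors are declared hydropathy heuristics over the
Kyte-Doolittle (KD) scale, not re-implementations of the neural-network
servers a study would normally call; a side channel accepts a table of
precomputed external predictions that overrides them. All thresholds are
exposed in `localization_params()`:

* **Signal peptide** — tripartite, von-Heijne-style: an n-region of at most
  12 residues with net charge (K+R-D-E) >= 0, followed by the first 7-residue
  window with mean KD >= 1.6 fully inside residues 1-45, followed by the
  first downstream position (<= 45) satisfying the (-3,-1) small-residue
  rule (position -1 in A/G/S/C/T, position -3 additionally allowing V). All
  three elements are required.
* **Transmembrane** — greedy left-to-right maximal windows of >= 19 residues
  with mean KD >= 1.6 in the mature chain. Because the criterion is a window
  mean, a segment may absorb a few polar flank residues around a strongly
  hydrophobic core; segments are maximal and non-overlapping.
* **GPI anchor** — positive iff the C-terminal 25 residues contain an
  >= 11-residue window with mean KD >= 1.0 and a small-residue omega-site
  candidate (A/C/D/G/N/S) lies 15-35 residues from the C-terminus; the most
  C-terminal candidate is reported.

Classification applies the secretory logic: GPI + signal peptide =>
membrane-bound (GPI); TM + signal peptide => membrane-bound (TM); signal
peptide only => secreted; none => cytosolic. A TM or GPI signature without a
signal peptide is incoherent for this family and is classified cytosolic
with a warning flag.

## Physicochemistry

Molecular weights are sums of average (not monoisotopic) residue masses plus
one water, the scale used by the standard web calculators. Isoelectric
points solve `Q(pH) = 0` by bisection on [0, 14] to an interval of 1e-7
(hence |Q| < 1e-4 at the root), with Henderson-Hasselbalch terms over
D/E/C/Y/H/K/R and both termini under the Bjellqvist pKa table: side-chain
pKs 4.05/4.45/9.0/10.0/5.98/10.0/12.0, residue-specific N-terminal
alpha-amino pKs, and a residue-specific C-terminal carboxyl pK (4.55 when
the chain ends in Asp, 4.75 for Glu, 3.55 otherwise). The table is
injectable because pI is pKa-set-dependent. One consequence worth knowing:
with the residue-specific C-terminal pK, appending an acidic residue to an
acidic peptide can *raise* the computed pI slightly; monotonicity of pI in
charged residues is guaranteed only under position-independent terminal pKs,
and the test suite asserts it exactly there.

ORF calling scans the forward strand only (inputs are oriented assembled
transcripts) for the longest ATG-initiated, in-frame-stop-terminated frame,
ties broken by smallest start. Reported ORF lengths include the stop codon,
so protein length is `orf_bp/3 - 1`; the published characteristics table of
the six coral isozymes obeys this law in five of six rows, and the package
flags the sixth (row 1: 1032 bp vs 356 aa, where 1032/3 - 1 = 343) as a
printed-table anomaly rather than "fixing" it. Glycosylation is reported
only as the N-X-S/T (X != P) sequon count and phospho-acceptors only as
S/T/Y inventories — declared motif proxies, not predictor reproductions.

## Codon evolution of the triad

Histidine is encoded by CAC/CAT. For any codon the package enumerates all
nine single-nucleotide neighbors with transition/transversion class (every
codon has exactly 3 transitions and 6 transversions among its neighbors),
and computes minimal mutational paths to any residue by breadth-first search
over the 64-codon graph — equivalently the minimal hamming distance to the
residue's codon family, which the tests assert. From CAC, seven distinct
non-His residues are reachable in one substitution (D, L, N, P, Q, R, Y);
the recurrent CARP triplet R-H-Q lies one substitution per slot from the
His family. For each CARP the report reads the actual codons at the three
triad slots from the CDS, gives the distance from the nearer of CAC/CAT and
the transition/transversion composition of those changes, and flags the
strict R-H-Q and the permissive R/H/Y - H/R - Q/H signatures. The ancestral
state is always taken as the His family itself, not reconstructed
phylogenetically.

## qPCR model

Efficiencies come from 10-fold dilution standard curves by OLS of Ct on
log10(dilution), `E = 10^(-1/slope)`. Technical replicates are collapsed by
arithmetic mean (switchable to median) before any ratio. Two quantities are
computed per gene: within-fraction expression relative to a housekeeping
reference, `E_t^(-Ct_t) / E_r^(-Ct_r)` per biological replicate (the
efficiency-adjusted 2^-dCt; with both efficiencies 2 and equal Ct it is 1,
one extra target cycle halves it), and the Pfaffl between-fraction ratio
`E_t^(dCt_t) / E_r^(dCt_r)` with dCt = control - sample, paired by
biological replicate. The two are algebraically consistent — the Pfaffl
ratio equals the ratio of within-fraction relative expressions replicate by
replicate — and at E = 2 the Pfaffl ratio reduces to the classic 2^-ddCt;
both identities are fuzz-tested. Housekeeping candidates are ranked by the
coefficient of variation of per-fraction mean Ct. Group comparisons are the
classical equal-variance Student t (two groups) and one-way ANOVA (more),
with no multiple-testing correction.

## Distances and trees

Pairwise protein divergence is the p-distance (mismatches over compared
sites, excluding any column with a gap in either sequence — complete
deletion at the pair level), optionally Poisson-corrected as
`d = -ln(1 - p)`, which is undefined at saturation (p = 1) and always >= p.
For prealigned input an optional site-coverage filter removes columns below
a coverage fraction (e.g. 0.95) before comparison. Trees are Saitou-Nei
neighbor joining; on additive matrices the tree reproduces the input path
lengths to 1e-9 (asserted), negative branch-length estimates are clamped to
zero with a flag, and output is Newick. NJ here is a distance sanity-check
surrogate, not a replacement for likelihood or Bayesian inference, which is
out of scope.

## The synthetic generator

`generate_ca_cds()` produces records whose ground truth is known by
construction, on the CAII backbone: canonical positions (triad, shuttle,
gatekeepers, the QSPID motif region, bridge columns) are planted per
configuration and protected; 30% of the remaining positions (the default
rate, chosen to sit near the within-family divergence of coral alpha-CA
paralogs) are substituted, drawing from a polar/charged alphabet so random
drift cannot fabricate the hydrophobic signatures the localization
detectors look for; class-specific elements are appended in provably
detectable form (a 16-residue signal peptide with its cleavage site fixed by
the (-3,-1) rule, a 21-residue Ile transmembrane tail with its omega band
sanitized so the GPI detector cannot fire, a GSA + 18-Leu GPI tail whose
omega site is the most C-terminal small residue). Proteins are
back-translated with uniform synonymous codon choice (planted triad codons
excepted) and framed ATG..stop inside pyrimidine-only UTR noise, which by
construction cannot contain an upstream ATG. `synthetic_study_set()` fixes a
six-record configuration mirroring the structure of the red-coral
repertoire: one cytosolic catalytic isozyme, one secreted CARP (Y-R-H triad,
Pro in place of the Thr gatekeeper, conserved shuttle, both bridges), three
further secreted isozymes, one GPI-anchored one, with shuttle residues
K/H/N/S/R/H.

`generate_qpcr()` draws Ct values from the standard-curve model
`Ct = intercept + slope * log10(quantity)` with Gaussian cycle noise
(default sd 0.15 cycles, a typical technical-replicate scatter), for a
three-fraction, 3 biological x 3 technical design, plus per-gene dilution
series — matching the design of the emulated experiment.

What the generator does **not** emulate: realistic coral codon usage or GC
content, indel variation (substitution-only mutation keeps query-reference
alignments colinear, which is why triad recovery is exact), assembly errors,
between-biological-replicate variance components, or primer-specific
amplification artifacts. Green closed-loop tests therefore demonstrate that
the pipeline's logic is correct and deterministic, not that the heuristics
would match external predictors on real coral sequences; for real data the
external-prediction override exists.

## Numerical and design choices

* Bisection (pI): interval 1e-7; degenerate inputs (empty, illegal
  residues) are errors; X is ignored as non-ionizable in pI but is an error
  in MW where mass would be undefined.
* Alignment ties: the backend's deterministic trace; alignment *scores* are
  oracle-checked, and an internal deletion's gap may slide within an
  equal-score window without affecting canonical-column reads.
* NJ ties: the library's deterministic implementation.
* Problem sizes in the shipped checks (200 localization records, 25-100
  qPCR seed replicates, 50 alignment oracle pairs) keep the whole suite
  within a few minutes while leaving Monte Carlo margins far from the
  asserted thresholds.
* The six-isozyme emulation is used wherever the deposited GenBank
  transcripts (KU557743-KU557748) would be needed; those sequences are not
  redistributed, and checks that require the *published* per-isozyme values
  (exact MWs, pIs, substitution positions) are present in the suite but
  fail informatively without them rather than being silently skipped.

## Known limitations

Localization heuristics are intentionally crude stand-ins with declared
thresholds; cleavage sites on real sequences will differ from dedicated
predictors. Bridge anchor columns are homology estimates, not derived from
the original pair coordinates. Mitochondrial targeting is not modelled
(intracellular isozymes are reported simply as cytosolic). The codon report
describes mutational accessibility from the His family, not reconstructed
history.
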