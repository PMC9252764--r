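---
title: "Untrained prediction of protein stability change from sequence profiles and structure"
author: "ddgpred authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untrained prediction of protein stability change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgpred)
```

## The problem and the model

A single amino-acid substitution changes a protein's unfolding free
energy by ΔΔG = ΔG~variant~ − ΔG~wild-type~; under this convention
negative values destabilize. `ddgpred` estimates ΔΔG without any fitted
parameters. The only protein-specific input is the sequence profile
`prof(a, j)`: the frequency of amino acid `a` among the homologs aligned
at query position `j`. The profile modulates every score, which is why
alignment quality matters more to this method than anything else.

For a substitution `w → m` at position `j` the package computes three
sequence scores — a BLOSUM62 conservation difference, a pairwise contact
potential difference summed over the ±2 sequence window, and a
Kyte–Doolittle hydropathy difference — and, when a structure is
available, a fourth score over the residues within 5 Å of the site.
Each score has the form "profile-weighted (variant term − wild-type
term)", which makes every score *exactly* anti-symmetric: scoring
`m → w` under the same profile flips the sign bit-for-bit, and `w → w`
is exactly zero. This is a biophysical requirement (the reverse variant
must have opposite ΔΔG), and the test suite asserts it end-to-end over
thousands of randomized cases.

The weighted combinations

ΔΔG[SEQ] = 0.30·s~Bl~ + 0.43·s~Sk~ + 0.27·s~Hp~,
ΔΔG[3D] = (1.1 − ac)·(0.20·s~Bl~ + 0.29·s~Sk~ + 0.18·s~Hp~ + 0.33·s~BV~)

use weights fixed a priori and normalized to 1; the weighted sum is
reported directly in kcal/mol with no further calibration constant. The
`(1.1 − ac)` factor encodes that substitutions at solvent-exposed sites
tend to perturb stability less: at relative accessibility `ac = 0.1` the
factor is exactly 1, at full exposure it shrinks the prediction to one
tenth. Because `ac` is computed on the wild-type structure only (the
mutant structure is never modelled), the modulation is the one place
where anti-symmetry can be lost in 3D mode; the unmodulated score sum
still negates exactly, and the tests check precisely that split.

Multi-site variants are predicted per site and combined as
`max(s) + min(s) − mean(s)`: the extreme per-site effects are taken to
dominate the joint effect, and their sum is centred on the mean. For one
site this is the identity, for two sites the mean.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window` | 2 | positions | half-width of the sequence-neighbour window (up to 4 neighbours, site excluded, clipped at termini) |
| `radius` | 5.0 | Å | spatial contact radius; a residue is in the environment if any heavy-atom pair is within it |
| `decimals` | 1 | — | display rounding; a prediction that rounds to 0.0 is classed *neutral*, otherwise the sign decides *increase*/*decrease* |
| `probe` | 1.4 | Å | solvent probe radius for accessibility |
| `n_points` | 256 | — | quadrature points per atom in the accessibility routine |
| `gaps_in_denominator` | `FALSE` | — | alternative profile normalization (see below) |

The "2-residue window" is implemented as ±2 positions around the site
because that reading preserves a symmetric local context and degrades
gracefully at the termini; it is a single argument, so the 2-total
reading can be recovered with `window = 1`.

## Numerical and design choices

**Profile.** Frequencies are raw counts over observed *standard*
residues: gaps and nonstandard codes are excluded from numerator and
denominator, so each column with at least one observation sums to 1.
The alternative — counting gaps in the denominator, which shrinks
columns in gappy regions — is available as `gaps_in_denominator = TRUE`.
No pseudocounts and no redundancy weighting are applied: the method is
deliberately untrained, and the profile is meant to be exactly the
observed frequencies. Columns with no observation at all fall back to a
one-hot column on the query residue. Positions are 1-based in the query,
matching variant strings like `T7W`.

**Hydropathy score.** Among the anti-symmetric forms expressible with
the profile and the scale, the endpoint difference
`prof(m,j)K(m) − prof(w,j)K(w)` is used: it uses only the two residues
actually exchanged, weighting each by how often it is observed at the
site.

**Neighbour weighting.** The sequence-window and spatial scores weight
each neighbour by the *neighbour's own* profile column, since both
scores measure interaction of the exchanged residue with its (fixed)
neighbours.

**Contact rule.** "Within 5 Å of the variant site" is implemented as
minimum heavy-atom–to–heavy-atom distance ≤ radius. This is robust to
missing side-chain atoms and is the common convention for contact
potentials; a Cα/Cβ-center rule was considered and rejected because toy
and real structures with incomplete side chains would silently change
neighbour sets.

**Accessibility.** SASA is computed numerically in the package
(Shrake–Rupley-style: each heavy atom inflated by the 1.4 Å probe and
sampled with a deterministic Fibonacci sphere; points inside any other
inflated atom are discarded), then divided by the residue type's
maximum accessibility (Rost & Sander 1994 constants, `MAX_ACC`) and
clamped to [0, 1]. The quadrature is deterministic, so repeated runs are
byte-identical. 256 points per atom resolve `ac` to well under 0.01,
far below the 0.05-scale effect the modulation factor needs.

**Structure parsing.** One chain is extracted with author numbering and
insertion codes preserved; first model only; alternate locations resolve
to the highest occupancy (ties to altloc `A`); hydrogens and waters are
dropped; nonstandard residues (e.g. MSE) are kept for geometry but never
scored. The chain is mapped onto the profile's query by exact contiguous
match with overhang allowed; ambiguous or mismatching placements are
errors rather than guesses, and environment residues that fall outside
the query are skipped with a warning.

**Parameter tables.** BLOSUM62 and the Kyte–Doolittle scale are
transcriptions of the published tables (cross-checked in the test suite
against independent copies in `Biostrings` and `seqinr`). The two
pairwise contact potentials are bundled as deterministic *synthetic*
surrogates, constructed from a hydrophobicity outer product plus a fixed
symmetric perturbation and labelled as such in their file headers; the
bundled files are pinned by checksum. Every property the package
guarantees (table symmetry, score anti-symmetry, identity zeros, the
combination algebra) is independent of the entries; absolute ΔΔG values
in the structure/neighbour terms, however, reflect the surrogate scales,
so users wanting the original potentials can drop replacement files with
the same 20×20 BLAST-style layout into `inst/extdata/matrices/`.

**Ties and degenerate inputs.** `round()` (half-to-even) is used for
display; exactly 0.0 after rounding is *neutral* with no extra epsilon
band. A single-residue protein has an empty neighbour window and scores
`s_Sk = 0`; an isolated residue has an empty 5 Å environment and scores
`s_BV = 0`. Reverse-variant predictions reuse the given (wild-type)
profile — recomputing a profile from a mutant alignment would break
exact anti-symmetry and is intentionally not done.

## The synthetic-data generator

`make_msa()` draws, per column, a residue distribution from a Dirichlet
prior concentrated on the query residue (`conservation` pseudo-counts on
the query, 0.5 elsewhere) and samples homolog rows i.i.d. from it;
`conservation` therefore sweeps columns from near-uniform to one-hot,
and `gap_rate` adds alignment gaps. `make_structure()` emits toy PDB
chains with engineered properties: a fully exposed residue, a residue
pair whose minimum heavy-atom distance is solved by bisection to the
requested value within 0.01 Å, a centre residue buried under a
quasi-uniform shell, and an insertion-coded numbering case (27, 27A,
28). Defaults (50-row, 40-column alignments at moderate conservation;
shells of 26 residues) are sized like small real alignments and tight
first coordination shells.

What the fixtures emulate is *controlled geometry and column
statistics*, not real proteins: columns are independent, rows are
unrelated by phylogeny, and toy chains have idealized, sterically naive
geometry. Passing tests therefore demonstrate that the implementation
computes the stated formulas with the stated invariants — not that the
predictor reaches any particular accuracy on experimental ΔΔG data,
which requires real alignments (e.g. from hhblits against a clustered
UniProt release) and curated measurement sets. The test and acceptance
runs use hundreds of alignments of 12–40 columns and structures of 1–27
residues, sizes at which every suite completes in about a minute.

## Known limitations

- The mutant structure is never modelled; structure mode reads the
  wild-type environment only (partial anti-symmetry loss via the
  accessibility factor, documented above).
- Substitutions only — no indels, no HGVS parsing.
- Sequence mode without an alignment (one-hot profile) runs but loses
  all evolutionary signal; the CLI warns loudly.
- mmCIF input and fetching structures over the network are out of scope;
  an external DSSP-style accessibility backend is an interface stub
  (`--sasa internal` is the only built-in).
- The bundled contact potentials are labelled synthetic surrogates (see
  above).

## Package shape

The package is tidyverse-shaped where the data are naturally tabular:
`predict_ddg()` returns a tibble (one row per variant, a `components`
list-column with per-site breakdowns) that pipes into `dplyr` and has an
`autoplot()` method, and profiles export to tibbles/TSV. The MSA,
profile and structure containers are lightweight S3 objects rather than
data frames, because a 20×L frequency matrix and an atom-coordinate set
are matrix-shaped; no `tidy()`/`glance()` methods exist since an
untrained method has no fitted object to summarize.
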