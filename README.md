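# ddgpred

`ddgpred` predicts the change in protein unfolding free energy caused by
amino-acid substitutions,

ΔΔG = ΔG<sub>variant</sub> − ΔG<sub>wild-type</sub> (kcal/mol, negative = destabilizing),

for single and multi-site variants, from sequence alone or from sequence
plus structure. It is aimed at structural bioinformaticians who want a
fast, fully *untrained* baseline predictor: every parameter is a fixed,
published (or bundled) table, and nothing is fitted to experimental ΔΔG
data, so the method doubles as an honest benchmark for trained predictors.

## The model

All scores are weighted by the sequence profile `prof(a, j)` — the
frequency of amino acid `a` at query position `j` in a multiple sequence
alignment of homologs. For a substitution `w → m` at position `j`:

- **Conservation**: `s_Bl = Σ_a prof(a,j) · [B(a,m) − B(a,w)]` with `B` the
  BLOSUM62 matrix.
- **Sequence neighbours**: `s_Sk = Σ_{k: 0<|k−j|≤2} Σ_a prof(a,k) ·
  [P_Sk(a,m) − P_Sk(a,w)]`, a pairwise contact potential over a ±2 sequence
  window.
- **Hydropathy**: `s_Hp = prof(m,j)·K(m) − prof(w,j)·K(w)` with `K` the
  Kyte–Doolittle scale.
- **Spatial contacts** (structure mode): `s_BV = Σ_{r∈env(j)} Σ_a
  prof(a,pos(r)) · [P_BV(a,m) − P_BV(a,w)]`, where `env(j)` is every
  residue with a heavy atom within 5 Å of the variant site in the
  wild-type structure.

These are combined with fixed weights:

    ΔΔG[SEQ] = 0.30·s_Bl + 0.43·s_Sk + 0.27·s_Hp
    ΔΔG[3D]  = (1.1 − ac)·(0.20·s_Bl + 0.29·s_Sk + 0.18·s_Hp + 0.33·s_BV)

with `ac` the relative solvent accessibility of the site, so exposed
positions are damped. Every score is anti-symmetric by construction:
the reverse substitution `m → w` under the same profile receives exactly
the opposite prediction. Multi-site variants are combined as
`max(s) + min(s) − mean(s)` over the per-site predictions.

Note: the two pairwise contact potentials are shipped as clearly labelled
deterministic *synthetic* surrogates (see the file headers under
`inst/extdata/matrices/`); all structural properties of the method are
independent of their entries.

## Worked example

```r
library(ddgpred)

msa  <- make_msa(fixture_spec(seed = 42, n_sequences = 50, length = 40,
                              conservation = 5))     # or read_msa("aln.a3m")
prof <- build_profile(msa)
pred <- predict_ddg(c("D5A", "D5A,V13G"), prof)
prediction_table(pred, ascii = TRUE)
#>   VARIANT N_SITES  S_BL    S_SK S_HP DDG_SEQ DDG_SEQ_FULL EFFECT_SEQ
#>       D5A       1 -3.36 -0.1831 1.61    -0.7   -0.6520416          -
#>  D5A,V13G       2    NA      NA   NA    -1.0   -1.0013217          -
```

`D5A` loses a conserved aspartate (`s_Bl = −3.36` in half-bit units) and
gains hydropathy (`s_Hp = +1.61`); the weighted sum, −0.7 kcal/mol, is a
predicted destabilization (`-`). The two-site variant's prediction is the
max + min − mean combination of its per-site predictions (for two sites,
their mean); the per-site breakdown is in `pred$components[[2]]`.

With a structure (here a toy buried site generated by the fixture module):

```r
pdb <- tempfile(fileext = ".pdb")
make_structure(fixture_spec(seed = 1, geometry = "buried", n_shell = 26), pdb)
model <- read_structure(pdb, "A")
prof  <- single_sequence_profile(structure_sequence(model))
prediction_table(predict_ddg("A1W", prof, model = model, mode = "both"),
                 ascii = TRUE)
#>  VARIANT N_SITES S_BL  S_SK S_HP  S_BV REL_ACC DDG_SEQ DDG_SEQ_FULL EFFECT_SEQ
#>      A1W       1   -7 -0.18 -1.8 0.286       0    -2.7      -2.6634          -
#>  DDG_3D DDG_3D_FULL EFFECT_3D
#>    -1.9   -1.850002         -
```

`REL_ACC = 0` says the site is fully buried, so the `(1.1 − ac)` factor
leaves the structure-based prediction at full strength.

A command-line interface with the same three modes is installed as
`exec/ddgpred`:

```sh
ddgpred --mode both --pdb protein.pdb --chain A --msa aln.a3m \
        --variants "T7W; T7W,K6L" --out predictions.tsv
```

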