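---
title: "Contact prediction from MSA covariation with a multivariate Gaussian model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact prediction from MSA covariation with a multivariate Gaussian model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gausscontact)
```

## The problem

Residues that are close in a protein structure tend to covary across the
protein's family: when one member of an interacting pair mutates, the
change is often accommodated by a compensating mutation in the partner,
and strongly covarying pairs also concentrate in slowly evolving protein
cores. Either way, covariation observed between two columns of a multiple
sequence alignment (MSA) is evidence of spatial proximity. The catch is
transitivity: if position $i$ contacts $j$ and $j$ contacts $k$, the
columns $i$ and $k$ correlate even when those residues never touch.
Separating *direct* from *indirect* covariation is the defining problem of
direct coupling analysis (DCA), and `gausscontact` solves it with the
simplest statistical machine that can: a multivariate Gaussian model whose
*precision* (inverse covariance) matrix encodes conditional, rather than
marginal, dependence.

## The model

An MSA has $N$ aligned sequences of length $L$ over the 20 amino acids
plus a gap symbol. An *encoding* maps each amino acid to a vector of $s$
real components; the gap always maps to the zero vector. Concatenating
the per-position vectors turns sequence $S_n$ into a numeric row $X_n$ of
length $Ls$. Three encoding families are built in:

* **binary20** ($s = 20$): amino acid $i$ maps to the indicator vector
  $r_i(k) = \delta_{ik}$. This is the encoding of the classical Gaussian
  DCA programs.
* **1-D property scales** ($s = 1$): each amino acid is a single real
  value taken from an AAindex1-style physicochemical scale. The final
  contact ranking is invariant under affine changes of scale
  $v \mapsto av + b$ (the covariance chain only ever sees centered,
  scale-propagated quantities), so scales need no standardisation.
* **substitution-matrix PCA** ($s = k$): each amino acid's row of a
  BLOSUM matrix is a point in 20 dimensions; amino acids get their
  coordinates along the top $k$ principal components of that point cloud.

Given per-sequence weights $w_n$ (below), the model uses the weighted
moments
$$\bar X = \frac{\sum_n w_n X_n}{\sum_n w_n}, \qquad
  \bar C = \frac{\sum_n w_n (X_n - \bar X)^T (X_n - \bar X)}{\sum_n w_n},$$
which are the maximum-likelihood Gaussian parameters in the uniform-weight
case. $\bar C$ is singular in practice — with 20-dimensional one-hot
vectors every gap-free position block annihilates the all-ones direction
exactly, and rare residues are simply absent — so it is blended with a
prior built from a uniform amino-acid composition: with $\bar r$ and $C_r$
the mean and population covariance of the 20 encoding vectors,
$\mu_P = (\bar r, \ldots, \bar r)$ and $C_P = I_L \otimes C_r$,
$$C_M = \lambda C_P + (1-\lambda)\bar C
        + \lambda(1-\lambda)(\bar X - \mu_P)^T(\bar X - \mu_P).$$
The coupling matrix is the precision matrix $J = C_M^{-1}$. Its
off-diagonal $s \times s$ blocks $J(i,j)$ quantify the *conditional*
dependence of positions $i$ and $j$ given all others, which is what
discounts transitive correlation.

Each block is reduced to a scalar score by double-centering (subtract row
and column means, add the grand mean — the zero-sum gauge) and summing
squared entries, the squared Frobenius norm in that gauge. The centering
matters: the raw norm is not invariant under the additive row/column
shifts ("gauge freedom") that leave the model's probabilities unchanged,
while the centered score is. The score diagonal is zero by construction —
the self-block $J(i,i)$ is a within-position curvature term, not a pair
coupling, and for nearly singular models its inverse-ridge magnitude would
otherwise dominate the row sums of the correction that follows. The
$L \times L$ score matrix then receives the average product correction
(APC), $P^{APC}_{ij} = P_{ij} - \tfrac{\text{row}_i\,\text{col}_j}{\text{total}}$,
which removes separable per-column signal strength (conservation and
phylogenetic effects). Finally pairs with $j - i > 4$ are ranked by
decreasing corrected score and the top 200 are reported.

## Sequence reweighting

Sequences in real alignments are phylogenetically dependent. Each
sequence is down-weighted by the size of its neighbourhood: $m_n$ counts
the sequences (itself included) sharing at least $rL$ identical non-gap
residues with sequence $n$, the weight is $w_n = 1/m_n$, and
$M_{\text{eff}} = \sum_n w_n$ is the effective number of independent
sequences. Duplicating every sequence leaves $M_{\text{eff}}$ unchanged.
The cutoff $r$ defaults to the fixed value $0.8$; an automatic mode sets
$r$ inversely proportional to the mean pairwise identity,
$r = \mathrm{clip}(0.32 / \overline{\mathrm{id}},\ 0.5,\ 0.9)$. Only the
proportionality is principled; the constant $0.32$ and the clip bounds are
this package's documented defaults, chosen so that alignments of typical
diversity (mean identity near 0.4) land at the fixed default, and they are
configurable and recorded with every run.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.8 | prior weight in $C_M$; 0 = data only, 1 = prior only. 0.8 is the established optimum for the binary encoding; lower-dimensional encodings tolerate (and PCA embeddings of growing $k$ increasingly need) larger $\lambda$. |
| `r` | 0.8 | identity cutoff defining weight neighbourhoods |
| `max_gap_fraction` | 0.9 | sequences with strictly more gaps are dropped before modelling |
| `min_separation` | 4 | only pairs with $j-i>4$ are ranked (short-range contacts are trivial) |
| `top_k` | 200 | length of the reported prediction list |
| contact threshold | 8 Å | minimum heavy-atom distance below which two residues count as in contact (strict `<`) |

The $\lambda = 1$ endpoint is an exact null model: $C_M = C_P$ is
block-diagonal, every inter-position coupling block is exactly zero, and
all pair scores vanish — prior information alone predicts nothing, which
the tests assert literally.

## Numerical choices

* **Inversion and ridging.** $C_M$ is inverted by Cholesky
  factorization. If the factorization fails, a ridge $\varepsilon I$ is
  added, with $\varepsilon$ taken from a geometric ladder starting at
  $10^{-8} \times \mathrm{mean}(\mathrm{diag}\,C_M)$ and growing tenfold
  up to $10^{-2}$ of that scale; the $\varepsilon$ actually used is stored
  in the model and in the run metadata. The relative scaling keeps the
  affine-invariance property of 1-D encodings intact. A `ridge = "none"`
  policy turns singularity into an error instead.
* **PCA conventions.** Matrix rows are centered; the eigendecomposition
  uses the $1/20$ population covariance (rankings are invariant to this
  global scale); components are ordered by descending eigenvalue; each
  component's sign is fixed by making its largest-magnitude loading
  positive, so embeddings are bit-reproducible. Coordinates are raw
  projections, not whitened.
* **Ties.** Equal scores are ranked lexicographically by $(i, j)$. Ties
  are measure-zero in floating-point pipelines but ubiquitous in
  degenerate cases (the $\lambda = 1$ null model ranks purely
  lexicographically), and a deterministic rule keeps runs reproducible.
* **APC degeneracy.** An all-zero score matrix would divide by zero in
  the APC; it is returned unchanged with a warning.
* **Symbol mapping.** Inputs are uppercased; `.` and `-` become the gap;
  the ambiguity codes B, Z, X, J, O, U also become gaps (zero vectors),
  which loses less information than guessing a residue and keeps
  encodings exact. How the original datasets handled non-standard codes
  is not documented anywhere we know of; this mapping is a package
  decision.
* **Column-to-residue mapping.** For evaluation against a structure,
  column $p$ maps to the $p$-th non-gap residue of the *first* sequence
  of the alignment (the convention of benchmark alignments built around a
  reference structure); columns where the reference is gapped are
  excluded from scoring. An explicit mapping vector overrides this.
* **Short prediction lists.** AUC200 sums $\mathrm{PPV}(k)$ over the
  available ranks only and flags the result; nothing is extrapolated.

## The synthetic test bed

Real benchmark families require large external downloads, so the package
ships a generator whose output exercises every pipeline stage with known
ground truth. Background cells are i.i.d. from a uniform composition over
the 20 amino acids (uniform is the natural default here: it matches the
model's prior assumption of no compositional structure and leaves planted
signal as the only non-noise feature). Each planted pair $(i, j)$ is, with
probability `coupling`, drawn *jointly* — both columns receive the same
background draw (a matched-type pair table) — and otherwise
independently. Chained triples $(i, j, k)$ couple $i$ and $k$ to the
middle column only, so the $i$–$k$ correlation is purely indirect; a
precision-matrix method must rank both direct pairs above it, and the
tests require exactly that. Gaps overwrite cells i.i.d., and a configurable
fraction of rows are exact copies of earlier rows to exercise the
reweighting. A single seed drives every draw.

The standard study conditions used by the tests and the acceptance script
are $L = 60$, $N = 2000$, eight disjoint planted pairs at separation 5,
coupling 0.8, gap rate 0.05, binary encoding, $\lambda = 0.8$, twenty
replicates; the chained preset uses $L = 30$, $N = 1000$, one triple at
positions (5, 12, 19). These sizes are large enough for the planted
signal to dominate sampling noise yet small enough to run a full
20-replicate study in well under a minute.

What the generator does *not* emulate: phylogenetic tree structure (its
duplicates are exact copies, not correlated descendants), realistic
substitution processes, position-specific conservation profiles, or the
entropic gradients that make APC essential on real data. Passing the
recovery tests therefore demonstrates that the machinery — moments,
prior, inversion, gauge-corrected scoring, APC, ranking — is correct, not
that any particular accuracy will be achieved on real protein families,
where performance depends strongly on $M_{\text{eff}}$ and alignment
quality.

## Worked example

```{r example}
spec <- synthetic_spec(L = 60, N = 2000,
                       planted_pairs = spaced_pairs(60, 8),
                       coupling = 0.8, gap_rate = 0.05, seed = 42)
sim <- generate_msa(spec)
run <- predict_contacts(sim$msa, lambda = 0.8)
run
evaluate_contacts(run, contact_map(sim$truth$planted_pairs, n_residues = 60))
```

All eight planted pairs surface as the top eight predictions; the AUC200
then decays harmonically because only eight true pairs exist among 200
reported ones.

```{r sweep}
truth <- contact_map(sim$truth$planted_pairs, n_residues = 60)
sweep_lambda(sim$msa, truth, lambdas = c(0.2, 0.8, 1))
```

## Known limitations

* Dense covariance algebra: memory and time scale as $(Ls)^2$ and
  $(Ls)^3$; with $s = 20$ and $L$ up to a few hundred this is a desktop
  workload, but long alignments with high-dimensional encodings will not
  fit.
* The bundled substitution matrices are those distributed with
  Biostrings (BLOSUM45/50/62/80/100); other matrices are accepted as
  square text files via `read_substitution_matrix()`.
* The PDB reader intentionally handles only single-chain ATOM records
  (first model, first alternate location); anything more exotic should be
  reduced to a contact-list TSV first.
* The automatic identity cutoff is a documented heuristic; only the
  fixed cutoff reproduces a fully specified, deterministic weighting.
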