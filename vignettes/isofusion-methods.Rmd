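---
title: "Isoform function prediction by multi-omics fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform function prediction by multi-omics fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Alternative splicing lets one gene produce several isoforms with distinct
biological functions, but functional annotation (Gene Ontology terms) is
recorded almost exclusively at the gene level. `isofusion` predicts GO term
memberships for individual isoforms by integrating three omics views — isoform
expression profiles across samples, isoform sequence features, and the
protein–protein interaction (PPI) network of their genes — under the
multiple-instance assumption that links the two annotation levels: *if a gene
carries a function, at least one of its isoforms does*. Operationally, every
gene-level comparison in the package uses the within-gene maximum of isoform
scores.

## Data model

For `n` isoforms of `g` genes the package holds three aligned matrices:
`X1` (`n × e`, nonnegative expression over `e` samples), `X2` (`n × s` real
sequence features; `s` is free — embeddings are computed upstream), and `X3`
(`n × g` binary), where `X3[i, m] = 1` when the gene of isoform `i` interacts
with gene `m`. PPIs exist between genes, so all isoforms of a gene share one
`X3` row; the resolution of interactions *between isoforms* is exactly what
the generation module adds. Labels are a binary `g × T` gene-by-term matrix.
GO terms outside a size window (defaults 5–1000 annotated genes) are removed
as too specific or too general. Annotations are taken as given; no ontology
propagation is applied before filtering (a deliberate choice — whether labels
should first be propagated up the hierarchy is a data-preparation question we
leave upstream).

Train/test splits operate on genes, never isoforms: isoforms of one gene, and
genes of one homologous group (supplied as a two-column table), always land on
the same side, since homologs share sequence and would leak test information
into training. The implementation merges both constraints into connected
components and assigns whole components greedily after a seeded shuffle, so
requested fractions are met to within one component. A validation subset
(default 10% of training genes) is carved out the same way.

## Generating isoform–isoform interactions

Gene-level PPIs are refined into isoform-level interactions (IIIs) by a
multi-input multi-output autoencoder trained with cycle-consistency and
adversarial objectives. Three input layers (one per modality) feed shared
encoder layers down to a bottleneck; a mirrored decoder emits three outputs.
The expression and sequence heads reconstruct their inputs; the interaction
head is widened from `g` genes to `n` isoforms so each isoform's decoded state
yields a predicted interaction score against every other isoform.

The losses are:

* **Generation.** A PPI between genes `a` and `b` asserts that at least one
  isoform of `a` interacts with at least one isoform of `b`. For every ordered
  pair of distinct genes, the maximum generated score over the corresponding
  isoform-pair block is compared to the binary PPI with binary cross-entropy,
  averaged over gene pairs. The subgradient of the block maximum flows to the
  argmax entry only.
* **Reconstruction.** Mean squared error on the expression and sequence heads.
* **Cycle consistency.** The three outputs are fed back through the model and
  must reproduce the original inputs under an L1 penalty. The interaction
  output is `n`-dimensional while the PPI input layer expects `g` columns, so
  interaction rows are max-pooled over each gene's isoform columns before
  re-entering the model — the natural inverse of the gene-to-isoform widening.
  The same pooling defines the III-side cycle target.
* **Auxiliary objectives.** Three additional copies of the loss each zero-mask
  one modality's input and regenerate it from the other two (all shared
  parameters are common; only input/output layers are modality-specific).
  Masking is zero-filling, so a masked modality is exactly equivalent to
  feeding zeros, and perturbing a masked input provably changes nothing.
* **Adversarial.** A three-layer discriminator separates real PPI rows from
  generated interaction rows pooled to gene columns (pooling makes the two
  distributions dimensionally comparable). The discriminator minimizes the
  usual minimax objective; the generator receives the non-saturating
  `-log D(fake)` form, which avoids the early-training stall of the literal
  minimax gradient while leaving the reported minimax value unchanged.

The final III matrix is the elementwise maximum of the generated matrix and
its transpose with a zero diagonal (idempotent, symmetric by construction).

**Design note — the interaction head.** A head with a free `n`-column dense
layer turned out to be structurally unable to resolve isoforms of a
multi-isoform partner gene: its columns only ever receive gene-block-level
supervision through the pairwise maximum, so which column of a partner gene
carries an interaction is unidentifiable, and recovery of held-out
interactions stalls near chance within positive blocks. The head is therefore
bilinear: isoform `i`'s decoded hidden state is projected into bottleneck
space and scored against the *encoder bottleneck embedding* of each candidate
partner `j`, plus a per-partner bias, through a sigmoid. Partner identity is
then determined by the partner's own features, as in inner-product decoders
for graph link prediction, while every stated contract (output dimension `n`,
sigmoid range, all loss definitions) is unchanged.

Training alternates one discriminator and one autoencoder Adam step per
epoch. Early stopping monitors the pairwise generation loss on a held-out 10%
of genes; because that estimate is noisy at desk scale, the default patience
is long (100 epochs) and the best-validation parameters are restored at the
end. Defaults: shared widths (512, 256), bottleneck 128, discriminator
(256, 64), loss weights λ = (1, 1, 1) across generation/reconstruction/cycle,
adversarial weight 0.1, learning rate 1e-3. The λ weights and architecture
are exposed in `ae_config()`; the adversarial weight is kept a modest fraction
of the primary objective so the discriminator regularizes rather than drives
generation.

## Omics-specific graph convolutional classifiers

Each view `X` (`n × d`) induces a graph: cosine similarities `s_ij` between
feature rows, thresholded at the `(n·a)`-th largest off-diagonal value so each
node keeps `a` edges on average (`a = 10` by default; ties at the threshold
are all retained, which keeps the adjacency symmetric; all-zero rows get zero
similarity by convention). With `Ā = A + I` and its degree matrix `P̄`, the
propagation operator is `Ã = P̄^{-1/2} Ā P̄^{-1/2}`. Three convolution layers
`H_{l+1} = σ(Ã H_l W_l)` (leaky rectifier; dropout 0.5 between layers during
training) feed a dense layer with elementwise sigmoid, giving per-isoform term
probabilities.

Supervision is gene-level: isoform scores are max-pooled per gene and scored
with a class-weighted binary cross-entropy, where each term's positive weight
is the inverse of the positive-gene proportion among training genes (and
analogously for negatives); per-term losses are means over genes, summed over
terms, so terms are comparable regardless of `T`. Terms with no positive
training gene are dropped from that view's loss with a warning. Training is
transductive: the graph spans all isoforms, but only training-gene labels
enter the gradient (shuffling test labels leaves every training-side quantity
bitwise unchanged — this is asserted in the test suite). Early stopping uses
the validation-gene loss.

For the III view, the symmetrized interaction matrix serves as both the
feature matrix and the source of its similarity graph, matching how the other
views derive their graphs from their own features.

## Cross-omics integration

Per isoform, the three predicted label distributions form the tensor
`C[e1, e2, e3] = ŷ¹(e1) · ŷ²(e2) · ŷ³(e3)`, flattened row-major (`T³`
entries, third index fastest) and classified by a one-hidden-layer network
(width `⌈T³/2⌉`, sigmoid output) that learns cross-view label correlations.
Tensors are built per isoform block, so peak memory scales as `O(batch · T³)`
— the practical ceiling on `T` for this integration style.

Joint training starts by pretraining each view's classifier, then alternates:
with the integrator fixed, each classifier takes a step on its own loss; with
the classifiers fixed, the integrator takes a step on the class-weighted loss
of its fused, gene-pooled predictions. By default classifier updates do not
receive integrator gradients (the alternation text underdetermines this; a
`couple_vcdn` flag enables the coupled reading, implemented through the tensor
product on the same autodiff tape). The integrator trains on training genes'
isoforms and predicts for all. Early stopping monitors the validation
integration loss with patience 20.

One master seed fans out deterministically to per-stage seeds (split,
autoencoder, each classifier, integrator), so every stage is independently
reproducible and two identical runs produce bitwise-identical outputs.

## Numerical core

No deep-learning framework is used: all networks run on a small reverse-mode
automatic-differentiation tape over dense matrices written for this package
(~20 operators, including group-maximum pooling with argmax subgradients and
the row-wise triple Kronecker product). Every operator's gradient is checked
against central differences in the test suite, including through the
non-smooth gene-pair-max and gene-pool paths. Optimization is Adam
(`lr = 1e-3`, β = (0.9, 0.999)). Probabilities entering logarithms are clipped
to `[1e-7, 1 - 1e-7]`; ties in maxima resolve to the first index; AUC uses
midpoint ranks for ties and AUPRC uses step-wise (non-interpolated)
precision–recall summation, which avoids the optimism of trapezoidal
interpolation.

## The synthetic benchmark

Real multi-omics compendia for this task need external databases and days of
training, so validation uses a generator that plants exactly the structure
the method assumes. Latent functional modules drive everything: each isoform
carries 1–3 of `n_latent` modules; expression rows are module-profile means
scaled by an effect size (`signal`, default 3) plus Gaussian noise (default
sd 1), clipped at zero to stay TPM-like; sequence rows are module prototypes
plus noise; isoform pairs sharing a module interact with probability
`iii_density` (default 0.8) against a uniform background of one tenth that;
GO terms map to modules, isoform labels are module memberships, gene labels
their OR, and gene-level PPIs the OR over isoform-pair blocks — precisely the
generation loss's assumption, and verified exactly in tests. About half the
genes are single-isoform (as in real transcriptomes), and 10% of genes are
cloned into two-gene homolog groups with correlated features to exercise the
split constraints. The reference fixture uses 150 base genes, 8 terms, 30
samples and 40 sequence features.

What the generator does *not* emulate: count-based sequencing noise,
batch structure, the heavy-tailed degree distribution and sparsity of real
interactomes, GO's hierarchical dependency between terms, and realistic
module overlap. Passing the planted-recovery tests therefore demonstrates
that the machinery recovers the signal it models, not that it attains any
particular accuracy on real data.

## Validation quantities and problem sizes

`scripts/acceptance.R` regenerates the fixture, runs the full pipeline plus
the three single-view ablations at fixture-scale settings (autoencoder widths
64/32 for 400 epochs; classifiers at their 300-epoch defaults; 60 alternating
epochs), and reports: AUROC of generated interactions against the planted
network on test-gene isoform pairs; median gene-level test AUC of each single
view and of the integrated model; median test AUPRC of the integrated model;
and the within-gene isoform-resolution AUC against the planted isoform truth
and against a within-gene-shuffled copy of it. The shuffle control isolates
multiple-instance resolution: gene-pooled metrics are blind to within-gene
ordering, so the within-gene statistic is the one that must collapse to 0.5
under shuffling. At ceiling performance the integrated model and the best
single view can tie to within rounding on an 8-term median, so the
integration-dominance check carries a small tie allowance (0.005 AUC)
established from reference runs at seeds 7–9.

The test suite runs the same recovery checks at seeds 7, 8 and 9, plus split
integrity over 100 random seeds, bitwise determinism of two end-to-end runs,
and completion of all six ablation variants; training-dependent tests use
down-scaled widths and epoch counts chosen as the smallest that keep the
assertions stable.

## Known limitations

* The cross-omics tensor is cubic in the number of terms; beyond a few dozen
  terms the integrator dominates memory and the per-term variant (or a
  factorized integration) is the practical route.
* The generated interaction matrix inherits the PPI's gene-block structure;
  its isoform-level resolution rests on feature informativeness, and on real
  data its quality is bounded by how strongly co-expression and sequence
  similarity track true interaction partners.
* Class weights are computed per term independently; strongly dependent terms
  (as in real GO hierarchies) are integrated only through the label-space
  tensor, not through structured output constraints.
* Full-batch training is deliberate at desk scale; the gene-minibatch option
  subsamples gene pairs in the generation loss but still forwards all
  isoforms, because the bilinear head scores against every partner embedding.
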