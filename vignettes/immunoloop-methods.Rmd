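---
title: "Methods: model-guided screening of innate-immune modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-guided screening of innate-immune modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

High-throughput screens of immunomodulators measure how a small molecule,
co-delivered with a pattern-recognition-receptor agonist (LPS or MPLA for
TLR4, CpG for TLR9, cGAMP for STING), shifts reporter readouts of NF-κB
(SEAP absorbance) and IRF (luciferase luminescence) activity relative to the
agonist alone. A screening campaign wants, from a library far too large to
assay exhaustively, molecules that *enhance* or *suppress* each
pathway–agonist combination as strongly as possible. `immunoloop` implements
the full closed loop: featurize the library, embed it, fit per-goal
surrogates, select batches by Bayesian optimization, process the resulting
plate data, monitor convergence, and extract interpretable fragment rules —
plus a synthetic plate-level oracle so the entire loop is testable without a
wet lab.

## Data model

Six channels are measured per molecule: NF-κB × {LPS, MPLA, CpG} and
IRF × {LPS, MPLA, cGAMP} (cGAMP acts mainly through IRF and CpG through
NF-κB, so the two off-pairings are not assayed). Raw well readings are
divided by the mean of same-plate positive controls (agonist, no modulator),
giving a dimensionless fold change; this cancels any per-plate multiplicative
factor exactly, which the tests assert end to end. Two replicate plates are
averaged; the reported error is the standard deviation of the mean (for two
replicates, `|a − b| / 2`), propagated onto the log2 scale by the delta
method `err/(fold·ln 2)`. A molecule is *viable* iff both confluency-mask
scores exceed 70% of resting cells (strict inequality); non-viable molecules
are flagged, never deleted, and excluded from rankings and counts only.

Eight *combinations* (six specialists plus the NF-κB and IRF generalists)
and twelve *goals* (NF-κB combinations in both directions, IRF
enhance-only) are fixed vocabulary. A goal's target is `log2` of the
combination's base fold (arithmetic mean of fold changes over the agonist
group for generalists — the literal convention; a geometric-mean switch is
provided for sensitivity analysis), negated for suppression goals so the
optimizer always maximizes.

## Molecular representation

Molecules are ingested from SMILES, canonicalized through RDKit (reached by
a batch subprocess bridge, `inst/python/chem_bridge.py` — no R
cheminformatics stack exists in this environment), with stereochemistry
stripped: the representation is 2D topology throughout. Salts and
co-crystals stay one entity; components are ordered by descending heavy-atom
count and joined with a reserved `[LINK]` token.

The token grammar is a SELFIES-style codec implemented natively in R (the
reference SELFIES library is unavailable here): atom tokens carry bond
order, explicit hydrogen count and charge; branch and ring tokens carry
base-16 length/offset payloads; decoding caps every bond by the remaining
valence of its atoms and skips malformed control tokens, so *any* token
sequence decodes to a valid structure (an empty derivation falls back to
methane). Round-tripping is defined as equality of stereo-stripped canonical
SMILES and holds for 100% of generated libraries in the test suite. The
grammar is this package's own: it honors the same contracts as standard
SELFIES (robust decoding, linking token, one-hot flattening), but token
strings are not byte-compatible with the reference vocabulary.

## Embedding

The variational autoencoder consumes one-hot flattened token sequences. The
encoder is a fully connected stack ending in a Gaussian latent (posterior
*mean* is the embedding, making it deterministic and frozen for a whole
campaign, enforced by a hash check each round). Because no autodiff
framework (torch for R or Python) is available in this environment, the VAE
is implemented with hand-written gradients and Adam — and the decoder is a
one-shot MLP emitting per-position token logits rather than the recurrent
stack of the original design. That substitution is the package's own: a
hand-rolled backprop-through-time GRU was judged a larger defect risk than
the architectural deviation, and nothing downstream consumes the decoder
(the embedding is the encoder's posterior mean; decoding is a diagnostic).
The full-scale geometry (500-200-100 encoder, 100D latent) remains a named
preset; tests exercise a 64-32 / 12–16D desk preset.

The KL weight β defaults to 0.1 with a linear warm-up over the first 10% of
epochs. β = 1 posterior-collapses at the toy data scales exercised here
(reconstruction 1.3% vs ~90% at β = 0.1 with identical budgets); sub-unit β
is standard practice for small molecular VAEs and stays config-exposed.
An ECFP4 fingerprint embedding (2048-bit default, any width) is a validated
drop-in replacement for the latent coordinates; the test suite checks its
downstream surrogate error is no more than 1.2× the VAE's, mirroring the
published ablation, and the campaign-scale tests use it (128 bits) for
speed.

## Surrogates

One exact GP per goal maps latent coordinates to the signed log2 target,
isotropic RBF kernel, targets standardized internally per fit. Predictive
variance includes the fitted noise term, so it tends to `σ_f² + σ_n²` far
from data. Hyperparameters come from seeded multi-restart L-BFGS
maximization of the marginal likelihood (analytic gradients) or, at
campaign scale, a median-pairwise-distance heuristic (ℓ = median distance,
σ_f² = 1, σ_n² = 0.1 on the standardized scale); the strategy is
config-exposed because no single tuning protocol is canonical for this
setting. Cross-validated MAE uses seeded random
folds with per-fold refits and falls back to leave-one-out below the fold
count.

## Batch selection

Each round, every goal model scores all untested candidates by Expected
Improvement against the incumbent `f*` = best *measured* target (believed
values never move it; ξ defaults to 0). A Kriging-believer sweep collects
each model's top-EI nomination against a shared availability snapshot —
two goals may nominate the same molecule; duplicates are merged — then
appends the nominees to every model's training set with *that model's own*
posterior mean as a believed label, updates all posteriors, and repeats
until at least B molecules are selected. Believed labels are purged when
real measurements arrive; an audit in the tests confirms none survive.

Posterior updates during sweeps are exact block-Cholesky extensions of a
preallocated workspace (the believed-update-equals-full-refit contract is
asserted to 1e-8). With `refit = "first_round"` the factorization also
extends across rounds: at a round boundary only the labels change (believed
→ measured, same points), so the Cholesky factor and cross-kernel cache stay
valid and only the solved response vector is recomputed. This is the
campaign-scale default; `refit = "each_round"` rebuilds everything with
freshly derived hyperparameters.

## Convergence monitors

*Stabilizing predictions*: a stop set is drawn once from the untested pool
(100,000 at full scale; 1,000 in the scaled presets) and frozen; after each
round the mean Bhattacharyya distance (univariate-Gaussian closed form,
checked against quadrature to 1e-6) between successive posteriors over the
stop set is reported per goal with its standard error. *Performance
difference*: per-round 5-fold CV-MAE per goal. Both are reported, never
auto-acted on — stopping is a human/config decision.

## The synthetic world

The generator assembles molecules from a scaffold-and-substituent grammar
(16 scaffolds, 30 substituents) chosen so the 85 RDKit `fr_*` substructure
counters vary; libraries up to ~16k distinct canonical structures are
reachable. The planted structure–activity map is linear in fragment counts
per channel: 8 active fragments per channel with log2-scale coefficients of
magnitude 0.4–1 and random sign. Eight (not fewer) active fragments is a
deliberate realism statement: with very sparse maps the discrete optimum is
shared by many molecules and a small random bootstrap already contains the
library optimum for several goals — something no real screen exhibits —
whereas eight effects make top performers rare and span folds ≈ 0.06–16×,
the range a real campaign reports. Replicate noise is Gaussian on the log2
scale (log-normal on folds, keeping them positive; default SD 0.2), plates
carry a log-normal factor (SD 0.1) that normalization must cancel, and a
configurable fraction (default 10%, matching the observed 10.5%) of
molecules receives a sub-threshold confluency mask. All randomness flows
through named sub-streams of one seed so any stage is independently
reproducible.

What a green test does establish: the pipeline is exact in the noiseless
limit (recovered targets equal planted ones to 1e-9), selection enriches
discovered optima over matched random screening, the convergence monitor
decays as information accumulates, and LASSO recovers planted signs. What
it does not establish: biophysical realism (no dose–response, no mechanism,
no correlated assay artifacts beyond plate factors), nor the wet-lab
numbers of the original campaign, which are not reproducible at desk scale.

## Design rules

Assayed molecules (viable, deduplicated by canonical SMILES) are featurized
over the 85 `fr_*` counters; zero-variance columns are dropped, then columns
with |ρ| > 0.95 against an earlier *retained* column (catalogue order fixes
which of a redundant pair survives — recorded in the retained mask); rows
are normalized to unit Euclidean length exactly as the source procedure
states (column standardization is available as a comparison switch, since
row normalization is the unusual but explicit convention). One LASSO per
combination (8 models, signed targets — enhancement and suppression share a
model) is fitted by glmnet over a 50-point log grid from λ_max down to
λ_max·1e-4, λ chosen by 5-fold CV on MAE, refit on all data. Positive
coefficients mark enhancer-promoting fragments, negative
suppressor-promoting; ranked reports cap at the six largest magnitudes.

## Numerical choices and degenerate inputs

Kernel matrices get escalating jitter (1e-8 × 100^k, k ≤ 5) before a
positive-definiteness error; EI at σ = 0 takes the deterministic branch
`max(0, μ − f* − ξ)`; Tanimoto of two all-zero fingerprints is defined as 1
(documented convention); all-zero feature rows stay un-normalized and
flagged; all-equal LASSO targets yield an intercept-only model with a
warning; rank ties everywhere break by molecule id or catalogue order so
every report is reproducible byte for byte.

## Known limitations

RDKit is reached through a subprocess bridge, so chemistry calls must be
batched (every API here is); the SELFIES-style grammar covers organic-subset
chemistry with charges and explicit hydrogens but not stereochemistry or
isotopes; the VAE decoder deviates architecturally as described; full-scale
training (10⁶ molecules, GPU-scale budgets) is out of desk scope by design
and represented by named presets only.
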