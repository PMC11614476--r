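# pldiffuser

SE(3)-equivariant diffusion for ligand-binding protein redesign, in R.

`pldiffuser` is for computational protein designers who want to redesign a
protein around a small-molecule ligand starting from *sequence and SMILES
alone* — no binding-pocket annotation, no multiple sequence alignment. The
model treats a protein–ligand complex as one point cloud (one Cα per
residue, one point per ligand heavy atom) and learns a joint generative
model over 3D coordinates and amino-acid identities. At design time, part of
the sequence is masked, the coordinates are sampled from noise by reverse
diffusion, and the masked residues are decoded from the final
representation.

## The model

**Diffusion.** Coordinates live in the zero-centroid subspace (the centroid
is pinned at the origin, which makes everything translation invariant). A
variance-preserving schedule with α_t² + σ_t² = 1 defines the forward
process

> q(z_t | x) = N_x(α_t x, σ_t² I),  t ∈ [0, 1],

with Gaussian transition posterior

> μ_{t→s} = (α_{t|s} σ_s²/σ_t²) z_t + (α_s σ²_{t|s}/σ_t²) x,
> σ²_{t→s} = σ²_{t|s} σ_s²/σ_t².

Generation runs the grid s(i) = (i−1)/T, t(i) = i/T backwards from a
standard-Gaussian prior, substituting the denoised estimate
x̂ = (z_t − σ_t ε̂)/α_t for x at every step.

**Denoiser.** Sequence, ligand chemistry (nine atom fields, three bond
fields), relative positions, RBF distance embeddings of the current latent
and a sinusoidal time embedding are assembled into per-token and
per-token-pair representations. A residual trunk alternates gated
single-representation attention with pair bias, an outer-product update
(pairwise Kronecker lift), and outgoing/incoming triangle multiplicative
updates. The final pair tensor is symmetrized and mapped by an MLP to a
scalar weight matrix W, and the noise prediction is the weighted sum of unit
relative differences

> ε̂_i = Σ_{j≠i} W_ij (z_i − z_j)/‖z_i − z_j‖,  centroid subtracted.

Because W sees only rotation/translation-invariant features and the field is
built from coordinate differences, ε̂(Rz + t) = R ε̂(z) holds exactly.

**Training.** The objective is L = L_WS + L_KL + L_CE: the Euclidean norm of
the noise residual, a schedule-weighted categorical KL between predicted and
forward-process sequence distributions, and cross-entropy on the stochastically
masked positions (the effective masking ratio is drawn uniformly between 0
and the configured ceiling each step). Gradients come from the package's own
reverse-mode tape (`R/autodiff.R`), verified against finite differences.

**Evaluation.** `diversity_score()` (mean pairwise Levenshtein distance),
`kabsch_rmsd()` (SVD superposition), `tm_score()` (length-normalized
similarity, iteratively reweighted superposition) and `contact_overlap()`
(Jaccard index of contact sets under an 8 Å cutoff).

## Worked example

Overfit a tiny model on one synthetic 16-residue/ethanol complex, then
redesign with 30 % masking:

```r
library(pldiffuser)

ref   <- generate_toy_complex(n_res = 16, ligand_smiles = "CCO", seed = 42)
model <- new_model(model_config(c_m = 16, c_z = 8, n_blocks = 1, c_head = 8,
                                n_head = 2, c_opu = 4, embed_dim = 8, T = 16),
                   seed = 1)
fit <- train_toy(model, list(ref), steps = 200, lr = 2e-2, seed = 7)

design <- sample_complex(fit$model, ref$sequence, ref$ligand,
                         T = 16, seed = 11, mask_ratio = 0.3)
```

which prints (seeds as above):

```
loss: step 1 55.00 -> step 200 9.15
input : TCAIDWTPEDCFVWPN
masked: T--IDW--EDCFVW-N
design: TCAIDWTPEDCFVWPN
RMSD 27.90 A | TM 0.063 | contact overlap 0.033
diversity over 4 designs: 0.50
```

The training loss drops as the model memorizes the single complex; the
redesigned sequence recovers every masked residue (the sequence heads
overfit quickly), while the sampled *structure* of a 200-step toy model is
still far from the reference — structure metrics near their random baseline
are the expected outcome at this scale, and the metric functions are how you
quantify it. A serious run uses more blocks, more steps and many complexes.

There is also a small CLI (installed at `exec/pldiffuser` inside the
package) with `make-fixture`, `train-toy`, `redesign` and `evaluate`
subcommands writing PDB/FASTA/CSV.

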