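---
title: "Interactive segmentation with geodesic scribble encoding and trainable CRFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive segmentation with geodesic scribble encoding and trainable CRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scribbleseg)
```

## The problem and the model

Medical segmentation targets — a placenta in fetal MRI, a tumour in FLAIR —
often have low contrast and ambiguous boundaries, so fully automatic
segmentations need correction and fully manual annotation is too slow.
`scribbleseg` implements a two-stage interactive pipeline:

1. **Automatic proposal.** A resolution-preserving dilated-convolution
   network (*P-Net*) scores every pixel, and a trainable mean-field CRF
   (*CRF-Net(f)*) regularizes the scores into an initial segmentation.
2. **Scribble-driven refinement.** The user marks mis-segmented pixels as
   foreground or background. Each scribble class is converted to a geodesic
   distance map, concatenated with the image and the initial segmentation
   into a $C_I + 3$-channel stack, and passed to a refinement network
   (*R-Net*) whose CRF (*CRF-Net(fu)*) additionally enforces the scribbles
   as hard constraints.

### Geodesic scribble encoding

For a scribble set $\mathcal S$, the unsigned geodesic distance of pixel
$i$ is

$$G(i, \mathcal S) = \min_{j \in \mathcal S} \min_{p \in \mathcal P_{i,j}}
  \int_0^1 \lVert \nabla I(p(s)) \cdot u(s) \rVert \, ds,$$

the cheapest accumulated intensity change over paths from $i$ to the
scribbles. Distances are small inside the homogeneous region containing the
scribble and rise sharply across image edges, which is what makes them a
stronger interaction encoding than Euclidean distance (kept only behind an
ablation flag). On the grid we use edge cost
$\lVert I(i) - I(j) \rVert_2$ between 8-connected (2D) or 26-connected (3D)
neighbours — the pure gradient integrand with no additive spatial term, so a
constant image gives an identically zero map, distances scale linearly with
intensity, and voxel anisotropy does not enter. Distances are computed with
the raster-scan algorithm (forward plus backward sweeps with a 3×3 or
3×3×3 kernel). One pass pair is a fast approximation; *converged* mode (the
default) repeats pass pairs until no distance changes by more than $10^{-6}$
(cap: 20 pairs — a handful of adversarial layouts need more than the
classical single pair, and the package promises exact agreement with
Dijkstra's algorithm on the neighbour graph, which the test suite checks).

Two conventions the source description leaves open, fixed here and tested:
each *computed* geodesic channel is rescaled so its maximum is 1 before
concatenation, and an empty scribble class yields a channel of seeded
uniform $[0,1]$ noise so both channel types share a value range. The
initial-segmentation channel carries the foreground probability by default
(`seg_channel = "binary"` switches to hard labels).

### Resolution-preserving networks

P-Net/R-Net adapt a VGG-like stack: five blocks of 3×3 convolutions
(τ = 2, 2, 3, 3, 3 layers) with stride 1 everywhere and dilation
$q_i = d \cdot 2^{i-1}$ in block $i$, zero padding $q_i r$ per layer so every
feature map keeps the input extent. The receptive field of block $i$ is

$$R_i = 2 \sum_{j \le i} \tau_j \, r \, q_j + 1,$$

i.e. $4d+1, 12d+1, 36d+1, 84d+1, 180d+1$ for $r = 1$ — multi-scale context
without downsampling. Features of all five blocks are concatenated (length
$5C$) and classified by two 1×1 layers. The 3D variant pools once by factor
2 before the blocks, compresses each block's features by factor 4 with
1×1×1 convolutions before concatenation, and upsamples the final scores
back trilinearly; average pooling and trilinear restoration are this
package's choices where the source description names neither mechanism.
Rectified-linear units follow every convolution except the score layer; no
normalization layers are used. The 2D block width defaults to $C = 64$
(VGG block-1 width; never stated for 2D in the source) and 3D uses the
stated $C = 16$; desk-scale runs in the tests use $C = 8$. Convolution
biases start at 0.01 rather than 0: with narrow desk-scale networks, zero
biases leave He-initialized rectified channels exactly dead at the origin.

### The trainable CRF

Labelings $x$ are scored by the Gibbs energy
$E(x) = \sum_i \psi_u(x_i) + \sum_{(i,j) \in \mathcal N} \psi_p(x_i, x_j)$
with unary potentials $\psi_u(l) = -s_i(l)$, the negated network scores (so
with no pairwise term the CRF reduces exactly to the softmax classifier).
Pairwise potentials factor as
$\psi_p(x_i, x_j) = \mu(x_i, x_j) \, f(\tilde f_{ij}, d_{ij})$: a trainable
$L \times L$ label-compatibility matrix (initialized to the Iverson bracket
$[x_i \ne x_j]$) times a freeform *Pairwise-Net* — a fully connected
32–16–1 network evaluated on the feature difference $\tilde f_{ij}$ and the
pixel distance $d_{ij}$. Pairs live in a local patch around each pixel
(7×7 in 2D, 5×5×3 in 3D, centre excluded, ordered pairs); features are the
image intensity channels; $d_{ij}$ is measured in grid units by default
(`spacing_aware` switches to mm). Because $f$ depends on $(i, j)$ only
through $(\tilde f_{ij}, d_{ij})$, its values are evaluated once per pixel
and offset and reused across iterations and labels — bitwise identical to
naive per-pair evaluation, which the tests verify.

Inference is mean-field: $T$ iterations of message passing, compatibility
transform, adding the unary potentials, and normalizing,

$$Q_i(l) \propto \exp\!\big(-\psi_u(l) - \textstyle\sum_{l'} \mu(l, l')
  \sum_{j} f(\tilde f_{ij}, d_{ij}) \, Q_j(l')\big),$$

with scribbled pixels overwritten to exactly 1/0 after every normalization
and in the final output (the hard-constraint rule; applied after
normalization, an ordering the source leaves open). $T$ is likewise never
stated; the default is 5, joint training unrolls $T = 2$ at desk scale, and
the oracle tests use $T \le 3$. The whole unrolled computation is
differentiable in the scores, $\mu$, and the Pairwise-Net weights;
constrained pixels pass no gradient. $\mu$ and $f$ are unconstrained after
training, so potentials need not stay submodular — mean-field inference
does not care, which is precisely why graph cuts are not an option here.

### Pairwise-Net pre-training

The Pairwise-Net is initialized by regression towards the classical
contrast-sensitive weight

$$f_0(\tilde f, d) = \exp\!\Big(\frac{-\lVert \tilde f \rVert^2}{2 \sigma^2 F}\Big)
  \cdot \frac{\omega}{d}, \qquad \sigma = 0.08,\ \omega = 0.5.$$

Training samples draw each feature coordinate from Normal(0, sd 2) and $d$
uniformly from $[1, 8]$: distances below one grid step never occur between
distinct pixels, and because $f_0 \sim \omega/d$ the quadratic loss has
infinite expectation if $d$ may approach 0, so the realizable range is the
defensible sampling domain. 100k samples is the full-scale set; the
desk-scale profile uses 10k. Two numerical choices matter. First, the
hidden activations are tanh (the source layout names only the widths):
with $\sigma = 0.08$ the target is a spike of width $\approx 0.16$ inside a
feature range of $\pm 6$, and rectified-linear hinges never migrated into
that region under plain SGD, while tanh units fit it to a held-out MSE of
order $10^{-5}$. Second, a fixed diagonal input scaling (features
$\times\, 1/(2\sigma)$, distance $\times\, 1/8$) puts the spike at
order-one width so a standard initialization can see it. Fitting uses
minibatch SGD (batch 100, momentum 0.9, initial rate 0.02, slow hyperbolic
decay, 60 epochs).

## Training protocol

All images are standardized by the global per-channel mean and standard
deviation of the training set; the statistics are stored in every
checkpoint and re-applied verbatim at inference. Augmentation applies
horizontal/vertical flips (probability 1/2), rotations uniform in
$[-\pi/8, \pi/8]$, and zooms uniform in $[0.8, 1.25]$ — identically to image
(bilinear) and mask (nearest neighbour); in 3D the transforms act in-plane,
slice by slice, since arbitrary-axis volumetric rotation is not claimed by
the protocol this follows.

The optimizer is plain SGD, minibatch 1, momentum 0.99, weight decay
$5 \times 10^{-4}$, learning rate halved every 5000 iterations (0-based
step convention: the rate at iteration 10000 is a quarter of the initial
rate). The stages run strictly in order:

1. **P-Net pre-training** — cross-entropy on the softmax scores; initial
   rate $10^{-3}$, 100k iterations at full scale.
2. **Pairwise-Net pre-training** — as above.
3. **Joint P-Net + CRF-Net(f)** — cross-entropy on the CRF output $Q$,
   gradients flowing into the network, $\mu$, and the Pairwise-Net (all
   trainable; the source does not say whether anything is frozen); 50k
   iterations, full-scale rate $10^{-6}$.
4. **R-Net + CRF-Net(fu)** — the frozen stage-1 model segments the training
   images; connected under-/over-segmented regions against ground truth
   receive $n = \lceil N_m / 100 \rceil$ simulated clicks ($0$ if
   $N_m < 30$), sampled uniformly without replacement; geodesic input
   stacks are built once; R-Net then trains like P-Net — the first two
   thirds of the stage on plain cross-entropy, the remainder jointly with
   the constrained CRF.

### The desk-scale profile

`desk_scale` divides the *maximum iteration counts* only. The halving
interval stays at 5000: compressing it proportionally collapses the rate by
$2^{20}$ within a few hundred iterations and no stage can learn, whereas the
published schedule's first segment is an effectively constant rate, which a
desk run reproduces. For the same reason the joint stages use $10^{-4}$ at
desk scale — $10^{-6}$ over a few hundred iterations is a no-op — while
`desk_scale = 1` restores the published $10^{-6}$. The suites in this
package train at `desk_scale = 200` (500 P-Net iterations, 250 joint, 500
R-Net) on 32×32 images with block width $C = 8$ and $T = 2$ unrolled
iterations; mean-field oracle checks run at $\le 4 \times 4$; the geodesic
oracle at $\le 16 \times 16$ / $\le 8^3$. These sizes are the package's
reference configuration for a single-CPU laptop-class run.

## What the synthetic fixtures emulate — and what they do not

`make_image()` draws smooth blobs (thresholded band-limited Gaussian noise)
or ellipses on a darker background, adds a zero-mean low-frequency
multiplicative inhomogeneity field and i.i.d. Gaussian noise. Defaults
(contrast 0.5, noise sd 0.1–0.15, inhomogeneity 0.2, foreground fraction
0.25) give visibly ambiguous boundaries — the regime where interactive
refinement earns its keep — while remaining learnable by a desk-scale
network. Blob boundaries are deliberately irregular so the CRF and the
geodesic encoding face curvature, unlike geometric primitives.

What passing tests on these fixtures shows: the machinery — encoding,
networks, CRF, click simulation, training loop — is wired correctly and the
qualitative ordering (refinement improves on the automatic stage) holds.
What it does not show: performance on real MRI. The fixtures have a single
texture per class, no partial-volume effects, no anatomy-shaped priors, no
inter-rater ambiguity, and noise that is Gaussian rather than Rician.
Absolute Dice/ASSD values on fixtures transfer to no clinical dataset.

`degrade_segmentation()` manufactures controlled mis-segmentations
(erode/dilate/shift/drop-component) so the click-count law
$\sum_m [N_m \ge 30] \lceil N_m / 100 \rceil$ can be verified against
analytically known region sizes.

## Degenerate inputs and tie-breaks

Empty seed sets raise an error in `geodesic_distance()` but are handled in
`encode_interactions()` by the documented random fill. A pixel scribbled as
both classes is rejected everywhere. Dice of two empty masks and ASSD of
any empty mask are errors, not conventions. Label ties in the final argmax
resolve to the lower label. Connected components use face connectivity by
default (4 in 2D, 6 in 3D; `"full"` switches to 8/26). Surface points are
region pixels with a face-adjacent outside neighbour, the image border
counting as outside.

## Known limitations

- Training is plain SGD on a single CPU; there is no minibatching across
  images, no GPU path, and full-scale (100k-iteration) runs are not
  realistic in this implementation.
- The 3D variant mirrors the 2D layout beyond the stated width and
  compression factor; the exact per-layer 3D channel plan of the original
  is not fully specified anywhere.
- Pairwise features are raw intensity channels; the learned-feature
  variant the pairwise factorization would permit is not implemented.
- The CLI covers the simulated-interaction workflow; there is no graphical
  scribble capture.
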