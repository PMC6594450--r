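# scribbleseg

Two-stage interactive image segmentation for 2D images and 3D volumes, built
for the regime where automatic segmentation of low-contrast targets (fetal
MRI, brain tumours) needs fast human correction rather than full manual
annotation.

**Stage 1 — automatic proposal.** A resolution-preserving dilated-convolution
network (P-Net: five blocks of 3×3 convolutions, τ = 2, 2, 3, 3, 3 layers,
dilation q_i = d·2^(i−1), receptive fields R_i = 2Σ_{j≤i} τ_j r q_j + 1 =
4d+1 … 180d+1) scores every pixel, and a trainable mean-field CRF with a
learned freeform pairwise potential regularizes the result. The pairwise
potential factors as ψ_p(x_i, x_j) = μ(x_i, x_j)·f(f̃_ij, d_ij): a trainable
label-compatibility matrix (initialized to the Iverson bracket [x_i ≠ x_j])
times a small fully connected network (Pairwise-Net, hidden widths 32/16)
evaluated on the intensity difference and pixel distance of each pair inside
a local patch (7×7 in 2D, 5×5×3 in 3D). Pairwise-Net is pre-trained towards
the contrast-sensitive weight exp(−‖f̃‖²/(2σ²F))·ω/d (σ = 0.08, ω = 0.5),
then everything — network, μ, Pairwise-Net — trains jointly by
back-propagation through the unrolled mean-field iterations.

**Stage 2 — scribble-driven refinement.** User scribbles (foreground /
background pixel sets) are encoded as geodesic distance maps
G(i, S) = min_{j∈S} min_paths ∫‖∇I·u‖ ds — computed by converged raster
scans, exactly the shortest-path distance on the 8/26-connected pixel graph
— and concatenated with the image and the initial segmentation into a
C_I + 3-channel stack for the refinement network (R-Net, same architecture).
Its CRF additionally forces Q_i = 1/0 at scribbled pixels in every
mean-field iteration, so user corrections are honored exactly. Training
interactions are simulated: each connected mis-segmented region of size N_m
gets ⌈N_m/100⌉ uniform random clicks (none if N_m < 30).

Evaluation uses Dice overlap 2|A∩B|/(|A|+|B|) and the average symmetric
surface distance (ASSD) between boundary point sets.

Everything runs at desk scale on one CPU: seeded synthetic fixtures stand in
for clinical data, and `desk_scale` shrinks the published iteration counts
(see the methods vignette, `vignettes/interactive-segmentation-methods.Rmd`).

## Worked example

Train the full two-stage pipeline on 30 synthetic 32×32 blobs, then segment
and refine a harder, lower-contrast 64×64 image the models never saw (the
networks are fully convolutional, so image size is free):

```r
library(scribbleseg)

train <- lapply(1:30, function(i)
  make_image(fixture_config(ndim = 2, extent = 32, contrast = 0.5,
                            noise = 0.15, inhomogeneity = 0.2,
                            rng_seed = 1000 + i)))
models <- train_full_pipeline(train, desk_scale = 200, channels = 8,
                              crf_iterations = 2, rng_seed = 1)

test <- make_image(fixture_config(ndim = 2, extent = 64, contrast = 0.3,
                                  noise = 0.25, inhomogeneity = 0.3,
                                  rng_seed = 5006))
auto <- segment_image(models$stage1, test$image)
clicks <- simulate_interactions(auto$labels, test$truth, rng_seed = 7)
refined <- refine_image(models$stage2, test$image, auto$prob, clicks,
                        rng_seed = 7)
```

Output of this run (about 2.5 minutes on one CPU):

```
Pairwise-Net held-out MSE: 6.93e-05
stage 1 (P-Net + CRF) Dice: 0.705, ASSD: 3.09 px
simulated clicks: 2 foreground, 0 background
stage 2 (R-Net + constrained CRF) Dice: 0.837, ASSD: 2.12 px
```

Reading the numbers: the Pairwise-Net reproduces the contrast-sensitive
target almost exactly (MSE ~7e-5 against values up to 0.5). On the harder
test image the automatic stage reaches Dice 0.705; two simulated foreground
clicks on its largest missed regions, geodesically encoded and fed to
R-Net + CRF-Net(fu), lift it to 0.837 and cut the mean surface error from
3.1 to 2.1 pixels — the pattern the two-stage design is built to produce.

## Command-line interface

A thin Rscript driver covers the whole workflow on PNG/NIfTI files:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "scribbleseg.R", package = "scribbleseg"))')
Rscript $CLI fixtures          --out fx --n 20 --extent 64 --seed 11
Rscript $CLI train-pnet        --data fx --out pnet.rds --seed 1
Rscript $CLI pretrain-pairwise --out pw.rds --seed 1
Rscript $CLI train-joint       --data fx --pnet pnet.rds --pairwise pw.rds --out stage1.rds --seed 1
Rscript $CLI train-rnet        --data fx --stage1 stage1.rds --out stage2.rds --seed 1
Rscript $CLI segment           --image fx/image_001.png --model stage1.rds --out-prob prob.png --out-label lab.png
Rscript $CLI simulate-clicks   --auto lab.png --truth fx/truth_001.png --out clicks.png --seed 3
Rscript $CLI refine            --image fx/image_001.png --prob prob.png --scribbles clicks.png --model stage2.rds --out refined.png --seed 3
Rscript $CLI score             --seg-dir segs --truth-dir fx --out scores.csv
```

Scribble masks are single-channel images congruent with the input
(0 = unlabeled, 1 = foreground, 2 = background); every subcommand accepts
`--seed`, and unseeded runs draw and log one.

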