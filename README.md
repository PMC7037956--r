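# patchentropy

Structural descriptor images for **multimodal medical image similarity and
registration**, built on logarithmic fuzzy entropy and related strictly
concave uncertainty measures.

## The problem and the method

Images of the same anatomy in different modalities (T1/T2/PD MRI, CT vs
ultrasound) cannot be aligned by comparing raw intensities: contrast can
invert between modalities, so the mean absolute difference (MAD) of
intensities is meaningless across them. `patchentropy` maps both images
into a common "third modality" first: every pixel *x* is replaced by the
uncertainty of its local patch intensity distribution,

```
D_{x,l} = M(p_1, ..., p_r),   M(p) = sum_i f(p_i),
```

where *p_i* are the (optionally spatially weighted, optionally
Parzen-smoothed) histogram probabilities of the l×l patch N_{x,l} and *f*
is a strictly concave core function. Four kinds are provided:

* `m1` — Shannon entropy, `f(p) = -p log p`, bound `B1(r) = log r`;
* `m2` — **logarithmic fuzzy entropy**, `f(p) = -[p log p + (1-p) log(1-p)]`,
  bound `B2(r) = log r + (r-1) log(r/(r-1))`;
* `m3` — exponential fuzzy entropy (bound saturates at ≈ 2.705 near
  r = 256, limit e);
* `m4` — rational concave function (bound saturates at ≈ 0.496, limit ½).

Here `r = min(l², 2ⁿ, bins)` is the *variety degree* of a patch (n = image
bit depth). The measures vanish on monochrome patches and attain their
closed-form bounds exactly at uniform distributions. The interest of `m2`
is its wider quantification range: `Δ(r) = B2(r) − B1(r) → 1` nat, an 18%
gain over Shannon entropy at 256 gray levels, which yields more
representative descriptor sets and faster-converging similarity curves.
Descriptor images of the two modalities are then compared by plain MAD
(lower = more similar); bijective intensity remaps leave descriptors
unchanged, which is what makes the comparison modality-independent.

The package also ships the surrounding experiment harness: rigid
rotation/translation similarity curves with valid-overlap masking, a
convergence-rate summary, bit-depth compression, slice matching with
deflection statistics (RDN/LDN/ZDN/ZDP), discrete deformation selection
with the τ residual, mutual-information and raw-MAD baselines, and seeded
generators for multimodal phantoms (shared anatomy, reversed-contrast
LUTs, 3% noise, 20% intensity nonuniformity, 13-bit storage) so everything
runs offline.

## Worked example

```r
library(patchentropy)

pair <- standard_pair(1, size = 128)   # aligned 13-bit pair, reversed contrast
d1 <- compute_descriptor_image(pair$a, patch_spec(l = 7), "m2")
d2 <- compute_descriptor_image(pair$b, patch_spec(l = 7), "m2")
d1
#> <descriptor_image> m2, 128 x 128, l=7, bins=49, r=49, range [1.743, 3.985]

mad_similarity(d1, d2)     # descriptor MAD of the aligned pair
#> [1] 0.2738377
mad_similarity(pair$a, pair$b)  # raw MAD: huge, contrast is inverted
#> [1] 4598.824
```

The descriptor values live in `[0, B2(49)]` nats; 0.27 nats of mean
disagreement between the two modalities' descriptors (vs ~4600 intensity
units of raw disagreement) is the modality-independence at work. A
rotation sweep recovers the alignment:

```r
cv <- similarity_curve(pair$a, pair$b, "m2", patch_spec(l = 7),
                       parameters = seq(-25, 25, 5))
cv[cv$parameter %in% seq(-10, 10, 5), ]
#>  parameter similarity   overlap
#>        -10  0.4566694 0.9194336
#>         -5  0.4093937 0.9521484
#>          0  0.2450596 1.0000000
#>          5  0.4104906 0.9521484
#>         10  0.4546770 0.9194336
```

The curve bottoms at 0°: the pair is aligned. `overlap` is the
valid-region fraction the similarity was evaluated on. The bound table
behind the theory:

```r
bounds_table(r = c(2, 256, 8192))
#>      r        b1        b2       b3        b4       gap
#> 1    2 0.6931472  1.386294 1.297443 0.1666667 0.6931472
#> 2  256 5.5451774  6.543222 2.705726 0.4961089 0.9980443
#> 3 8192 9.0109133 10.010852 2.717889 0.4998779 0.9999390
```

Note `b3`/`b4` barely move past r = 256 while `b2 − b1` (`gap`) approaches
1 nat.

## Command line

A thin CLI over the same functions lives at `inst/cli/patchentropy.R`:

```sh
Rscript inst/cli/patchentropy.R bounds --r_min 2 --r_max 1024 --out out/
Rscript inst/cli/patchentropy.R curve --seed 1 --method m1,m2 --l 7 \
    --from -25 --to 25 --step 1 --out out/
Rscript inst/cli/patchentropy.R match --seed 1 --n_slices 30 --l 15 \
    --bins 16 --weighting modified --estimator parzen \
    --method m2,m1,mad_raw --out out/
```

Subcommands: `bounds`, `descriptor`, `curve`, `match`, `warp-select`,
`synth`. Flags mirror a flat key-value config file (`--config run.cfg`);
every run writes its resolved configuration next to its outputs, and
identical configs produce byte-identical CSVs.

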