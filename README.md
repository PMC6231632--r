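# qdcp — counter-color texture descriptors for stained tissue

Pathology images are colored by design: chemical stains bind tissue
substances selectively, so the *spatial interleaving of distinct stain
chromaticities* (counter colors — e.g. trichrome red muscle/cytoplasm
against blue-green collagen) encodes tissue architecture. This package
implements a compact rotation-invariant color-texture descriptor built on
that observation, for anyone classifying stained-tissue patches (glomerulus
detection, blood-cell screening, and similar two-class patch problems).

## The descriptor

Each pixel's color vector is split into brightness and a unit chromatic
direction, `I(p) = I_M(p) · I_O(p)` with `‖I_O(p)‖ = 1`. Similarity between
two directions is their inner product `m_{p,i} = I_O(p)·I_O(i)` (the cosine
of the color-separation angle). Around every pixel, 8 neighbors on a unit
circle are compared to the center and binarized with `b_{p,i} = 1` iff
`m_{p,i} < T_O`; the ring code is reduced to the minimum over cyclic shifts,

```
I_QDCP(p) = min_{0 ≤ n < 8} Σ_i b_{p,i} · 2^((i+n) mod 8),
```

which has exactly **36** distinct values (binary necklaces of length 8).
The image feature is the 36-bin histogram of these labels — the **QDCP**
descriptor. A rotation-invariant LBP on the brightness image complements it:
concatenation gives the 72-dim **QDCP-LBP**, the joint co-occurrence table
the 1296-dim **QDCP/LBP**. `T_O ∈ [0.75, 0.85]` (30–40° of color
separation) is a good default for stained tissue; the evaluation harness
selects it by nested cross-validation.

The package also ships a two-class synthetic stained-texture generator
(counter-color micro-structure vs. single-stain smooth patches, iso-luma
stain pairs so luma is class-uninformative) and the full evaluation
protocol: repeated stratified nested cross-validation with FLD, RBF-SVM,
and KNN, reporting accuracy and ROC-AUC.

## A worked example

```r
library(qdcp)

# a synthetic benchmark: 65 images/class, 40° stain separation
ds <- generate_dataset(65, stain_texture_params(), seed = 7)

# one counter-class image's descriptor
h <- qdcp_feature(ds$images[[66]], t_o = 0.8)
tidy(h)
#> # A tibble: 36 × 2
#>    label   value
#>    <int>   <dbl>
#>  1     0 0.894
#>  2     1 0.0666
#>  3     2 0.0250
#>  4     3 0.00234
#> # …
# bin 0 is the all-zero code (no counter-color change in the ring); the
# mass in higher bins is the counter-color micro-structure.

# nested CV of the fused descriptor, threshold selected in the inner loop
sets <- feature_set_grid(ds$images, "qdcp_lbp", t_o_grid = default_t_o_grid())
ev <- nested_cv(sets, ds$labels, "fld", n_repeats = 1, seed = 7)
glance(ev)
#> # A tibble: 1 × 6
#>   classifier acc_mean acc_sd auc_mean auc_sd n_scores
#>   <chr>         <dbl>  <dbl>    <dbl>  <dbl>    <int>
#> 1 fld           0.993 0.0230        1      0       10
```

An accuracy of 0.99 with AUC 1.0 says the fused descriptor separates
counter-color from smooth patches almost perfectly at this separation; the
grayscale-LBP baseline on the same images scores near chance (~0.5),
because the two stains are constructed iso-luma.

The command-line wrapper mirrors the API:

```sh
qdcp synth --n-per-class 65 --separation 40 --out data/
qdcp extract --data data/ --descriptor qdcp-lbp --t-o 0.8 --out features.csv
qdcp classify --features features.csv --classifier svm --report report.json
```

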