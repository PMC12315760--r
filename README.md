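# vascmrf

Simulation and reconstruction toolkit for **MR vascular fingerprinting**:
estimating sub-voxel microvascular properties — blood volume fraction (BVf,
%), mean vessel radius (R, µm), blood oxygen saturation (SO₂, %) and tissue
T₂ (ms) — from pre/post-contrast GESFIDSE signal evolutions matched against
simulated dictionaries.

## Who this is for

Researchers developing or evaluating vascular fingerprinting methods who
need a self-contained, deterministic forward model (voxel-scale vascular
geometry → susceptibility field → diffusing-isochromat GESFIDSE signal →
fingerprint dictionary) and both reconstruction routes (exhaustive matching
and Bayesian inverse regression), without any external imaging data.

## The model in brief

A voxel is a periodic binary vascular occupancy grid. Intravascular cells
carry a susceptibility offset

    Δχ = Δχ_deoxy · Hct · (1 − SO₂/100) + Δχ_CA

(Δχ_deoxy = 3.318 ppm SI per unit haematocrit, Hct = 0.42, Δχ_CA = 0.5 ppm
post contrast agent). The induced field offset is solved with the Fourier
dipole kernel `1/3 − (k·b̂)²/|k|²` at B₀ = 4.7 T. The GESFIDSE response
(TR 4000 ms, 32 echoes, ΔTE 3.3 ms, spin echo at 60 ms) is simulated by
isochromat stepping: per step `exp(i·δω·dt)` dephasing, Gaussian diffusion
convolution of the complex magnetization (ADC = 1000 µm²/s), an ideal 180°
pulse at 30 ms, and `exp(−t/T₂)` relaxation applied analytically. The pre-
and post-contrast echo trains are concatenated and L2-normalized into one
64-sample fingerprint per voxel.

Dictionaries pair each voxel geometry with one scrambled-Sobol draw of
(SO₂, T₂) over [35, 90] % × [45, 110] ms and record the geometry's
*measured* BVf and min-Feret mean radius. Reconstruction is either

* **DBM** — dot-product search over the dictionary (estimates sit on the
  dictionary grid), or
* **DBL** — a Gaussian locally linear mapping (mixture of affine
  parameter→signal regressions fitted by EM, inverted analytically), whose
  posterior mean interpolates between grid points.

Estimates are clipped to physical ranges: BVf, SO₂ ∈ [0, 100] %,
R ∈ [0, 250] µm, T₂ ≥ 0 ms.

## Worked example

```r
library(vascmrf)

# one cylinder voxel, its field, and its fingerprint
g  <- grid_spec(c(32, 32, 48), 2.5)           # 80 x 80 x 120 um^3
v  <- make_cylinder_voxel(g, radius_law = 5, target_bvf = 4, seed = 2)
print(v)
#> <vmrf_voxel> [cylinder3d] 32 x 32 x 48 cells, BVf 4.079%, mean radius 5.06 um

sq <- sequence_spec(dt_sim_ms = 0.3)
fp <- simulate_fingerprint(v, so2 = 60, t2_ms = 80, seq = sq)
print(fp)
#> <vmrf_fingerprint> 2 x 32 echoes, norm 3.638

# a small dictionary and both reconstructions of a two-region phantom
d  <- make_dictionary(n = 200, family = "cylinders", grid = g, seq = sq, seed = 1)
ph <- make_phantom(
  tibble::tibble(region = 1:2, bvf = c(3, 8), radius = c(5, 7),
                 so2 = c(70, 80), t2 = c(65, 80)),
  snr = 30, grid = g, seq = sq, seed = 11
)
maps <- reconstruct_maps(ph$series, d, method = "dbm")
est  <- tidy(maps)
est$region <- ph$region_map[cbind(est$x, est$y)]
aggregate(cbind(bvf, so2) ~ region, est, mean)
#>   region      bvf      so2
#> 1      1 3.596073 75.32413
#> 2      2 6.556447 70.52148
```

The phantom's "tumour" block (region 2) was planted with higher blood
volume (8 % vs 3 %) and oxygenation (80 % vs 70 %) than the surrounding
tissue. The blood-volume ordering survives reconstruction at SNR 30
(region 2 mean ≈6.6 % vs ≈3.6 %) even with this deliberately tiny
200-entry dictionary. The SO₂ ordering does not separate at this
dictionary size — fingerprints of independently realized geometries with
identical parameters scatter more than a 10 pp SO₂ change moves them, a
small-dictionary effect discussed in the methods vignette; the acceptance
suite's 2,000-entry dictionary recovers both orderings under both
reconstruction methods.

`autoplot()` methods exist for voxels, fingerprints, dictionaries and maps;
`tidy()`/`glance()` summarize dictionaries, maps and DBL models. A thin
command-line wrapper is installed under `exec/vascmrf`
(`vascmrf geom|dict|phantom|recon|stats|run`).

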