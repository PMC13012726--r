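# microvasc

Reconstruction and analysis of cerebral microvascular networks from time
series of volumetric two-photon fluorescence microscopy data.

Functional hyperemia — the local adjustment of brain blood flow to neuronal
activity — plays out across networks of hundreds of interconnected
microvessels, but most analyses interrogate vessels one at a time.
`microvasc` turns two-channel 3D volumes (vascular dye + labeled neurons),
or binary masks from any segmentation model, into a vascular graph with a
radius estimate at every micrometer-spaced centerline vertex and time
point, and quantifies the network-level geometric response. It is aimed at
groups doing in vivo 2PFM of cortical vasculature who need vessel-wise and
vertex-wise calibers tracked across stimulation conditions.

## What it computes

* **Graph reconstruction** — isotropic upsampling, rigid registration (MSE
  descent), mask cleanup (hole filling, < 50-voxel component removal),
  slicewise dilation + union across time points, homotopy-preserving 3D
  thinning, iterative pruning of terminal "hairs" under 20 µm, and graph
  construction with ordered vertex paths sampled every 1–1.73 µm.
* **Vertex-wise radii** — Richardson–Lucy deconvolution with the microscope
  PSF, extraction of the plane orthogonal to the local centerline tangent,
  36 radial intensity profiles at 10° steps (5× bicubic sub-sampling),
  per-spoke boundary at the minimum of the profile gradient, 2-SD outlier
  rejection, radius = mean retained boundary distance. A vessel-wise prior
  radius from the mask distance transform (≈ R/3 for a cylinder) scales all
  smoothing kernels.
* **Network statistics** — responder classification (radius change beyond
  twice the baseline SD; vessels > 20 µm only), capillary/large split at
  5 µm radius, assortativity q of radius changes on the vessel adjacency
  graph (Pearson over linked pairs, both orientations), Poiseuille
  resistance ρ = 8µL/(πR⁴) (µ = 4 cP), and capillary network efficiency
  E = mean over ordered junction pairs of 1/ρ(least-resistive path), with
  vessels over 10 µm diameter excluded.
* **Phantoms and validation** — a synthetic generator (tubes on curved
  centerlines, beads, neuron somas, PSF blur, SNR-calibrated noise) with
  exact ground truth, plus the three validation experiments: rescaling
  (scale equivariance), noise injection (robustness), and simulated
  fluorescent beads (accuracy/precision vs. averaging).

## Worked example

```r
library(microvasc)

# a Y-shaped capillary network, one arm dilating 12% after "stimulation"
n <- 76; c0 <- (n - 1) * 0.99 / 2; ctr <- c(c0, c0, 21)
arm <- function(d) { u <- d / sqrt(sum(d^2)); rbind(ctr, ctr + u * (c0 - 4.5)) }
spec <- phantom_spec(
  c(n, n, 44), c(0.99, 0.99, 0.99),
  tubes = list(
    list(centerline = arm(c( 1.0,  0.12, -0.10)), radius = 3.0, intensity = 900),
    list(centerline = arm(c(-0.5,  0.866, 0.12)), radius = 2.6, intensity = 900),
    list(centerline = arm(c(-0.5, -0.866,-0.12)), radius = 2.6, intensity = 900)),
  background_level = 300,
  timepoints = list(c(1, 1, 1), c(1.03, 0.97, 1.03),
                    c(0.97, 1.03, 0.97), c(1.12, 1, 1)))
ph <- generate_phantom(spec)

psf <- gaussian_psf()
vols <- lapply(seq_along(ph$volumes), function(t) list(
  vascular = apply_psf_and_noise(ph$volumes[[t]]$vascular, psf,
                                 target_snr = 6.9,
                                 foreground_mask = ph$vessel_masks[[t]],
                                 seed = 10 + t)))
res <- run_pipeline(pipeline_config(vols, baseline = 1:3, post = 4,
                                    register = FALSE, psf = psf,
                                    segment_method = "fixed",
                                    segment_threshold = 600))
res$graph
#> <vascular_graph> 4 nodes (1 junctions, 3 endpoints), 3 vessel segments
#>   segment length: mean 35.0 um, range [20.9, 45.1] um
subset(res$summaries,
       select = c(edge, length, baseline_radius_mean, delta_radius, responder))
#>   edge   length baseline_radius_mean delta_radius responder
#> 1    1 20.88469             2.513871   0.05296103      none
#> 2    2 39.16006             2.420502   0.04232847      none
#> 3    3 45.07910             2.927621   0.26645941   dilator
res$report$efficiency$change$pct
#> [1] 19.57531
```

The dilating arm (edge 3, the 3.0 µm tube) is the only responder: its
+0.27 µm change exceeds twice its baseline SD, while the other arms'
small fluctuations do not. The ~+20% capillary-network efficiency change
reflects the R⁻⁴ resistance law along paths through the dilated arm.

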