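# npgtv

Non-local patch graph total variation (NPGTV) denoising of
single-channel images, with applications as a preprocessing stage for
micrographs and other grayscale scientific imagery.

## The problem and the method

An observed image is modelled as $u_0 = u + z$ with i.i.d. Gaussian
noise $z \sim N(0, (\sigma/255)^2)$ per pixel (noise level quoted on
the 8-bit gray scale, intensities stored on $[0,1]$). Classical total
variation regularizes differences between *adjacent* pixels and
therefore erases texture. NPGTV instead measures total variation on a
graph built from patch similarity: each pixel's $s \times s$ patch is
vectorized, augmented with its spatially weighted coordinates
$v'_i = (v_i, \lambda i_{row}, \lambda i_{col})$, joined to its $K$
nearest neighbours in feature space, and weighted by
$w(i,j) = \exp(-d^2(i,j)/\sigma_k^2)$. The denoised image solves the
constrained convex program

$$\hat u = \arg\min_u\ \sum_i \Big[\sum_{j \in N_i} W_{ij} (u_i - u_j)^2\Big]^{1/2}
\quad \text{s.t.}\quad \|u - u_0\|_2 \le \varepsilon ,$$

solved by Douglas–Rachford splitting between the fidelity-ball
projection and the graph-TV proximal operator (itself computed by an
accelerated primal–dual scheme with a duality-gap certificate).
Defaults follow the noise-adaptive policy: patch side 5 below
$\sigma = 15$, 9 above; $K = 5$; $\lambda = 0.05$; kernel bandwidth
$\sigma_k^2 = 0.2 s^2 (\sigma/255)^2$; ball radius
$\varepsilon = (\sigma/255)\sqrt{n}$.

The package also ships seeded phantom generators with the additive
noise model, a 4/8-connected grid-graph TV baseline run through the
same solver, PSNR/SSIM metrics, PNG/TIFF I/O, and a small CLI.

## Worked example

```r
library(npgtv)

clean <- make_phantom("piecewise", 64, 64, num_regions = 4, seed = 2)
nz    <- noise_model(25, seed = 3)          # sigma = 25 on the 8-bit scale
noisy <- add_awgn(clean, nz)

res <- npgtv_denoise(noisy, noise = nz)     # default parameter policy
psnr(clean, noisy)$psnr_db                  # 20.69
psnr(clean, res$denoised)$psnr_db           # 33.41
ssim(clean, res$denoised)                   # 0.985

grid <- baseline_grid_tv(noisy, noise = nz) # classical TV, same solver
psnr(clean, grid$denoised)$psnr_db          # 28.11
```

The noisy phantom sits at 20.7 dB PSNR; the non-local pipeline lifts
it to 33.4 dB (SSIM 0.985), about 5.3 dB above the classical grid-TV
baseline on the identical solver — the gap attributable to the
non-local graph alone.

Lower-level building blocks are exported individually:
`extract_patch_features()`, `knn_edges()` (exact brute-force and
k-d-tree backends), `build_weighted_graph()`, `total_variation()`,
`p_dirichlet()`, `prox_graph_tv()`, `project_l2_ball()`,
`drs_solve()`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "npgtv.R", package = "npgtv"))')
Rscript $CLI simulate --kind piecewise --size 64 --regions 4 \
    --noise-std 25 --seed 7 --out noisy.png --clean clean.png
Rscript $CLI denoise --in noisy.png --out denoised.png --noise-std 25
Rscript $CLI evaluate --ref clean.png --test denoised.png
```

Every run that writes an image also writes a `*.config.yaml` snapshot
of the fully merged settings, sufficient to replay the run exactly.

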