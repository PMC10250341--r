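# ifcfit

Single cells aspirated through a constriction microchannel narrower than
themselves form a transient mega-ohm electrical seal. The impedance
transient measured during each transit at two demodulation frequencies
(100 and 180 kHz) carries enough information to recover the cell's
**intrinsic, size-independent electrical properties**: the specific
membrane capacitance *C*<sub>sm</sub> (µF/cm²) and the cytoplasm
conductivity *σ*<sub>cyto</sub> (S/m), jointly with the seal leak
resistance *R*<sub>leak</sub> (Ω). `ifcfit` implements the complete
signal-to-properties stack for this class of impedance flow cytometer, in
streaming order, for people building or evaluating such instruments:

* **Equivalent-circuit model** — empty channel
  *Z*<sub>base</sub> = *R*<sub>ch</sub> ∥ 1/(jω*C*<sub>p</sub>); sealed cell
  *Z*<sub>cell</sub> = *R*<sub>leak</sub> ∥ (*n*<sub>m</sub>/(jω*C*<sub>m</sub>) + *R*<sub>cyto</sub>),
  measured as *Z*<sub>total</sub> = 1/(jω*C*<sub>p</sub>) ∥ (*R*<sub>ch</sub> + *Z*<sub>cell</sub>),
  with closed-form decoupling and channel-parameter fitting.
* **Streaming detector** — per 2 ms frame, a Gaussian-KDE mode estimate of
  the baseline, near-neighbour refinement robust to temporary clogging,
  threshold detection, and extraction of the eight impedance parameters per
  event (peak/baseline × amplitude/phase × two frequencies).
* **Cached-grid least-error solver** — the forward model evaluated once for
  all 256×128×128 grid circuits and cached (8,388,608 complex impedances at
  two frequencies); each cell is fitted by the argmin of
  Δ<sub>i,j,k</sub> = Σ<sub>f</sub> |ΔRe *Z*<sub>f</sub>| + |ΔIm *Z*<sub>f</sub>|,
  plus a per-cell reference solver that is bit-identical by construction.
* **FCNN comparator** — the five-layer MLP baseline (MSE, SGD, lr 1e-3,
  batch 32, 50 epochs, one net per target) that is accurate in distribution
  and degrades on shifted populations, unlike the physics-based fit.
* **Metrics & synthetic data** — KL divergence between binned property
  distributions, identity-line R², quadrant gating (1.4 µF/cm², 0.4 S/m),
  KDE density peaks, and a fully seeded synthetic-stream generator with
  known ground truth.

## Worked example

```r
library(ifcfit)

# a 0.6 s synthetic acquisition: 50 cells, 0.5 % amplitude noise
sim <- simulate_stream(stream_spec(n_cells = 50, duration = 0.6,
                                   noise_sd_amp = 0.005,
                                   noise_sd_phase = 0.001, seed = 42))
fv  <- detect_cells(sim)                       # 50 events detected
fit <- ifc_fit(fv, grid = grid_spec_from_sample(sim$truth, 64, 32, 32))
summary(fit)
```

```
Least-error circuit fit summary (fppf)
  events fitted: 50 (errored: 0, on a grid boundary: 10)
  quartiles:
     C_sm sigma_cyto  R_leak delta
25% 2.354     0.3781 2121000 11770
50% 2.526     0.4324 2456000 18790
75% 2.980     0.4783 2791000 29160
  throughput: 4.18 ms/cell (0.21 s total, informational)
```

The fitted population has its median *C*<sub>sm</sub> at 2.53 µF/cm² and
median *σ*<sub>cyto</sub> at 0.43 S/m — the generator's configured
log-normal locations (2.6 µF/cm², 0.4 S/m) up to sampling noise and grid
quantisation. `delta` is the per-cell least-error objective in Ω; `coef(fit)`
returns the per-cell property matrix, `residuals(fit)` the objective
values, and `plot(fit, gate = quadrant_gate())` the gated scatter of
*C*<sub>sm</sub> vs *σ*<sub>cyto</sub>. The same fit with
`method = "traditional"` (per-cell grid recomputation, no cache) returns
bit-identical results — the cached path changes the schedule, never the
answer.

A thin command-line front end covers the same pipeline from a shell:

```sh
Rscript inst/cli/ifcfit.R run --cells 100 --duration 1 --grid 64x32x32 --out out/ --seed 7
Rscript inst/cli/ifcfit.R synth  --cells 200 --seed 3 --out stream.csv
Rscript inst/cli/ifcfit.R detect --in stream.csv --out features.csv
```

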