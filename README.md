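# bimqp — quantitative 2D microwave breast imaging in R

Microwave tomography recovers the dielectric profile of tissue from
scattered electromagnetic fields measured outside it. Because malignant
tissue contrasts strongly with healthy breast tissue in permittivity and
conductivity, a quantitative reconstruction doubles as a detection map —
but the breast is a *strong* scatterer (relative permittivity 2.5–67
against a matching medium of 10), which makes the inverse scattering
problem nonlinear and severely ill-posed.

`bimqp` implements a complete reconstruction chain for the 2D problem:

* **Forward solver** — pulse-basis method-of-moments discretization of the
  electric-field integral equations (state and data equations), with
  Hankel-function Green operators, multi-source / multi-frequency
  acquisition on a circular array, and optional measurement noise.
* **Inverse solver** — the Born iterative method (BIM) with every contrast
  update posed as a real-valued quadratic program: minimize
  `sum |d_m|^2 + lambda * ||grad chi||^2` subject to the linearized data
  equations `d_m + sum_n g_mn chi_n E_t,n = Es_m` stacked over all
  receivers, sources and frequencies, with box bounds on the complex
  contrast `chi` derived from the physical permittivity/conductivity
  ranges.
* **Learned refinement** — a convolutional encoder–decoder (U-Net-style
  contracting/expanding paths with skip connections, implemented directly
  in R with BLAS-backed im2col convolutions) that maps BIM permittivity
  reconstructions to ground-truth-like maps, trained on a 108-phantom
  synthetic sweep (4 breast-density classes × 3 tumor diameters × 9
  positions).
* **Phantoms and metrics** — the concentric-circle validation phantom, a
  procedural generator for layered breast phantoms of four density
  classes, the Frobenius relative error `Re` with accuracy
  `100·(1 − Re)`, and the tissue conductivity regression
  `sigma = 0.019·eps_r − 0.047` S/m.

See `vignettes/microwave-imaging-methods.Rmd` for the model, the
discretization, the QP solver, and every tunable parameter with its
default and rationale.

## Worked example

Reconstruct the concentric-circle validation phantom from its own
simulated data (fine 150×150 simulation grid, 18 sources and 30 receiver
positions on a 10 cm circle, 15 frequencies from 600 kHz to 600 MHz,
inversion on 32×32 with 10 Born-QP iterations):

```r
library(bimqp)

phantom <- circular_phantom(build_grid(0.18, 150))
medium  <- background_medium(10, 0, default_frequencies(15))
array   <- antenna_array(18, 30, 0.10)
data    <- simulate_dataset(phantom, array, medium, 150)
data
#> <mwi_dataset> 15 frequencies x 18 sources x 30 receivers (fine grid 150)

recon <- bim_reconstruct(data, build_grid(0.18, 32),
                         bim_config(iterations = 10,
                                    init = "multi_freq_source"))
recon
#> <mwi_recon> 32 x 32 map after 10 iterations; final data residual 0.1563

truth <- matrix(render_phantom(phantom, 32)$eps_r, 32)
relative_error(truth, matrix(recon$eps_r, 32))
#> <mwi_error_report> Re = 0.4737 (accuracy 52.63%) over 1 test
```

The final line is the Frobenius relative error of the iterative
reconstruction alone: about 47% on this strong scatterer, i.e. the bulk
structure is recovered (the homogeneous starting map scores 54%) but the
sharp concentric profile is not — which is precisely the gap the
refinement network closes on the breast-class sweep:

```r
ts  <- make_training_set(base_seed = 7)        # 108 simulate+reconstruct runs
cfg <- refiner_config(input_size = 32, depth = 3, base_channels = 8,
                      seed = 8, epochs = 250, lr = 5e-3, batch_size = 16)
tr  <- train_refiner(build_refiner(cfg), ts, lr = refiner_schedule(250))
accs <- sapply(ts$val_idx, function(i)
  relative_error(ts$pairs[[i]]$target,
                 refine(tr$model, ts$pairs[[i]]$input))$accuracy)
round(median(accs), 1)
#> [1] 95.1
```

A config-driven end-to-end run (`run_pipeline()`) and a thin command-line
tool (`inst/scripts/bimqp` with `simulate | reconstruct | train | refine |
evaluate | run` subcommands) wrap the same functions.

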