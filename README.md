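# digitizerlab

Quantitative characterization and predictive modeling of
recombinase-based **digitizer** gene circuits — circuits that convert a
graded (analog) transcriptional input into a near-Boolean output via
irreversible Flp/frt recombination, with an shRNA-imposed threshold
suppressing leak. The package is aimed at synthetic biologists
characterizing such circuits from single-cell flow-cytometry data
(calibrated MEFL units) and tuning component ratios in silico.

It provides four things:

1. **Signal-quality metrics** for ON/OFF population pairs:
   geometric fold change (FC), empirical ROC **AUC** (Mann–Whitney with
   tie correction), and an extended **SNR**

   SNR = 10·log10( Δμ² / ( σ̄² + (P_Dud + P_Leaky)·Δμ² ) ) dB,

   where Δμ is the log10 separation between the ON mode of the induced
   population and the OFF mode of the uninduced population (from
   deterministic two-component Gaussian mixture fits), σ̄ the average
   mode spread, and the fail power charges dud cells (OFF when they
   should be ON) and leaky cells (ON when they should be OFF) a
   full-amplitude error each. Δ-metrics (output − input) quantify
   amplification through a circuit.

2. **A per-cell ODE model** of three digitizer topologies (no-shRNA,
   constant-shRNA, feedforward-shRNA) on a transient-transfection
   platform: quasi-steady-state elimination of the fast RNA species
   leaves a molecular-titration nonlinearity
   φ = ½[(m−s−K_d) + √((m−s−K_d)² + 4·K_d·m)] on the Flp production
   flux, a first-order Flp activity pool, an irreversible recombined
   fraction, and linear fluorescent-protein accumulation — plus the
   explicit fast-species reference model used to validate the reduction.

3. **Fitting and identifiability**: dose-response fitting on log10
   geometric means of gated populations with common random numbers,
   multistart landscapes, the b_f–K_d profile ridge, and recovery of
   the dimensionless groups (effective threshold eKd = K_d/(b_f·copies),
   basal fraction a_f/b_f) that the data actually constrain.

4. **Forward prediction**: metric heatmaps over Flp:shRNA
   component-ratio grids, and transduction of empirical graded input
   distributions (e.g. a weak synNotch-driven signal) into predicted
   output populations.

A synthetic-data module generates complete virtual experiments
(transfection-dose heterogeneity, onset delays, measurement noise,
dose-response/time-series/ratio-sweep designs, weak bimodal inputs), so
the entire pipeline runs and is tested without any external data.

## Worked example

Simulate a balanced constant-shRNA digitizer (35:5 ng Flp:shRNA) at
225 nM dox vs uninduced, gate the top 30% of CFP-expressing cells, and
score the output channel:

```r
library(digitizerlab)

ind <- simulate_population(2000, dose_map(35, 5), dox = 225,
                           topology = "CONSTANT", seed = 1)
uni <- simulate_population(2000, dose_map(35, 5), dox = 0,
                           topology = "CONSTANT", seed = 2)
gi <- gate_top_fraction(ind, "cfp", 0.30)
gu <- gate_top_fraction(uni, "cfp", 0.30)

metric_set(gi, gu, "ofp")
#> <metric_set> FC=169  AUC=1.000  SNR=19.65 dB
metric_set(gi, gu, "ifp")
#> <metric_set> FC=46.6  AUC=1.000  SNR=17.51 dB
delta_metrics(metric_set(gi, gu, "ifp"), metric_set(gi, gu, "ofp"))
#> <delta_report> dSNR=2.14 dB  dFC=123  dAUC=0.000
```

The induced and uninduced output populations are perfectly separable
(AUC = 1), the output is 169-fold above the OFF state, and the circuit
adds about 2 dB of signal-to-noise over its own input channel — the
digitizing amplification the topology is designed for. Fitting the model
to one ratio's dose response (`fit_dose_response`) and sweeping
`sweep_ratio_grid` then predicts FC/AUC/SNR across ratios not used in
the fit; `transduce_distribution` pushes a measured weak input
distribution through any configuration to predict whether it will be
amplified.

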