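# Default synflash pipeline configuration. Paths left unset fall back to
# the packaged CEPC machine description and radiolysis network.
dose_grid: [5, 10, 20, 30]
dose_rate_grid: [1.0e-2, 5.6e-2, 3.2e-1, 1.8, 10, 56, 320, 1800, 1.0e+4,
                 5.6e+4, 3.2e+5, 1.8e+6, 1.0e+7]
surrogate_degree: 3
followup_s: 100
mean_dose_rates: [6.13e+6, 1.06e+7]   # CEPC beamline, with / without filters
prediction_dose: 10
fit_method: likelihood
n_boot: 200
seed: 1
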