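# CEPC storage ring / bending magnet machine description (Higgs mode).
# Beam current is the collider design value; it is not fixed by the
# closed-form dose-rate chain, which uses published downstream rates.
electron_energy_GeV: 120
bend_radius_m: 10700
beam_current_mA: 17.4
bend_angle_rad: 2.844e-3
n_bunches: 242
revolution_frequency_Hz: 3003
bunch_duration_s: 14.7e-12
sigma_x_mm: 2.09e-2
sigma_y_mm: 6.8e-5
emittance_x_nmrad: 1.21
emittance_y_nmrad: 3.1e-3
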