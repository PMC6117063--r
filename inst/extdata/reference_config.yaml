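# Reference configuration: six stages of proliferative retinal PSE growth.
# Per-stage generator means come from the packaged calibration
# (default_calibration()); entries under `calibration:` override single
# columns for single stages. Embryo-level CVs are package choices (the
# source measurements report figure error bars, not embryo-level variance).
seed: 1
stages: [20, 24, 30, 36, 42, 48]
n_embryos: 10
scenario: control
thickness_correction: true
cmz_correction_factor: 0.95
heatmap_bins: 8
transition_hpf: 35.5
ramp_hours: 6
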