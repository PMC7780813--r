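# Demo pipeline configuration: synthesize a paced atrial-like and
# ventricular-like recording, condition and measure them, build the
# restitution curves, and run a 4-dose screen of a saturating
# APD-prolonging drug. Times in ms, rates in bpm, doses in the ec50 unit.
seed: 7
out_dir: cardiomap_out
protocol:
  mode: fixed
  rate_bpm: 60
  n_beats: 8
duration: 9000
frame_rate: 100
cell_types: [atrial, ventricular]
noise:
  gaussian_sd: 0.02
  drift_slope: -0.005
analyze:
  polarity: auto
  detrend: percentile
  smooth: true
restitution:
  bpm_start: 60
  bpm_end: 200
  bpm_step: 10
  beats_per_step: 8
  discard_per_step: 2
dose:
  doses: [3, 10, 30, 100]
  n_wells: 6
  drug:
    name: demo-prolonging
    effects:
      - param: apd
        emax: 1.0
        ec50: 10
        hill_n: 1
        group: atrial
      - param: apd
        emax: 0.3
        ec50: 10
        hill_n: 1
        group: ventricular
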