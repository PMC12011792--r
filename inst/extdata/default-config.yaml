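# ecgid default run configuration — the single reference for every tunable.
# Values here are the package defaults; load with read_run_config(), override
# per run via CLI flags. Unknown keys are an error.

noise:                      # synthetic-cohort contaminants (mV, Hz, events/s)
  powerline_amp: 0.05       # mains sinusoid amplitude, mV
  powerline_freq: 50.0      # mains frequency (50 Hz region)
  baseline_amp: 0.1         # baseline-wander amplitude, mV
  baseline_freq: 0.25       # respiratory drift frequency, Hz
  emg_amp: 0.03             # muscle-noise SD (20-120 Hz band-limited), mV
  motion_spike_rate: 0.1    # electrode/motion artifact events per second
  motion_amp: 0.1           # motion random-walk excursion scale, mV

preprocess:
  bandpass_low: 0.5         # Hz; high-pass edge removes DC and drift
  bandpass_high: 40.0       # Hz; low-pass edge suppresses mains interference
  butter_order: 6           # per direction; run zero-phase (forward-backward)
  lowpass_only: no          # yes = low-pass at bandpass_high only
  loess_span_s: 1.5         # baseline-trend window, s
  nlm_patch: 11             # non-local-means patch length, samples (odd)
  nlm_search: 101           # search window, samples (odd)
  nlm_h: ~                  # ~ = auto: 0.4 x MAD-based noise SD
  feature_mode: raw         # raw samples (F = 2570) or wavelet coefficients
  wavelet_name: db4
  wavelet_level: 4

discretization:             # histogram MI estimator
  n_bins: 16
  strategy: equal_width     # or equal_frequency
  log_base: 2               # entropies in bits (fixed)

gcn:
  n_graph_layers: 5         # depth variants: 5 / 10 / 15
  channels: 64              # channels per node after input projection
  dense_layers: 2           # dense-head depth (published tuned head: 13)
  dense_width: 64
  dropout_p: 0.2            # applied after the graph blocks, training only
  output_mode: softmax_identify   # or sigmoid_verify
  learning_rate: 0.001      # Adam step size
  epochs: 600
  batch_size: ~             # ~ = full batch
  seed: 0

tau: 0.0                    # MI threshold; 0 keeps all positive edges
adjacency_mode: per_record  # or cohort (averaged MI graph)
n_subjects: 20              # simulator cohort shape
recordings_per_subject: 6
duration: 10.0              # s
fs: 257.0                   # Hz
K: 10                       # folds for k-fold cross-validation
seed: 42                    # master seed
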