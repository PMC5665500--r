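# Example run configuration for muacprobit::run_pipeline().
# All paths are resolved relative to the working directory.

# Master seed: mandatory; every stage derives its own substream from it.
seed: 12345

# Synthetic populations to generate (arguments to population_spec()).
# Alternatively supply `input_csv: path/to/child_records.csv` instead.
populations:
  - n_clusters: 30
    children_per_cluster: 27
    muac_mean_mm: 135
    muac_sd_mm: 12.5
    icc: 0.05
    region: east_africa
  - n_clusters: 30
    children_per_cluster: 27
    muac_mean_mm: 138
    muac_sd_mm: 12.5
    icc: 0.05
    region: asia

# MUAC plausibility bounds in mm; records outside are excluded and counted.
cleaning_bounds: [80.0, 220.0]

# SD reference for the external-SD PROBIT estimator:
#   builtin - published regional mean MUAC SDs (point masses)
#   build   - build from the populations above (effective-sample-size
#             weighted, regionally stratified bootstrap)
#   <path>  - a JSON reference written by write_sd_reference()
sd_reference: builtin

# Small-sample study grid.
design:
  sample_sizes: [25, 50, 100]
  reps: 20
  n_clusters_sub: 25

methods: [classic, probit_I, probit_II]
cutoffs: [115.0, 125.0]   # SAM, GAM (mm)
n_boot: 500               # bootstrap replications per PROBIT estimate
thresholds: [5.0, 10.0, 15.0]  # GAM classification thresholds (percent)
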