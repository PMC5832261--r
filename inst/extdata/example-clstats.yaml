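# beat-to-beat |dCL| statistics for matched periodic and random pacing
# run with: run_experiment(system.file("extdata", "example-clstats.yaml", package = "apmem"))
protocol: clstats
CL_star: 350.0
clv: 35.0
omega: 2.4
seed: 7
n_beats: 10000
thresholds: [0, 10, 20, 30, 40, 50, 60, 70]
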