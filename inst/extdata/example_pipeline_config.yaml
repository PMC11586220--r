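# Example run_pipeline() / CLI config: simulate a database with one planted
# signal and analyze all four drug groups.
source:
  synthetic:
    n_cases: 20000
    duplicate_fraction: 0.05
    background_rates: 0.01
    seed: 42
policy: all
top_k: 15
out_dir: pipeline_output
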