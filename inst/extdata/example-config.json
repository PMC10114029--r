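{
  "_comment": "Annotated example configuration; keys beginning with an underscore are comments and ignored by the loader. Every field is optional: omitted fields take the model defaults and are echoed, fully resolved, into the output metadata sidecar. 'params' holds the model rates and protocol; 'populations' the census sizes; 'p_mig' a scalar applied to every ordered pair or a full square matrix; 'experiment' one of run, sweep, unique, rescue, curve, timeline (the sweep/rescue/curve fields neighbour_sizes, migration_probs, n, p_mig_values, p_mig_grid, variant, payload_k may then be set).",

  "params": {
    "p_inv": 0.001,
    "beta": 0.1,
    "p_loss": 0.1,
    "f": 1,
    "payload_mode": "fraction",
    "loss_model": "scaled",
    "t_max": 200000,
    "window_start": 100000,
    "window_end": 200000,
    "unique_sample_every": 100
  },

  "populations": [200, 400],
  "p_mig": 5e-06,

  "experiment": "run",
  "seed": 1,
  "replicates": 10,
  "out": "results.csv"
}
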