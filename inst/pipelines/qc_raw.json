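{
  "experimentName": "qc_raw",
  "seed": 1,
  "scaleTransformProcessingSteps": [
    { "name": "aggregate", "FUN": "aggregate_samples",
      "ARGS": { "n_files": 4, "n_events_per_file": 10000 } },
    { "name": "remove_margins", "FUN": "remove_margins",
      "ARGS": { "bounds": { "FSC-A": [0, 262144], "SSC-A": [0, 262144] } } },
    { "name": "compensate", "FUN": "compensate" },
    { "name": "estimate_transforms", "FUN": "estimate_transform_set",
      "ARGS": { "fluoro_channels": ["FL1-A", "FL2-A", "LD-A"] } }
  ],
  "flowFramesPreProcessingSteps": [
    { "name": "read", "FUN": "read_sample" },
    { "name": "remove_margins", "FUN": "remove_margins",
      "ARGS": { "bounds": { "FSC-A": [0, 262144], "SSC-A": [0, 262144] } } },
    { "name": "qc_in_time", "FUN": "qc_in_time",
      "ARGS": { "channels": ["FL1-A", "FL2-A", "LD-A"],
                "bin_size": 100, "mad_cutoff": 6 } },
    { "name": "compensate", "FUN": "compensate" },
    { "name": "remove_doublets", "FUN": "remove_doublets",
      "ARGS": { "area_channel": "FSC-A", "height_channel": "FSC-H",
                "nmad": 4 } },
    { "name": "remove_debris", "FUN": "remove_debris",
      "ARGS": { "fsc_channel": "FSC-A", "ssc_channel": "SSC-A",
                "n_clusters": 2 } },
    { "name": "remove_dead_cells", "FUN": "remove_dead_cells",
      "ARGS": { "ld_channel": "LD-A", "transformSet": true } }
  ]
}
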