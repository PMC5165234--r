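# Leaky-zone scenario: resensitization deep inside the opposite zone.
# Load with: load_config(system.file("extdata", "leaky-zones.yaml", package = "gcsim"))
motility:
  preset: low_resens
arena:
  radius_um: 120
  n_fdc: 85
gc:
  n_tfh: 105
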