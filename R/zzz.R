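utils::globalVariables(c(
  "value", "series", "frame", "epoch", "mse", "set", "truth", "estimate",
  "sequence", "train_mse", "val_mse", "intensity", "metric"
))
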