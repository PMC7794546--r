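{
  "channel_R": "ON",
  "channel_ABS": "ON",
  "channel_ABS_D1": "ON",
  "channel_ABS_D2": "ON",
  "channel_ABS_SNV": "OFF",
  "n_conv_blocks": 1,
  "n_fc_blocks": 2,
  "conv1_filters": 55,
  "conv1_kernel": 5,
  "conv1_stride": 4,
  "conv1_padding": "Same",
  "conv1_batch_norm": "OFF",
  "conv1_activation": "SELU",
  "conv1_pooling": "OFF",
  "conv1_dropout": "OFF",
  "fc1_nodes": 251,
  "fc1_batch_norm": "ON",
  "fc1_activation": "ELU",
  "fc1_dropout": "ON",
  "fc2_nodes": 219,
  "fc2_batch_norm": "ON",
  "fc2_activation": "Swish",
  "fc2_dropout": "ON",
  "conv_dropout_rate": 0.25,
  "fc_dropout_rate": 0.22,
  "optimiser": "Adam",
  "batch_size": 1105,
  "epochs": 1448
}
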