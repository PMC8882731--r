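{
  "encoder": "ONEHOT2",
  "trainFraction": 0.8,
  "folds": 5,
  "voteThreshold": 3,
  "seed": 1,
  "gridSearch": false,
  "grids": {
    "RF": {"num.trees": [200, 500]},
    "MLP": {"size": [4, 8], "decay": [0.001, 0.01]},
    "SGD": {"learningRate": [0.01, 0.05, 0.1], "lambda": [0.0001, 0.001]},
    "XGB": {"eta": [0.1, 0.3], "max_depth": [3, 6]}
  }
}
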