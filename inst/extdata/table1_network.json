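{
  "input_shape": [240, 240, 3],
  "activation": "relu6",
  "padding_mode": "same_ceil",
  "layers": [
    {
      "kind": "standard_conv",
      "kernel": [3, 3, 3, 32],
      "stride": 2,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 32],
      "pointwise_out": 64,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 64],
      "pointwise_out": 128,
      "stride": 2,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 128],
      "pointwise_out": 128,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 128],
      "pointwise_out": 256,
      "stride": 2,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 256],
      "pointwise_out": 256,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 256],
      "pointwise_out": 512,
      "stride": 2,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 512,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 512,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 512,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 512,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 512,
      "stride": 1,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 512],
      "pointwise_out": 1024,
      "stride": 2,
      "bn": true
    },
    {
      "kind": "depthwise_separable",
      "depthwise": [3, 3, 1024],
      "pointwise_out": 1024,
      "stride": 2,
      "bn": true
    },
    {
      "kind": "standard_conv",
      "kernel": [1, 1, 1024, 15],
      "stride": 1,
      "bn": false
    }
  ]
}
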