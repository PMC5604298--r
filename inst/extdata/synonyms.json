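{
  "month": ["date"],
  "disease": ["illness", "condition", "infection"],
  "gender": ["sex"],
  "treatment": ["therapy"],
  "tissue": ["organ"],
  "donor": ["patient", "subject"],
  "stage": ["phase"],
  "duration": ["time", "length"],
  "age": ["years"],
  "strain": ["breed"],
  "illness": ["condition"]
}
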