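{
  "outcomes": ["Death", "Above knee amputation", "Below knee amputation", "Severe pain", "Deep surgical site infection", "Bone healing complication", "Moderate pain", "Mild pain", "Superficial surgical site infection", "Perfect health"],
  "reference": "Perfect health"
}
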