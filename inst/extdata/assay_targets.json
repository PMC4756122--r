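{
  "Av4143": ["battery_hen", "poultry", "turkey"],
  "Av163": ["battery_hen", "poultry", "turkey", "waterfowl"],
  "Av43": ["battery_hen", "poultry"],
  "Av216": ["waterfowl"],
  "Av24": ["waterfowl"],
  "Av13": ["waterfowl"]
}
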