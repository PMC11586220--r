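{
  "pitolisant": ["PITOLISANT", "PITOLISANT HYDROCHLORIDE", "WAKIX"],
  "sodium_oxybate": ["SODIUM OXYBATE", "LUMRYZ", "XYREM", "XYWAV"],
  "solriamfetol": ["SOLRIAMFETOL", "SOLRIAMFETOL HYDROCHLORIDE", "SUNOSI"],
  "modafinil": ["MODAFINIL", "PROVIGIL"]
}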