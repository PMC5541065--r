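{
  "description": "Benthic annotation classes for an 11-category shallow reef transect: seven scleractinian/octocoral genera, turf algae, sediment, and the in-scene gray reference board.",
  "labels": [
    "Acropora",
    "Briareum",
    "Echinopora",
    "Goniopora",
    "Isopora",
    "Pocillopora",
    "Porites",
    "Reference",
    "Sediment",
    "Seriatopora",
    "Turf"
  ],
  "reserved": {
    "Reference": "gray reference board used for white-balance / reflectance correction"
  }
}
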