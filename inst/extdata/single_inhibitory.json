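{
  "format": "oscibin-network-config",
  "version": 1,
  "units": {
    "tau": "ms",
    "theta": "input units",
    "J": "input units",
    "sigma_noise": "input units",
    "h_ext": "input units",
    "f": "Hz"
  },
  "network": {
    "name": "single_inhibitory",
    "labels": "I",
    "clamped": [],
    "N": {
      "I": 5000
    },
    "tau": 10,
    "p": [
      0.1
    ],
    "J": [
      -1
    ],
    "sigma_noise": {
      "I": 10.2469507659596
    },
    "theta": {
      "I": -142.578474067544
    },
    "m_clamped": {},
    "target_m": {
      "I": 0.3
    },
    "notes": "tau = 10 ms is a package choice; it only sets the time scale."
  },
  "drive": null
}
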