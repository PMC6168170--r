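{
  "_provenance": "Literal published kinetic constants, parsed from the undelimited 16-value vector as k0=0.005, k1=0.01, k2=0.4, k3=1, k4=0.1, k5=0.00135, k6=0.01, k7=0.01, k8=1, k9=1, k10=0.01, k11=5, k12=1, k13=0.005, k14=1, kd=1 (the unique 16-token parse). This set is monostable at every LIF level and fails the structural calibration gate; it is retained for reference and remains selectable via config.",
  "k0": 0.005,
  "k1": 0.01,
  "k2": 0.4,
  "k3": 1,
  "k4": 0.1,
  "k5": 0.00135,
  "k6": 0.01,
  "k7": 0.01,
  "k8": 1,
  "k9": 1,
  "k10": 0.01,
  "k11": 5,
  "k12": 1,
  "k13": 0.005,
  "k14": 1,
  "kd": 1
}
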