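{
  "_provenance": "Repository-default developmental parameter set: the published kinetic constants with kd = 0.01 and the Nanog/Gata6 coupling rebalanced (k2, k11, k13, k14) so that the structural calibration gate passes: three branch-tracked fixed points (stem cell / transition / differentiated) across L in [0, 200], transition branch unstable at every L. See the methods vignette, section 'Calibrating the developmental parameter set'.",
  "k0": 0.005,
  "k1": 0.01,
  "k2": 0.45,
  "k3": 1,
  "k4": 0.1,
  "k5": 0.00135,
  "k6": 0.01,
  "k7": 0.01,
  "k8": 1,
  "k9": 1,
  "k10": 0.01,
  "k11": 0.05,
  "k12": 1,
  "k13": 0.5,
  "k14": 0.1,
  "kd": 0.01
}
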