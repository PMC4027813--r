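{
  "geometry": {
    "Rb": 5e-05,
    "Rc": 5e-06
  },
  "diffusion": {
    "D": 1e-05,
    "D_carb": 1e-07
  },
  "membrane": {
    "kmC": 0.3,
    "kmH": 0.0003,
    "jc": 0.6,
    "alpha": 0,
    "Kalpha": 1
  },
  "shell": {
    "kc": 0.001,
    "Npores": 4800,
    "rpore": 3.5e-08,
    "lshell": 1.8e-07
  },
  "ca": {
    "Vca": 15000000,
    "Vba": 8800000,
    "Kca": 3200,
    "Kba": 9300
  },
  "rubisco": {
    "Vmax": 180000,
    "Km0": 270,
    "KO": 900,
    "VmaxO": 57118.5,
    "KmO": 900,
    "KC": 270
  },
  "external": {
    "Cout": 0.14,
    "Hout": 14,
    "O": 260
  },
  "scenario": "carboxysome",
  "ca_placement": "volumetric"
}
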