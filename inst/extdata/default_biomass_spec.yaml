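components:
- name: carbohydrate
  mass_fraction: 0.26
  volatile_fraction: 0.75
  A: 39839810000.0
  Ea: 100.0
  model: F1
- name: protein
  mass_fraction: 0.16
  volatile_fraction: 0.75
  A: 2.694099e+12
  Ea: 130.0
  model: F1
- name: lipid
  mass_fraction: 0.3
  volatile_fraction: 0.95
  A: 4.024345e+23
  Ea: 270.0
  model: F1
moisture_fraction: 0.06
ash_fraction: 0.22
moisture:
  A: 386000000.0
  Ea: 60.0
noise_sd: 0.0
initial_mass: 6.0
T_start: 303.0
T_end: 1073.0
grid_step: 0.5
seed: 1
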