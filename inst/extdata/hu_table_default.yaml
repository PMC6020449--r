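# HU -> material / density conversion table (same values as
# rtmc::default_hu_table()).  materials: contiguous HU bins; density:
# piecewise-linear breakpoints, clamped outside the range.
materials:
  - {hu_low: -1100, hu_high: -850, name: AIR,    index: 1}
  - {hu_low: -850,  hu_high: -150, name: LUNG,   index: 2}
  - {hu_low: -150,  hu_high: 300,  name: TISSUE, index: 3}
  - {hu_low: 300,   hu_high: 3100, name: BONE,   index: 4}
density:
  - {hu: -1000, density_g_cm3: 0.0012}
  - {hu: -800,  density_g_cm3: 0.26}
  - {hu: -200,  density_g_cm3: 0.92}
  - {hu: 0,     density_g_cm3: 1.0}
  - {hu: 300,   density_g_cm3: 1.10}
  - {hu: 1200,  density_g_cm3: 1.76}
  - {hu: 3000,  density_g_cm3: 2.8}
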