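# Synthetic left-foot insole layout (size 42-43 EU).
# Anatomical labels and zone partition follow the 16-cell instrumented
# insole; centroid coordinates (mm, origin at the posterior-medial corner,
# x anterior, y lateral) and sensing areas (cm^2) are a plausible synthetic
# stand-in, NOT manufacturer ground truth.
side: left
size_variant: "42-43"
length_mm: 270.0
width_mm: 95.0
sensors:
  - {id: 1,  label: "Posterior Medial Heel",            zone: rearfoot, x_mm: 30.0,  y_mm: 30.0, area_cm2: 11.0}
  - {id: 2,  label: "Posterior Lateral Heel",           zone: rearfoot, x_mm: 30.0,  y_mm: 62.0, area_cm2: 11.0}
  - {id: 3,  label: "Anterior Medial Heel",             zone: rearfoot, x_mm: 62.0,  y_mm: 30.0, area_cm2: 11.0}
  - {id: 4,  label: "Anterior Lateral Heel/Lateral Arch", zone: rearfoot, x_mm: 64.0, y_mm: 62.0, area_cm2: 11.0}
  - {id: 5,  label: "Central/Medial Midfoot",           zone: midfoot,  x_mm: 105.0, y_mm: 34.0, area_cm2: 9.0}
  - {id: 6,  label: "Central/Lateral Midfoot",          zone: midfoot,  x_mm: 105.0, y_mm: 60.0, area_cm2: 9.0}
  - {id: 7,  label: "Medial Arch",                      zone: midfoot,  x_mm: 130.0, y_mm: 28.0, area_cm2: 9.0}
  - {id: 8,  label: "Lateral Midfoot Border",           zone: midfoot,  x_mm: 133.0, y_mm: 72.0, area_cm2: 9.0}
  - {id: 9,  label: "1st Metatarsal Head (MTH1)",       zone: forefoot, x_mm: 185.0, y_mm: 24.0, area_cm2: 9.0}
  - {id: 10, label: "2nd Metatarsal Head (MTH2)",       zone: forefoot, x_mm: 192.0, y_mm: 42.0, area_cm2: 9.0}
  - {id: 11, label: "3rd Metatarsal Head (MTH3)",       zone: forefoot, x_mm: 196.0, y_mm: 57.0, area_cm2: 9.0}
  - {id: 12, label: "4th Metatarsal Head (MTH4)",       zone: forefoot, x_mm: 193.0, y_mm: 70.0, area_cm2: 9.0}
  - {id: 13, label: "5th Metatarsal Head (MTH5)",       zone: forefoot, x_mm: 185.0, y_mm: 82.0, area_cm2: 9.0}
  - {id: 14, label: "Hallux (Great Toe)",               zone: toes,     x_mm: 237.0, y_mm: 26.0, area_cm2: 7.0}
  - {id: 15, label: "Central Toes",                     zone: toes,     x_mm: 238.0, y_mm: 48.0, area_cm2: 7.0}
  - {id: 16, label: "Lateral Toes",                     zone: toes,     x_mm: 232.0, y_mm: 68.0, area_cm2: 7.0}
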