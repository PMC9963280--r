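# Rock-daisy paleo-structure: four areas x four biomes, four epochs.
# Matrix entries: 0 (absent), "weak" (replaced by weak_value), 1 (strong).
# Area order: SouthAmerica, BajaCalifornia, TransMexVolcanicBelt, BasinAndRange
# Biome order: tropical, temperate, subtropical, desert
weak_value: 0.1
epochs:
  - {name: Oligocene,      start: 33.9, end: 23.0}
  - {name: earlyMiocene,   start: 23.0, end: 16.0}
  - {name: midLateMiocene, start: 16.0, end: 5.3}
  - {name: recent,         start: 5.3,  end: 0.0}
areas: [SouthAmerica, BajaCalifornia, TransMexVolcanicBelt, BasinAndRange]
biomes: [tropical, temperate, subtropical, desert]
geo_adjacency:
  - # Oligocene
    - [1, 0, 0, 0]
    - [0, 1, 1, 1]
    - [0, 1, 1, 1]
    - [0, 1, 1, 1]
  - # earlyMiocene
    - [1, 0, 0, 0]
    - [0, 1, 1, 1]
    - [0, 1, 1, 1]
    - [0, 1, 1, 1]
  - # midLateMiocene: Baja weakly connected to the mainland
    - [1, 0, 0, 0]
    - [0, 1, weak, weak]
    - [0, weak, 1, 1]
    - [0, weak, 1, 1]
  - # recent: Baja fully separated
    - [1, 0, 0, 0]
    - [0, 1, 0, 0]
    - [0, 0, 1, 1]
    - [0, 0, 1, 1]
biome_availability:
  - # Oligocene: no desert anywhere
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
  - # earlyMiocene
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
    - [1, 1, 1, 0]
  - # midLateMiocene: desert emerging weakly
    - [1, 1, 1, weak]
    - [1, 1, 1, weak]
    - [1, 1, 1, weak]
    - [1, 1, 1, weak]
  - # recent: desert widespread
    - [1, 1, 1, 1]
    - [1, 1, 1, 1]
    - [1, 1, 1, 1]
    - [1, 1, 1, 1]
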