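# Reference chemical universe: 9 metabolites, 43 conversion reactions,
# 8 importers + 8 exporters (one pair per non-energy metabolite).
#
# Per-metabolite rates are per time step. Influx is nonzero only for the
# resource R. The mass column of the source table could not be recovered
# unambiguously; mass is carried as 1.0 and is not consumed by the dynamics.
#
# Canonical reaction ordering (59 reactions, serialization-stable):
#   1..43  conversions in the order listed below (column-major order of the
#          published 5-column table, which groups R-degradations, building
#          block degradations, 2-reactant syntheses, the 2 M2 family and the
#          M3/M4/M5 family),
#   44..51 importers in symbol order (B1, B2, M1..M5, R),
#   52..59 exporters in the same symbol order.
name: reference
metabolites:
  - {id: R,  class: resource,       diffusion: 0.011, degradation: 0.0003, toxicity: 0.0779, mass: 1.0, influx: 0.002}
  - {id: B1, class: building_block, diffusion: 0.011, degradation: 0.0100, toxicity: 0.0588, mass: 1.0, influx: 0.0}
  - {id: B2, class: building_block, diffusion: 0.012, degradation: 0.0100, toxicity: 0.1038, mass: 1.0, influx: 0.0}
  - {id: E,  class: energy,         diffusion: 0.050, degradation: 0.1000, toxicity: 0.0651, mass: 1.0, influx: 0.0}
  - {id: M1, class: intermediate,   diffusion: 0.014, degradation: 0.0006, toxicity: 0.1056, mass: 1.0, influx: 0.0}
  - {id: M2, class: intermediate,   diffusion: 0.019, degradation: 0.0003, toxicity: 0.0804, mass: 1.0, influx: 0.0}
  - {id: M3, class: intermediate,   diffusion: 0.013, degradation: 0.0006, toxicity: 0.0797, mass: 1.0, influx: 0.0}
  - {id: M4, class: intermediate,   diffusion: 0.014, degradation: 0.0014, toxicity: 0.1586, mass: 1.0, influx: 0.0}
  - {id: M5, class: intermediate,   diffusion: 0.016, degradation: 0.0008, toxicity: 0.0475, mass: 1.0, influx: 0.0}
conversions:
  - "R -> B2 + E"
  - "R -> B1 + E"
  - "R -> M1 + 3 E"
  - "R -> M2 + 5 E"
  - "R -> M4 + 3 E"
  - "R -> M5 + 4 E"
  - "R -> M3 + 2 E"
  - "B1 -> M1 + 2 E"
  - "B1 -> M2 + 4 E"
  - "B1 -> M4 + 2 E"
  - "B1 -> M5 + 3 E"
  - "B2 -> M1 + 2 E"
  - "B2 -> M2 + 4 E"
  - "B2 -> M3 + E"
  - "B2 -> M4 + 2 E"
  - "B2 -> M5 + 3 E"
  - "M1 + M4 -> R"
  - "M1 + M2 -> M3"
  - "M1 -> M2 + 2 E"
  - "M2 + M3 -> B1"
  - "M2 + M3 -> B2"
  - "M2 + M5 -> M4"
  - "M2 + M4 -> M3"
  - "M2 + M5 -> M3"
  - "M2 + M4 -> B2"
  - "M2 + M5 -> B2"
  - "M2 + M5 -> R"
  - "M2 + M5 -> B1"
  - "M2 + M5 -> M1"
  - "2 M1 -> R"
  - "2 M2 -> M1"
  - "2 M2 -> B1"
  - "2 M2 -> B2"
  - "2 M2 -> M4"
  - "2 M2 -> M5"
  - "M3 + M5 -> R"
  - "M3 -> M5 + 2 E"
  - "M3 -> M4 + E"
  - "M4 -> M2 + 2 E"
  - "M4 + M5 -> B2"
  - "M4 + M5 -> R"
  - "M4 + M5 -> B1"
  - "M5 -> M2 + E"
transports:
  importers: [B1, B2, M1, M2, M3, M4, M5, R]
  exporters: [B1, B2, M1, M2, M3, M4, M5, R]
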