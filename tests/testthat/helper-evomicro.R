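## Shared fixtures: the reference universe is loaded once per test run.
ref_universe <- load_reference_universe()

## A hand-built 6-reaction toy universe for closure/viability oracles.
toy_universe <- function() {
  mets <- data.frame(
    id = c("R", "B1", "B2", "E", "M1"),
    mclass = c("resource", "building_block", "building_block", "energy",
               "intermediate"),
    diffusion = 0.01, degradation = 0.001, toxicity = 0.1, mass = 1,
    influx = c(0.002, 0, 0, 0, 0), stringsAsFactors = FALSE)
  evomicro:::build_universe(
    "toy", mets,
    c("R -> M1 + 2 E", "M1 -> B1 + E", "M1 -> B2", "2 M1 -> B2"),
    importers = c("R"), exporters = c("R"))
}

## Independent brute-force closure oracle (set expansion to fixpoint).
closure_oracle <- function(universe, conv_idx, start = "R") {
  have <- start
  repeat {
    grew <- FALSE
    for (i in conv_idx) {
      cv <- universe$conversions[[i]]
      if (all(names(cv$reactants) %in% have) &&
          !all(names(cv$products) %in% have)) {
        have <- union(have, names(cv$products))
        grew <- TRUE
      }
    }
    if (!grew) return(have)
  }
}

## Small deterministic genome for cell-level tests.
simple_cell_genome <- function(u = ref_universe) {
  genome(
    transporter_gene(u, "R", FALSE, promoter = 2, vmax = 2, ks = 1, ke = 0.5),
    enzyme_gene(u, 4L, promoter = 2, vmax = 2, ks = 0.5),    # R -> M2 + 5 E
    enzyme_gene(u, 32L, promoter = 2, vmax = 2, ks = 0.5))   # 2 M2 -> B1
}

## Tiny settled population for scheduler tests.
small_population <- function(seed = 11, w = 7, h = 7, steps = 10, ...) {
  cfg <- sim_config(seed = seed, width = w, height = h, record_every = 5, ...)
  st <- build_initial_population(cfg)
  if (steps > 0) st <- run_simulation(cfg, state = st, n_steps = steps)
  st
}
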