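## Configuration, snapshots, run outputs and packaged fixture communities.

#' Simulation configuration
#'
#' @param seed master seed; split into named per-phase RNG streams
#'   (initialisation, death, lottery, mutation, HGT, shuffling) so that
#'   disabling one stochastic phase does not perturb the draws of the
#'   others.
#' @param universe a `metabolic_universe` (default: the reference universe).
#' @param width,height lattice dimensions (default 45 x 45).
#' @param well_mixed replace diffusion by global averaging.
#' @param n_steps default run length.
#' @param n_init initial population size (default: fill the grid).
#' @param dynamics a [dynamics_params()].
#' @param mutation a [mutation_params()].
#' @param record_every history recording cadence in steps.
#' @param vol_to_site conversion factor from cell volume to site volume
#'   used at lysis.
#' @param init_pools `"empty"` (resource builds up from influx; the
#'   default, matching inoculation into fresh medium) or `"steady"`.
#' @param renew_markers whether lineage markers renew when one fixes
#'   (disable for scripted lineage assays).
#' @param init_vol,init_budget,init_internal,init_b_pop ancestral cell
#'   state: starting volume, budget, named internal concentrations (kept
#'   below the toxicity thresholds) and the initial population-production
#'   average (default: the production rate of the initial cell state, so
#'   early lottery odds are balanced).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, universe = NULL, width = 45L, height = 45L,
                       well_mixed = FALSE, n_steps = 1000L, n_init = NULL,
                       dynamics = dynamics_params(),
                       mutation = mutation_params(), record_every = 10L,
                       vol_to_site = 1, init_pools = "empty",
                       renew_markers = TRUE,
                       init_vol = 0.4, init_budget = 1,
                       init_internal = c(R = 0.02, E = 0.01,
                                         B1 = 0.02, B2 = 0.02),
                       init_b_pop = NULL) {
  if (is.null(universe)) universe <- load_reference_universe()
  n_init <- n_init %||% (as.integer(width) * as.integer(height))
  if (is.null(init_b_pop)) {
    bb <- universe$bb_ids
    init_b_pop <- production_rate(
      if (bb[1] %in% names(init_internal)) init_internal[[bb[1]]] else 0,
      if (bb[2] %in% names(init_internal)) init_internal[[bb[2]]] else 0)
  }
  structure(list(seed = as.integer(seed), universe = universe,
                 width = as.integer(width), height = as.integer(height),
                 well_mixed = isTRUE(well_mixed),
                 n_steps = as.integer(n_steps), n_init = as.integer(n_init),
                 dynamics = dynamics, mutation = mutation,
                 record_every = as.integer(record_every),
                 vol_to_site = vol_to_site, init_pools = init_pools,
                 renew_markers = renew_markers, init_vol = init_vol,
                 init_budget = init_budget, init_internal = init_internal,
                 init_b_pop = init_b_pop),
            class = "sim_config")
}

#' Load a simulation configuration from a YAML file
#'
#' Every key is optional (defaults are filled in); unknown keys are
#' rejected with an exhaustive listing. `dynamics` and `mutation` are
#' nested maps of parameter overrides; `universe` may name a universe file
#' path.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "universe", "width", "height", "well_mixed", "n_steps",
             "n_init", "dynamics", "mutation", "record_every", "vol_to_site",
             "init_pools", "renew_markers", "init_vol", "init_budget",
             "init_internal", "init_b_pop")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- raw
  if (!is.null(raw$universe))
    args$universe <- load_reference_universe(raw$universe)
  if (!is.null(raw$dynamics))
    args$dynamics <- do.call(dynamics_params, raw$dynamics)
  if (!is.null(raw$mutation))
    args$mutation <- do.call(mutation_params, raw$mutation)
  if (!is.null(raw$init_internal))
    args$init_internal <- unlist(raw$init_internal)
  do.call(sim_config, args)
}

## ---- serialization -------------------------------------------------------

universe_to_list <- function(u) {
  list(name = u$name,
       metabolites = u$metabolites,
       conversions = u$labels[seq_len(u$n_conversions)],
       importers = u$transports$substrate[u$transports$direction == "importer"],
       exporters = u$transports$substrate[u$transports$direction == "exporter"])
}

universe_from_list <- function(x) {
  build_universe(x$name, as.data.frame(x$metabolites),
                 unlist(x$conversions), unlist(x$importers),
                 unlist(x$exporters))
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$universe <- universe_to_list(config$universe)
  out$dynamics <- unclass(config$dynamics)
  out$mutation <- unclass(config$mutation)
  out$init_internal <- as.list(config$init_internal)
  out
}

config_from_list <- function(x) {
  x$universe <- universe_from_list(x$universe)
  x$dynamics <- do.call(dynamics_params, x$dynamics)
  x$mutation <- do.call(mutation_params, x$mutation)
  x$init_internal <- unlist(x$init_internal)
  do.call(sim_config, x[setdiff(names(x), character(0))])
}

#' Save a population snapshot
#'
#' Writes the full simulation state (environment pools and occupancy, every
#' cell's state and genome, clade registry, history, per-phase RNG streams
#' and configuration) as versioned JSON, so a run can be resumed or assayed
#' later with bit-identical continuation.
#'
#' @param state a `population_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(state, path) {
  snap <- list(
    schema = "evomicro-snapshot-1",
    step = state$step, b_pop = state$b_pop, epoch = state$epoch,
    status = state$status, next_marker = state$next_marker,
    next_clade = state$next_clade, n_hgt_events = state$n_hgt_events,
    n_discovery_events = state$n_discovery_events,
    config = config_to_list(state$config),
    env = list(width = state$env$width, height = state$env$height,
               well_mixed = state$env$well_mixed, pools = state$env$pools,
               occupant = state$env$occupant),
    site = state$site, vol = state$vol, budget = state$budget,
    ode_h = as.numeric(state$ode_h %||% numeric(length(state$vol))),
    etox = state$etox, lifetime = state$lifetime,
    production = state$production, marker = state$marker,
    clade = state$clade, internal = state$internal,
    gene_counts = vapply(state$genomes, nrow, 0L),
    genes = do.call(rbind, c(lapply(state$genomes, unclass),
                             list(matrix(numeric(0), 0, length(GENE_COLS))))),
    protein = unlist(state$proteins, use.names = FALSE),
    clades = list(id = state$clades$id, parent = state$clades$parent,
                  origin = state$clades$origin,
                  genotype = lapply(state$clades$genotype, which)),
    history = state$history,
    streams = state$streams)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, na = "null")
  invisible(path)
}

#' Load a population snapshot
#'
#' @param path snapshot written by [save_snapshot()].
#' @return a `population_state`.
#' @export
load_snapshot <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(snap$schema, "evomicro-snapshot-1"))
    stop("unrecognised snapshot schema in ", path)
  config <- config_from_list(snap$config)
  universe <- config$universe
  ids <- universe$metabolites$id
  state <- new.env(parent = emptyenv())
  class(state) <- "population_state"
  state$universe <- universe
  state$dyn <- config$dynamics
  state$mut <- config$mutation
  state$config <- config
  env <- make_environment(universe, snap$env$width, snap$env$height,
                          well_mixed = snap$env$well_mixed,
                          init_pools = "empty")
  env$pools <- matrix(as.numeric(snap$env$pools), env$n_sites, length(ids),
                      dimnames = list(NULL, ids))
  env$occupant <- as.integer(snap$env$occupant)
  state$env <- env
  for (nm in c("step", "epoch", "next_marker", "next_clade", "n_hgt_events",
               "n_discovery_events"))
    assign(nm, as.integer(snap[[nm]]), state)
  state$b_pop <- snap$b_pop
  state$status <- snap$status
  state$site <- as.integer(snap$site)
  state$vol <- as.numeric(snap$vol)
  state$budget <- as.numeric(snap$budget)
  state$etox <- as.numeric(snap$etox)
  state$lifetime <- as.integer(snap$lifetime)
  state$production <- as.numeric(snap$production)
  state$marker <- as.integer(snap$marker)
  state$clade <- as.integer(snap$clade)
  n <- length(state$vol)
  state$internal <- matrix(as.numeric(snap$internal), n, length(ids),
                           dimnames = list(NULL, ids))
  counts <- as.integer(snap$gene_counts)
  genes <- matrix(as.numeric(as.matrix(snap$genes)),
                  ncol = length(GENE_COLS))
  colnames(genes) <- GENE_COLS
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  state$genomes <- lapply(seq_len(n), function(i)
    genome(genes[seq2(starts[i], ends[i]), , drop = FALSE]))
  protein <- as.numeric(snap$protein)
  state$proteins <- lapply(seq_len(n), function(i)
    protein[seq2(starts[i], ends[i])])
  state$ode_failed <- logical(n)
  state$ode_h <- if (!is.null(snap$ode_h)) as.numeric(snap$ode_h)
                 else numeric(n)
  state$genotype <- lapply(state$genomes, genotype_bits, universe = universe)
  geno <- lapply(snap$clades$genotype, function(ix) {
    b <- logical(universe$n_reactions); b[as.integer(ix)] <- TRUE; b
  })
  names(geno) <- as.character(snap$clades$id)
  state$clades <- list(id = as.integer(snap$clades$id),
                       parent = as.integer(snap$clades$parent),
                       origin = as.integer(snap$clades$origin),
                       genotype = geno)
  h <- snap$history
  state$history <- list(
    step = as.integer(h$step), pop_size = as.integer(h$pop_size),
    mean_production = as.numeric(h$mean_production),
    mean_genome_len = as.numeric(h$mean_genome_len),
    marker_count = as.integer(h$marker_count), epoch = as.integer(h$epoch),
    gene_freq = if (is.matrix(h$gene_freq))
      lapply(seq_len(nrow(h$gene_freq)), function(i) h$gene_freq[i, ])
    else lapply(h$gene_freq, as.numeric),
    clade_abund = lapply(h$clade_abund, function(x)
      setNames(as.integer(unlist(x)), names(unlist(x)))))
  state$streams <- lapply(snap$streams, as.integer)
  state
}

## Tiny polynomial string fingerprint (hex) for run manifests.
fnv1a <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write run artifacts to a directory
#'
#' Writes the history time series (TSV), Muller edge/population tables
#' (TSV), the clade phylogeny (Newick), a full snapshot (JSON) and, last,
#' a manifest (JSON) listing the file inventory with a configuration hash;
#' the manifest's presence marks a complete write.
#'
#' @param state a `population_state`.
#' @param out_dir output directory (created if needed).
#' @param muller_subsample passed to [build_muller_table()].
#' @return named character vector of written files, invisibly.
#' @export
write_outputs <- function(state, out_dir, muller_subsample = 500L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(timeseries = file.path(out_dir, "timeseries.tsv"),
             muller_edges = file.path(out_dir, "muller_edges.tsv"),
             muller_populations = file.path(out_dir, "muller_populations.tsv"),
             clades = file.path(out_dir, "clades.nwk"),
             snapshot = file.path(out_dir, "snapshot.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write.table(history_frame(state), files["timeseries"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  mt <- build_muller_table(state, subsample = muller_subsample)
  write.table(mt$edges, files["muller_edges"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(mt$populations, files["muller_populations"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(clade_newick(state), files["clades"])
  save_snapshot(state, files["snapshot"])
  cfg_json <- jsonlite::toJSON(config_to_list(state$config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(schema = "evomicro-manifest-1",
                   config_hash = fnv1a(as.character(cfg_json)),
                   seed = state$config$seed, start_step = 0L,
                   end_step = state$step, status = state$status,
                   files = as.list(basename(files[names(files) != "manifest"])))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

## ---- engineered fixture communities -------------------------------------

#' Engineered obligate cross-feeding pair
#'
#' Two hand-parameterised strains over the reference universe, each with
#' the resource-energy topology: strain A imports the resource, degrades it
#' for energy (`R -> M2 + 5 E`), condenses `2 M2 -> B1`, exports B1 and
#' imports B2; strain B mirrors it (producing B2, importing B1). Neither is
#' viable alone (each lacks any route to one building block); together they
#' form an obligate cross-feeding pair.
#'
#' @param universe the reference `metabolic_universe`.
#' @return list with `name`, `description` and `genomes` (named list).
#' @export
make_fixture_crossfeeders <- function(universe = load_reference_universe()) {
  mk <- function(bb_make, bb_import, condense) {
    genome(
      transporter_gene(universe, "R", FALSE, promoter = 2, vmax = 2,
                       ks = 1, ke = 0.5),
      enzyme_gene(universe, conversion = 4L, promoter = 2, vmax = 2, ks = 0.5),
      enzyme_gene(universe, conversion = condense, promoter = 2, vmax = 2,
                  ks = 0.5),
      transporter_gene(universe, bb_import, FALSE, promoter = 2, vmax = 2,
                       ks = 0.5, ke = 0.5),
      transporter_gene(universe, bb_make, TRUE, promoter = 1, vmax = 1,
                       ks = 1, ke = 0.5))
  }
  ## conversion 4 is "R -> M2 + 5 E"; 32 is "2 M2 -> B1"; 33 is "2 M2 -> B2"
  list(name = "obligate_crossfeeders",
       description = paste("Two-strain engineered community with mutual",
                           "obligate building-block exchange"),
       genomes = list(A = mk("B1", "B2", 32L), B = mk("B2", "B1", 33L)))
}

#' Engineered autonomous major strain plus dependent minor
#'
#' The major strain is (nearly) self-sufficient: it imports the resource,
#' degrades it for energy (`R -> M2 + 5 E`), condenses the byproduct into
#' both building blocks and also recycles environmental building blocks.
#' The minor is a B1 specialist: it produces and exports B1 at high
#' capacity but cannot make B2, which it obtains from building blocks the
#' major releases (export surplus and lysis). Removing the major kills the
#' minor; removing the minor leaves the major alive but stripped of its
#' B1 subsidy and of the minor'"'"'s above-average production.
#'
#' @param universe the reference `metabolic_universe`.
#' @return list with `name`, `description` and `genomes` (named list).
#' @export
make_fixture_autonomous <- function(universe = load_reference_universe()) {
  auto <- genome(
    transporter_gene(universe, "R", FALSE, promoter = 2, vmax = 2,
                     ks = 1, ke = 0.5),
    enzyme_gene(universe, conversion = 4L, promoter = 2, vmax = 2, ks = 0.5),
    enzyme_gene(universe, conversion = 33L, promoter = 2, vmax = 2, ks = 0.5),
    enzyme_gene(universe, conversion = 32L, promoter = 0.6, vmax = 0.6,
                ks = 0.5),
    transporter_gene(universe, "B1", FALSE, promoter = 2, vmax = 2,
                     ks = 0.5, ke = 0.5),
    transporter_gene(universe, "B2", TRUE, promoter = 1, vmax = 1,
                     ks = 1, ke = 0.5))
  minor <- genome(
    transporter_gene(universe, "R", FALSE, promoter = 2, vmax = 2,
                     ks = 1, ke = 0.5),
    enzyme_gene(universe, conversion = 4L, promoter = 2, vmax = 2, ks = 0.5),
    enzyme_gene(universe, conversion = 32L, promoter = 2.5, vmax = 2.5,
                ks = 0.5),
    transporter_gene(universe, "B1", TRUE, promoter = 1, vmax = 1,
                     ks = 1, ke = 0.5),
    transporter_gene(universe, "B2", FALSE, promoter = 1, vmax = 1,
                     ks = 0.5, ke = 0.5))
  ## conversions: 4 "R -> M2 + 5 E", 33 "2 M2 -> B2", 32 "2 M2 -> B1"
  list(name = "major_minor",
       description = paste("Nearly autonomous major strain (strong B2,",
                           "weak backup B1 synthesis) plus a B1-specialist",
                           "minor that depends on it for B2"),
       genomes = list(autonomous = auto, satellite = minor))
}

#' Seed a population from fixture genomes
#'
#' Places the strains of a fixture in an alternating (checkerboard-like)
#' pattern over the full grid; all cells of one strain share a lineage
#' marker, so [dependency_test()] can remove a strain by marker.
#'
#' @param fixture a fixture from [make_fixture_crossfeeders()] or
#'   [make_fixture_autonomous()].
#' @param config a [sim_config()]; mutation is typically disabled for
#'   ecology-only assays.
#' @return a `population_state`; marker `i` holds all cells of strain `i`
#'   (in fixture genome order).
#' @export
fixture_population <- function(fixture, config = sim_config()) {
  ns <- length(fixture$genomes)
  state <- build_initial_population(config)
  n <- length(state$vol)
  strain <- ((seq_len(n) - 1L) %% ns) + 1L
  state$genomes <- lapply(strain, function(s)
    fixture$genomes[[s]])
  state$proteins <- lapply(state$genomes, function(g) g[, "promoter"])
  state$marker <- strain
  state$next_marker <- ns + 1L
  state$genotype <- lapply(state$genomes, genotype_bits,
                           universe = state$universe)
  state$clades <- list(id = integer(0), parent = integer(0),
                       origin = integer(0), genotype = list())
  state$next_clade <- 1L
  state$clade <- integer(n)
  for (s in seq_len(ns)) {
    id <- new_clade(state, NA_integer_,
                    genotype_bits(fixture$genomes[[s]], state$universe))
    state$clade[strain == s] <- id
  }
  state$history <- list(step = integer(0), pop_size = integer(0),
                        mean_production = numeric(0),
                        mean_genome_len = numeric(0),
                        marker_count = integer(0), epoch = integer(0),
                        gene_freq = list(), clade_abund = list())
  record_history(state)
  state
}
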