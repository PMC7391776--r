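## Per-time-step scheduler: ODE updates, environment dynamics, stochastic
## death with lysis, lottery reproduction with mutation, HGT / gene
## discovery, renewing lineage markers, clade tracking, and the run loop.
##
## The population state is an environment (mutated in place by the phase
## functions) carrying dense per-cell vectors; cells are compacted after
## deaths so indices 1..n always address living cells.

genotype_bits <- function(genome, universe) {
  bits <- logical(universe$n_reactions)
  if (nrow(genome)) bits[unique(genome[, "reaction"])] <- TRUE
  bits
}

## Evaluate expr drawing from the named per-phase RNG stream.
stream_eval <- function(state, phase, expr) {
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", state$streams[[phase]], envir = globalenv())
  on.exit({
    state$streams[[phase]] <- get(".Random.seed", envir = globalenv())
    if (!is.null(prev)) assign(".Random.seed", prev, envir = globalenv())
  })
  expr
}

new_clade <- function(state, parent, genotype) {
  id <- state$next_clade
  state$next_clade <- id + 1L
  state$clades$id <- c(state$clades$id, id)
  state$clades$parent <- c(state$clades$parent, parent)
  state$clades$origin <- c(state$clades$origin, state$step)
  state$clades$genotype[[as.character(id)]] <- genotype
  id
}

## Register a genotype change of cell i (new clade descending from current).
update_clade <- function(state, i, new_bits) {
  if (identical(new_bits, state$genotype[[i]])) return(invisible(NULL))
  state$clade[i] <- new_clade(state, state$clade[i], new_bits)
  state$genotype[[i]] <- new_bits
  invisible(NULL)
}

#' Build the ancestral population of minimally viable microbes
#'
#' Generates `n_init` genomes, each one importer for the resource plus 5
#' random enzyme genes with uniformly random parameters and random gene
#' order, resampled until the encoded network is viable (see
#' [is_viable_network()]); places one cell per site (filling the grid when
#' `n_init` equals the number of sites) and gives every cell a unique
#' lineage marker and its own root clade.
#'
#' @param config a [sim_config()].
#' @return a `population_state` environment.
#' @export
build_initial_population <- function(config) {
  universe <- config$universe
  env <- make_environment(universe, config$width, config$height,
                          well_mixed = config$well_mixed,
                          init_pools = config$init_pools %||% "empty")
  n <- config$n_init
  if (n > env$n_sites) stop("n_init exceeds number of grid sites")
  state <- new.env(parent = emptyenv())
  class(state) <- "population_state"
  state$universe <- universe
  state$dyn <- config$dynamics
  state$mut <- config$mutation
  state$config <- config
  state$env <- env
  state$step <- 0L
  state$b_pop <- config$init_b_pop
  state$epoch <- 0L
  state$status <- "running"
  state$n_hgt_events <- 0L
  state$n_discovery_events <- 0L
  state$streams <- make_rng_streams(config$seed)

  r_import_idx <- transport_index(universe, universe$resource_id, FALSE)
  stream_eval(state, "init", {
    genomes <- vector("list", n)
    for (i in seq_len(n)) {
      for (try in seq_len(1000L)) {
        enz <- sample.int(universe$n_conversions, 5L)
        if (is_viable_network(c(r_import_idx, enz), universe)) break
        if (try == 1000L) stop("could not sample a viable ancestor genome")
      }
      p <- runif(4, PARAM_MIN, PARAM_MAX)
      genes <- rbind(
        new_gene_row(GTYPE_TRANSPORTER, r_import_idx,
                     match(universe$resource_id, universe$metabolites$id),
                     p[1], p[2], p[3], p[4], 0),
        do.call(rbind, lapply(enz, function(j) {
          q <- runif(3, PARAM_MIN, PARAM_MAX)
          new_gene_row(GTYPE_ENZYME, j, 0, q[1], q[2], q[3], 0, 0)
        })))
      genomes[[i]] <- genome(genes[sample.int(nrow(genes)), , drop = FALSE])
    }
    sites <- if (n == env$n_sites) seq_len(n) else sample.int(env$n_sites, n)
    state$site <- sites
    state$env$occupant[sites] <- seq_len(n)
    state$genomes <- genomes
  })

  ids <- universe$metabolites$id
  init_int <- setNames(numeric(length(ids)), ids)
  init_int[names(config$init_internal)] <- config$init_internal
  state$internal <- matrix(rep(init_int, each = n), n, length(ids),
                           dimnames = list(NULL, ids))
  state$vol <- rep(config$init_vol, n)
  state$budget <- rep(config$init_budget, n)
  state$etox <- numeric(n)
  state$lifetime <- integer(n)
  state$production <- production_rate(init_int[universe$bb_ids[1]],
                                      init_int[universe$bb_ids[2]]) + numeric(n)
  state$proteins <- lapply(state$genomes, function(g) g[, "promoter"])
  state$ode_failed <- logical(n)
  state$marker <- seq_len(n)
  state$next_marker <- n + 1L

  state$clades <- list(id = integer(0), parent = integer(0),
                       origin = integer(0), genotype = list())
  state$next_clade <- 1L
  state$genotype <- lapply(state$genomes, genotype_bits, universe = universe)
  keymap <- new.env(parent = emptyenv())
  state$clade <- integer(n)
  for (i in seq_len(n)) {
    key <- paste(which(state$genotype[[i]]), collapse = ",")
    id <- keymap[[key]]
    if (is.null(id)) {
      id <- new_clade(state, NA_integer_, state$genotype[[i]])
      keymap[[key]] <- id
    }
    state$clade[i] <- id
  }

  state$history <- list(step = integer(0), pop_size = integer(0),
                        mean_production = numeric(0),
                        mean_genome_len = numeric(0),
                        marker_count = integer(0), epoch = integer(0),
                        gene_freq = list(), clade_abund = list())
  record_history(state)
  state
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state: ", length(x$vol), " cells on ", x$env$width, "x",
      x$env$height, " grid, step ", x$step, ", status ", x$status, ">\n",
      sep = "")
  invisible(x)
}

#' Number of living cells
#' @param state a `population_state`.
#' @export
population_size <- function(state) length(state$vol)

## Deep copy (the state is an environment; assays must not disturb the run).
clone_population <- function(state) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE)) assign(nm, get(nm, state), out)
  class(out) <- "population_state"
  out
}

remove_cells <- function(state, idx) {
  if (!length(idx)) return(invisible(state))
  keep <- setdiff(seq_along(state$vol), idx)
  state$env$occupant[state$site[idx]] <- 0L
  state$site <- state$site[keep]
  state$env$occupant[state$site] <- seq_along(keep)
  for (nm in c("vol", "budget", "etox", "lifetime", "production", "marker",
               "clade", "ode_failed"))
    assign(nm, get(nm, state)[keep], state)
  if (!is.null(state$ode_h)) state$ode_h <- state$ode_h[keep]
  state$internal <- state$internal[keep, , drop = FALSE]
  state$genomes <- state$genomes[keep]
  state$proteins <- state$proteins[keep]
  state$genotype <- state$genotype[keep]
  invisible(state)
}

## Phase 1: integrate every occupied site's coupled cell + pool system.
integrate_phase <- function(state, dt = 1) {
  n <- length(state$vol)
  if (n == 0L) return(invisible(state))
  counts <- vapply(state$genomes, nrow, 0L)
  flat <- do.call(rbind, lapply(state$genomes, unclass))
  if (is.null(flat)) flat <- matrix(numeric(0), 0L, length(GENE_COLS))
  starts <- c(0L, cumsum(counts))[seq_len(n)]
  protein <- unlist(state$proteins, use.names = FALSE) %||% numeric(0)
  res <- integrate_cells_cpp(
    internal = state$internal, budget = state$budget, vol = state$vol,
    etox = state$etox, pools = state$env$pools[state$site, , drop = FALSE],
    genes = flat, protein = protein,
    gene_start = as.integer(starts), gene_count = as.integer(counts),
    universe_c = universe_c(state$universe), dyn_r = state$dyn,
    b_pop = state$b_pop, dt = dt, rtol = state$dyn$rtol,
    atol = state$dyn$atol, max_steps = state$dyn$max_ode_steps,
    h_hint = state$ode_h %||% numeric(n))
  state$internal <- res$internal
  state$budget <- res$budget
  state$vol <- res$vol
  state$etox <- res$etox
  state$env$pools[state$site, ] <- res$pools
  state$production <- res$production
  state$ode_failed <- res$failed
  state$ode_h <- res$ode_h
  state$lifetime <- state$lifetime + 1L
  for (i in seq_len(n))
    if (counts[i]) state$proteins[[i]] <-
      res$protein[(starts[i] + 1L):(starts[i] + counts[i])]
  ## EMA of population production (budget-scaling reference)
  a <- 1 / state$dyn$b_pop_window
  state$b_pop <- max((1 - a) * state$b_pop + a * mean(state$production),
                     state$dyn$b_pop_floor %||% 0)
  invisible(state)
}

#' Stochastic death phase
#'
#' Every cell dies with the toxicity-dependent probability of
#' [death_probability()]; cells below the starvation volume (and cells whose
#' integration failed) are marked for death deterministically. Dead cells
#' lyse, releasing their internal metabolites into their site.
#'
#' @param state a `population_state`.
#' @return invisibly, the state; `state$last_deaths` holds the count.
#' @export
death_phase <- function(state) {
  n <- length(state$vol)
  if (n == 0L) return(invisible(state))
  d <- death_probability(state$etox, state$dyn)
  d[state$vol < state$dyn$vol_starve] <- 1
  d[state$ode_failed] <- 1
  u <- stream_eval(state, "death", runif(n))
  dead <- which(u < d)
  if (length(dead)) {
    add <- state$internal[dead, , drop = FALSE] * state$vol[dead] *
      state$config$vol_to_site
    state$env$pools[state$site[dead], ] <-
      state$env$pools[state$site[dead], , drop = FALSE] + add
    remove_cells(state, dead)
  }
  state$last_deaths <- length(dead)
  invisible(state)
}

divide_cell <- function(state, parent, site) {
  state$vol[parent] <- state$vol[parent] / 2
  rep_res <- stream_eval(state, "mutation",
                         replicate_genome(state$genomes[[parent]], state$mut,
                                          state$universe))
  child_genome <- rep_res$genome
  nold <- nrow(state$genomes[[parent]])
  child_protein <- if (nrow(child_genome) == nold) state$proteins[[parent]]
                   else child_genome[, "promoter"]
  j <- length(state$vol) + 1L
  state$site <- c(state$site, site)
  state$env$occupant[site] <- j
  state$vol <- c(state$vol, state$vol[parent])
  state$budget <- c(state$budget, state$budget[parent])
  state$etox <- c(state$etox, 0)
  state$lifetime <- c(state$lifetime, 0L)
  state$production <- c(state$production, state$production[parent])
  state$ode_failed <- c(state$ode_failed, FALSE)
  if (!is.null(state$ode_h))
    state$ode_h <- c(state$ode_h, state$ode_h[parent])
  state$marker <- c(state$marker, state$marker[parent])
  state$internal <- rbind(state$internal, state$internal[parent, ])
  state$genomes[[j]] <- child_genome
  state$proteins[[j]] <- child_protein
  bits <- genotype_bits(child_genome, state$universe)
  if (identical(bits, state$genotype[[parent]])) {
    state$clade <- c(state$clade, state$clade[parent])
    state$genotype[[j]] <- bits
  } else {
    state$clade <- c(state$clade, new_clade(state, state$clade[parent], bits))
    state$genotype[[j]] <- bits
  }
  j
}

#' Lottery reproduction phase
#'
#' Empty sites are processed in shuffled order. For each, the Moore
#' neighbours at or above the division volume compete in a lottery weighted
#' by their current production value, against a "no reproduction"
#' pseudo-entrant whose weight is the population production average (dynamic
#' scaling). The winner divides: volume is halved between parent and
#' offspring, concentrations are unchanged, the genome replicates with
#' mutations, the offspring starts with zero toxic effect and inherits the
#' parent's lineage marker.
#'
#' @param state a `population_state`.
#' @return invisibly, the state; `state$last_births` holds the count.
#' @export
reproduction_phase <- function(state) {
  empty <- which(state$env$occupant == 0L)
  state$last_births <- 0L
  if (!length(empty) || !length(state$vol)) return(invisible(state))
  order <- stream_eval(state, "shuffle",
                       if (length(empty) > 1L) sample(empty) else empty)
  births <- 0L
  for (s in order) {
    occ <- state$env$occupant[state$env$moore[s, ]]
    cand <- unique(occ[occ > 0L])
    cand <- cand[state$vol[cand] >= state$dyn$vol_divide]
    if (!length(cand)) next
    w <- state$production[cand]
    tot <- sum(w) + state$b_pop
    if (tot <= 0) next
    u <- stream_eval(state, "lottery", runif(1)) * tot
    if (u < state$b_pop) next
    winner <- cand[which(u - state$b_pop < cumsum(w))[1]]
    divide_cell(state, winner, s)
    births <- births + 1L
  }
  state$last_births <- births
  invisible(state)
}

#' Horizontal gene transfer and gene discovery phase
#'
#' Each living cell independently copies one gene from a uniformly chosen
#' occupied Moore neighbour with probability `p_hgt`, and appends a randomly
#' parameterised gene drawn uniformly from the universe with probability
#' `p_discovery`. Newly acquired genes start at zero protein concentration.
#'
#' @param state a `population_state`.
#' @return invisibly, the state; `state$last_hgt` holds the transfer count.
#' @export
hgt_and_discovery_phase <- function(state) {
  n <- length(state$vol)
  state$last_hgt <- 0L
  if (n == 0L) return(invisible(state))
  stream_eval(state, "hgt", {
    do_hgt <- if (state$mut$p_hgt > 0) runif(n) < state$mut$p_hgt
              else logical(n)
    do_disc <- if (state$mut$p_discovery > 0) runif(n) < state$mut$p_discovery
               else logical(n)
    for (i in which(do_hgt)) {
      occ <- state$env$occupant[state$env$moore[state$site[i], ]]
      donors <- unique(occ[occ > 0L & occ != i])
      if (!length(donors)) next
      donor <- if (length(donors) == 1L) donors else sample(donors, 1L)
      res <- hgt_copy(state$genomes[[i]], state$genomes[[donor]])
      if (!res$transferred) next
      state$genomes[[i]] <- res$genome
      state$proteins[[i]] <- append(state$proteins[[i]], 0, after = res$at)
      update_clade(state, i, genotype_bits(res$genome, state$universe))
      state$last_hgt <- state$last_hgt + 1L
      state$n_hgt_events <- state$n_hgt_events + 1L
    }
    for (i in which(do_disc)) {
      gene <- discover_gene(state$universe)
      state$genomes[[i]] <- genome(rbind(unclass(state$genomes[[i]]), gene))
      state$proteins[[i]] <- c(state$proteins[[i]], 0)
      update_clade(state, i, genotype_bits(state$genomes[[i]], state$universe))
      state$n_discovery_events <- state$n_discovery_events + 1L
    }
  })
  invisible(state)
}

#' Renew lineage markers when a single marker has fixed
#'
#' If all living cells share one marker (a common ancestor within the
#' current epoch), every cell receives a fresh unique marker and the epoch
#' counter increments.
#'
#' @param state a `population_state`.
#' @export
renew_markers_if_fixed <- function(state) {
  n <- length(state$vol)
  if (n == 0L) return(invisible(state))
  if (length(unique(state$marker)) == 1L) {
    state$marker <- state$next_marker + seq_len(n) - 1L
    state$next_marker <- state$next_marker + n
    state$epoch <- state$epoch + 1L
  }
  invisible(state)
}

record_history <- function(state) {
  h <- state$history
  k <- length(h$step) + 1L
  n <- length(state$vol)
  h$step[k] <- state$step
  h$pop_size[k] <- n
  h$mean_production[k] <- if (n) mean(state$production) else 0
  h$mean_genome_len[k] <- if (n) mean(vapply(state$genomes, nrow, 0L)) else 0
  h$marker_count[k] <- length(unique(state$marker))
  h$epoch[k] <- state$epoch
  h$gene_freq[[k]] <- if (n) Reduce(`+`, state$genotype) / n
                      else numeric(state$universe$n_reactions)
  ab <- table(state$clade)
  h$clade_abund[[k]] <- setNames(as.integer(ab), names(ab))
  state$history <- h
  invisible(state)
}

#' Advance the simulation one time step
#'
#' Sub-step order: (1) ODE integration of every occupied site's coupled
#' cell + local-pool system; (2) environment influx, degradation and
#' diffusion (or well-mixed averaging); (3) stochastic death with lysis;
#' (4) lottery reproduction with mutation; (5) HGT and gene discovery;
#' (6) marker renewal; (7) history recording at the configured cadence.
#'
#' @param state a `population_state`.
#' @return invisibly, the state (modified in place). On extinction
#'   `state$status` becomes `"extinct"`.
#' @export
step_population <- function(state) {
  state$step <- state$step + 1L
  integrate_phase(state)
  state$env <- influx_and_degrade(state$env, state$universe)
  state$env <- diffuse(state$env, state$universe)
  death_phase(state)
  reproduction_phase(state)
  hgt_and_discovery_phase(state)
  if (!isFALSE(state$config$renew_markers)) renew_markers_if_fixed(state)
  if (state$step %% state$config$record_every == 0L) record_history(state)
  if (length(state$vol) == 0L) state$status <- "extinct"
  invisible(state)
}

#' Run a simulation
#'
#' Builds the ancestral population from the configuration and advances it
#' `n_steps` steps or to extinction, recording population size, mean
#' production, genome length, per-reaction gene frequencies, marker counts
#' and clade abundances at the configured cadence.
#'
#' @param config a [sim_config()].
#' @param state optionally, an existing `population_state` to continue.
#' @param n_steps number of steps (defaults to `config$n_steps`).
#' @param progress print a line every `progress` steps (0 = silent).
#' @return the final `population_state` (status `"done"` or `"extinct"`).
#' @export
run_simulation <- function(config = sim_config(), state = NULL,
                           n_steps = NULL, progress = 0L) {
  if (is.null(state)) state <- build_initial_population(config)
  n_steps <- n_steps %||% state$config$n_steps
  for (k in seq_len(n_steps)) {
    step_population(state)
    if (progress > 0L && state$step %% progress == 0L)
      message(sprintf("step %d: %d cells, mean production %.4f",
                      state$step, length(state$vol),
                      if (length(state$vol)) mean(state$production) else 0))
    if (state$status == "extinct") break
  }
  if (state$status != "extinct") state$status <- "done"
  ## make sure the final step is on record
  if (length(state$history$step) == 0L ||
      state$history$step[length(state$history$step)] != state$step)
    record_history(state)
  state
}

#' History time series as a data frame
#'
#' One row per recorded step with population size, mean production, mean
#' genome length, marker count, epoch, and one `freq_<i>` column per
#' canonical reaction.
#'
#' @param state a `population_state`.
#' @export
history_frame <- function(state) {
  h <- state$history
  gf <- do.call(rbind, h$gene_freq)
  colnames(gf) <- paste0("freq_", seq_len(ncol(gf)))
  data.frame(step = h$step, pop_size = h$pop_size,
             mean_production = h$mean_production,
             mean_genome_len = h$mean_genome_len,
             marker_count = h$marker_count, epoch = h$epoch, gf,
             check.names = FALSE)
}
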