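## Single-cell model: Michaelis-Menten transport and catalysis, the biomass
## production budget, logistic volume growth, protein expression, toxicity
## accumulation and the death hazard.

#' Cell dynamics parameters
#'
#' Defaults are chosen so that a randomly parameterised viable ancestor grows
#' to division size within a few time steps:
#' * `g` volume growth rate (1.0) and `s_shrink` volume decay rate (0.01);
#' * `vol_max` maximum volume (1.0), `vol_divide` minimal division volume
#'   (0.5), `vol_starve` starvation threshold (0.05);
#' * `r` intrinsic stochastic death rate (0.03) and `s_tox` the half-effect
#'   scaling of the toxicity hazard (1.0);
#' * `expr_cost` scale of the budget spent on gene expression per unit
#'   promoter strength (0.02), the baseline of the protein-cost axis;
#' * `b_deg` budget decay (0.01) and `prot_deg` protein decay (0.1) per step;
#' * `b_pop_window` horizon (steps) of the exponential moving average of
#'   population production used for budget scaling (100), and `b_pop_floor`
#'   (2e-4), an absolute lower bound on that average: the budget-scaling
#'   reference never falls below the ancestral production scale, so a
#'   population whose production collapses loses spending power, shrinks
#'   and starves rather than idling indefinitely;
#' * `mdiff_mult` multiplier on passive membrane diffusion, which reuses the
#'   per-metabolite environmental diffusion rates (1.0);
#' * `stoich_powers` whether the catalysis rate law raises reactant terms to
#'   their stoichiometric power (default `FALSE`: plain product over distinct
#'   reactants, as in the printed rate law);
#' * `integrator`: `"auto"` (default: explicit embedded Runge-Kutta with a
#'   bounded substep budget, falling back per cell to a linearly implicit
#'   RODAS3 Rosenbrock method when the kinetics are too stiff), or force
#'   `"rk45"` / `"rosenbrock"`;
#' * `rtol`, `atol`, `max_ode_steps` integrator controls.
#'
#' @param ... overrides of the defaults.
#' @return a `dynamics_params` list.
#' @export
dynamics_params <- function(...) {
  p <- list(g = 1.0, s_shrink = 0.01, vol_max = 1.0, vol_divide = 0.5,
            vol_starve = 0.05, r = 0.03, s_tox = 1.0, expr_cost = 0.02,
            b_deg = 0.01, prot_deg = 0.1, b_pop_window = 100,
            b_pop_floor = 2e-4,
            mdiff_mult = 1.0, stoich_powers = FALSE, integrator = "auto",
            rtol = 1e-6, atol = 1e-9, max_ode_steps = 50000L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown dynamics parameter(s): ",
                        paste(bad, collapse = ", "))
  p <- modifyList(p, over)
  num <- unlist(p[c("g", "s_shrink", "vol_max", "vol_divide", "vol_starve",
                    "r", "s_tox", "b_deg", "prot_deg", "b_pop_window")])
  if (any(num <= 0)) stop("dynamics parameters must be positive")
  if (!(p$vol_starve < p$vol_divide && p$vol_divide <= p$vol_max))
    stop("need vol_starve < vol_divide <= vol_max")
  structure(p, class = "dynamics_params")
}

## Flat representation of universe rate data consumed by the C++ core.
universe_c <- function(universe) {
  m <- universe$metabolites
  list(reactant_stoich = universe$reactant_stoich,
       product_stoich = universe$product_stoich,
       degradation = m$degradation,
       diffusion = m$diffusion,
       toxicity = m$toxicity,
       energy_index = match(universe$energy_id, m$id),
       b1_index = match(universe$bb_ids[1], m$id),
       b2_index = match(universe$bb_ids[2], m$id))
}

#' Michaelis-Menten transport rate
#'
#' `v = v_max * [T] * [S]/([S]+K_S) * [E]/([E]+K_E)`, where `[S]` is the
#' external substrate concentration for importers and the internal one for
#' exporters, and `[E]` is the internal energy concentration. One unit of
#' energy is consumed per unit of substrate transported.
#'
#' @param gene a 1-row transporter gene matrix.
#' @param S_conc substrate concentration (side given by direction).
#' @param E_conc internal energy metabolite concentration.
#' @param T_conc transporter protein concentration.
#' @return the transport rate (concentration per time).
#' @export
transport_rate <- function(gene, S_conc, E_conc, T_conc) {
  stopifnot(gene[1, "type"] == GTYPE_TRANSPORTER)
  unname(gene[1, "vmax"] * T_conc *
         (S_conc / (S_conc + gene[1, "ks"])) *
         (E_conc / (E_conc + gene[1, "ke"])))
}

#' Michaelis-Menten catalysis rate
#'
#' `v = v_max * [enzyme] * prod_R [R] / prod_R ([R] + K)` with a single
#' shared Michaelis constant per gene applied to each reactant. With
#' `stoich_powers = TRUE` each reactant factor is raised to its
#' stoichiometric coefficient.
#'
#' @param gene a 1-row enzyme gene matrix.
#' @param reactant_concs named concentrations covering the reaction's
#'   reactants.
#' @param enzyme_conc enzyme protein concentration.
#' @param universe a `metabolic_universe`.
#' @param stoich_powers see [dynamics_params()].
#' @return the catalysis rate.
#' @export
enzyme_rate <- function(gene, reactant_concs, enzyme_conc, universe,
                        stoich_powers = FALSE) {
  stopifnot(gene[1, "type"] == GTYPE_ENZYME)
  cv <- universe$conversions[[gene[1, "reaction"]]]
  K <- gene[1, "ks"]
  num <- 1; den <- 1
  for (m in names(cv$reactants)) {
    conc <- max(0, reactant_concs[[m]])
    pw <- if (stoich_powers) cv$reactants[[m]] else 1
    num <- num * conc ^ pw
    den <- den * (conc + K) ^ pw
  }
  unname(gene[1, "vmax"] * enzyme_conc * num / den)
}

#' Biomass production rate
#'
#' Building blocks are converted to production budget at rate
#' `[B1][B2] / (1 + |B1 - m| + |B2 - m|)` with `m = ([B1]+[B2])/2`, which
#' algebraically equals `[B1][B2] / (1 + |B1 - B2|)`: imbalance between the
#' two essential building blocks is penalised, favouring homeostasis.
#'
#' @param B1_conc,B2_conc internal building block concentrations.
#' @export
production_rate <- function(B1_conc, B2_conc) {
  B1_conc <- pmax(0, B1_conc); B2_conc <- pmax(0, B2_conc)
  (B1_conc * B2_conc) / (1 + abs(B1_conc - B2_conc))
}

#' Budget scaling factor
#'
#' The fraction of budget spendable per unit time, `B / (B + B_pop)`, where
#' `B_pop` is a running (exponential moving) average of population
#' production. This keeps selection pressure as community productivity rises.
#'
#' @param B cell production budget.
#' @param B_pop population production average.
#' @export
budget_scaling <- function(B, B_pop) {
  ifelse(B + B_pop > 0, B / (B + B_pop), 0)
}

#' Toxicity accumulation increment
#'
#' Adds `sum_m max(0, ([m] - tox_m) / tox_m) * dt` over internal
#' metabolites.
#'
#' @param internal named internal concentrations.
#' @param universe a `metabolic_universe`.
#' @param dt time increment.
#' @export
toxic_increment <- function(internal, universe, dt = 1) {
  tox <- universe$metabolites$toxicity
  sum(pmax(0, (internal[universe$metabolites$id] - tox) / tox)) * dt
}

#' Per-step death probability
#'
#' `d = e_tox / (s_tox + e_tox) * (1 - r) + r`: the hazard starts at the
#' intrinsic rate `r` and saturates towards 1 as toxic effects accumulate.
#'
#' @param e_tox accumulated toxic effect (>= 0).
#' @param params a `dynamics_params` list.
#' @export
death_probability <- function(e_tox, params) {
  e_tox / (params$s_tox + e_tox) * (1 - params$r) + params$r
}

#' Construct a cell state
#'
#' @param universe a `metabolic_universe`.
#' @param genome a `genome`.
#' @param vol initial volume.
#' @param budget initial production budget.
#' @param internal named internal concentrations (missing metabolites 0).
#' @param protein per-gene protein concentrations; defaults to promoter
#'   strength (the pre-equilibrated expression level at unit scaling over
#'   the default protein decay).
#' @param marker,clade lineage marker and clade ids.
#' @return a `cell_state` list.
#' @export
cell_state <- function(universe, genome, vol = 0.4, budget = 1,
                       internal = NULL, protein = NULL, marker = 1L,
                       clade = 1L) {
  ids <- universe$metabolites$id
  conc <- setNames(numeric(length(ids)), ids)
  if (!is.null(internal)) conc[names(internal)] <- internal
  if (is.null(protein)) protein <- genome[, "promoter"]
  stopifnot(length(protein) == nrow(genome))
  list(genome = genome, internal = conc, protein = as.numeric(protein),
       budget = budget, vol = vol, e_tox = 0, lifetime = 0L,
       production = production_rate(conc[universe$bb_ids[1]],
                                    conc[universe$bb_ids[2]]),
       marker = as.integer(marker), clade = as.integer(clade))
}

#' Time derivatives of the full cell + local pool state (reference R
#' implementation)
#'
#' Assembles the coupled right-hand side: budget gains production and pays
#' growth and expression costs scaled by [budget_scaling()]; volume follows
#' logistic growth toward `vol_max` minus shrinkage; proteins are expressed
#' at `Pr * B_scaling` and decay/dilute; internal metabolites change through
#' catalysis, active transport, passive membrane diffusion, degradation and
#' dilution, and the building blocks are additionally consumed by
#' production; site pools mirror the membrane fluxes scaled by cell volume.
#' This mirrors the compiled integrator and is used as its cross-check.
#'
#' @param state a `cell_state`.
#' @param pools named external concentrations at the cell's site.
#' @param universe a `metabolic_universe`.
#' @param params a `dynamics_params`.
#' @param b_pop population production average.
#' @return list of derivatives: `internal`, `budget`, `vol`, `e_tox`,
#'   `protein`, `pools`.
#' @export
cell_odes <- function(state, pools, universe, params, b_pop) {
  ids <- universe$metabolites$id
  m <- universe$metabolites
  int <- pmax(state$internal[ids], 0)
  ext <- pmax(pools[ids], 0)
  g <- state$genome
  B <- max(0, state$budget)
  Vol <- state$vol

  Bs <- budget_scaling(B, b_pop)
  prod <- production_rate(int[universe$bb_ids[1]], int[universe$bb_ids[2]])
  volg <- if (Vol > 0) params$g * Vol * (1 - Vol / params$vol_max) * Bs else 0
  dVol <- volg - params$s_shrink * Vol
  dil <- if (Vol > 0) dVol / Vol else 0

  cost_growth <- volg * Bs * B
  cost_expr <- sum(g[, "promoter"]) * Bs * B * params$expr_cost
  dB <- prod - cost_growth - cost_expr - params$b_deg * B - dil * B

  dint <- setNames(numeric(length(ids)), ids)
  dext <- dint
  dint[universe$bb_ids] <- dint[universe$bb_ids] - prod
  dint <- dint - m$degradation * int - dil * state$internal[ids]
  flux <- params$mdiff_mult * m$diffusion * (ext - int)
  dint <- dint + flux
  dext <- dext - flux * Vol

  dprot <- numeric(nrow(g))
  detox <- toxic_increment(int, universe)
  ei <- universe$energy_id
  for (i in seq_len(nrow(g))) {
    P <- max(0, state$protein[i])
    dprot[i] <- g[i, "promoter"] * Bs - params$prot_deg * state$protein[i] -
      dil * state$protein[i]
    if (g[i, "type"] == GTYPE_ENZYME) {
      cv <- universe$conversions[[g[i, "reaction"]]]
      v <- enzyme_rate(g[i, , drop = FALSE], int, P, universe,
                       params$stoich_powers)
      dint[names(cv$reactants)] <- dint[names(cv$reactants)] - cv$reactants * v
      dint[names(cv$products)] <- dint[names(cv$products)] + cv$products * v
    } else {
      s <- ids[g[i, "substrate"]]
      exporting <- g[i, "exporting"] > 0
      S <- if (exporting) int[s] else ext[s]
      v <- transport_rate(g[i, , drop = FALSE], S, int[ei], P)
      if (exporting) {
        dint[s] <- dint[s] - v
        dext[s] <- dext[s] + v * Vol
      } else {
        dint[s] <- dint[s] + v
        dext[s] <- dext[s] - v * Vol
      }
      dint[ei] <- dint[ei] - v
    }
  }
  list(internal = dint, budget = dB, vol = dVol, e_tox = detox,
       protein = dprot, pools = dext)
}

#' Integrate one cell (and its local pools) over one time step
#'
#' Advances the coupled cell + site system with the adaptive embedded
#' Runge-Kutta integrator (relative tolerance 1e-6, absolute 1e-9),
#' clamping concentrations at zero, and returns the net per-metabolite
#' exchange with the environment for conservation bookkeeping.
#'
#' @inheritParams cell_odes
#' @param dt time step.
#' @return list: updated `state`, updated `pools`, `exchange`
#'   (environment loss = cell gain, in pool units), `failed` flag.
#' @export
integrate_cell <- function(state, pools, universe, params, b_pop, dt = 1) {
  ids <- universe$metabolites$id
  g <- state$genome
  res <- integrate_cells_cpp(
    internal = matrix(state$internal[ids], 1L),
    budget = state$budget, vol = state$vol, etox = state$e_tox,
    pools = matrix(pools[ids], 1L),
    genes = unclass(g), protein = state$protein,
    gene_start = 0L, gene_count = nrow(g),
    universe_c = universe_c(universe), dyn_r = params,
    b_pop = b_pop, dt = dt, rtol = params$rtol, atol = params$atol,
    max_steps = params$max_ode_steps, h_hint = numeric(1))
  state$internal <- setNames(res$internal[1, ], ids)
  state$budget <- res$budget[1]
  state$vol <- res$vol[1]
  state$e_tox <- res$etox[1]
  state$protein <- res$protein
  state$production <- res$production[1]
  state$lifetime <- state$lifetime + 1L
  list(state = state, pools = setNames(res$pools[1, ], ids),
       exchange = setNames(res$exchange[1, ], ids),
       failed = res$failed[1])
}
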