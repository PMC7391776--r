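## The toroidal lattice of external metabolite pools: influx, degradation,
## inter-site diffusion (or well-mixed averaging), occupancy and lysis.

## Toroidal neighbour index matrices. Sites are numbered 1..W*H in row-major
## order over 0-based (row, col) coordinates.
neighbour_offsets <- function(width, height, moore) {
  n <- width * height
  r <- rep(0:(height - 1L), each = width)
  c_ <- rep(0:(width - 1L), times = height)
  offs <- if (moore)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  out <- matrix(0L, n, length(offs))
  for (k in seq_along(offs)) {
    rr <- (r + offs[[k]][1]) %% height
    cc <- (c_ + offs[[k]][2]) %% width
    out[, k] <- rr * width + cc + 1L
  }
  out
}

#' Create a lattice environment
#'
#' A `width` x `height` toroidal grid of per-metabolite pools plus an
#' occupancy map. By default the resource pool starts at its influx /
#' degradation steady state (pre-equilibrated medium) and all other pools at
#' zero.
#'
#' @param universe a `metabolic_universe`.
#' @param width,height lattice dimensions (default 45 x 45).
#' @param well_mixed if `TRUE`, the diffusion step replaces every pool by
#'   the global per-metabolite mean (mass-conserving instantaneous mixing).
#' @param init_pools `"steady"` (resource at influx/degradation) or
#'   `"empty"`.
#' @return an `environment_state` list with `pools` (`n_sites` x
#'   `n_metabolites` matrix, amounts per site) and `occupant` (0 = empty).
#' @export
make_environment <- function(universe, width = 45L, height = 45L,
                             well_mixed = FALSE, init_pools = "steady") {
  n <- as.integer(width) * as.integer(height)
  ids <- universe$metabolites$id
  pools <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  if (identical(init_pools, "steady")) {
    ss <- ifelse(universe$metabolites$degradation > 0,
                 universe$metabolites$influx / universe$metabolites$degradation,
                 0)
    pools <- matrix(rep(ss, each = n), n, length(ids),
                    dimnames = list(NULL, ids))
  }
  list(width = as.integer(width), height = as.integer(height),
       n_sites = n, pools = pools, occupant = integer(n),
       well_mixed = isTRUE(well_mixed),
       vn = neighbour_offsets(width, height, moore = FALSE),
       moore = neighbour_offsets(width, height, moore = TRUE))
}

#' Apply influx and degradation to all pools
#'
#' `pools[m] += influx_m * dt` then `pools[m] -= degradation_m * pools[m] *
#' dt`, clamped at zero. With influx off and no cells, each metabolite's
#' grid total decays at its degradation rate; the resource alone has the
#' fixed point `influx / degradation`.
#'
#' @param env an `environment_state`.
#' @param universe a `metabolic_universe`.
#' @param dt time step.
#' @export
influx_and_degrade <- function(env, universe, dt = 1) {
  m <- universe$metabolites
  env$pools <- sweep(env$pools, 2L, m$influx * dt, "+")
  env$pools <- sweep(env$pools, 2L, 1 - m$degradation * dt, "*")
  env$pools[env$pools < 0] <- 0
  env
}

#' Diffuse pools between neighbouring sites
#'
#' Structured mode applies a von Neumann 4-neighbour discrete Laplacian per
#' metabolite at its diffusion rate with toroidal wrap-around; well-mixed
#' mode replaces every pool by the global per-metabolite mean. Both conserve
#' per-metabolite totals.
#'
#' @inheritParams influx_and_degrade
#' @export
diffuse <- function(env, universe, dt = 1) {
  D <- universe$metabolites$diffusion * dt
  if (env$well_mixed) {
    env$pools <- matrix(rep(colMeans(env$pools), each = env$n_sites),
                        env$n_sites, ncol(env$pools),
                        dimnames = dimnames(env$pools))
    return(env)
  }
  if (any(D > 0.25))
    warning("diffusion_rate * dt > 0.25: explicit stencil may be unstable")
  vn <- env$vn
  p <- env$pools
  nb_sum <- p[vn[, 1], ] + p[vn[, 2], ] + p[vn[, 3], ] + p[vn[, 4], ]
  env$pools <- p + sweep(nb_sum - 4 * p, 2L, D, "*")
  env$pools[env$pools < 0] <- 0
  env
}

#' Lyse a dead cell into its site
#'
#' Releases all internal metabolite amounts (`concentration * volume`,
#' converted to pool units with a site volume of 1) into the local pools and
#' clears the site.
#'
#' @inheritParams influx_and_degrade
#' @param cell a `cell_state`.
#' @param site 1-based site index.
#' @param vol_to_site conversion factor from cell volume to site volume.
#' @export
lyse <- function(env, cell, site, universe, vol_to_site = 1) {
  ids <- universe$metabolites$id
  env$pools[site, ] <- env$pools[site, ] +
    cell$internal[ids] * cell$vol * vol_to_site
  env$occupant[site] <- 0L
  env
}

#' Export the lattice state as tabular matrices
#'
#' Writes one `height` x `width` TSV matrix per metabolite (pool amounts)
#' plus `occupancy.tsv` (0 = empty site); rows and columns are 0-based
#' lattice coordinates.
#'
#' @param env an `environment_state`.
#' @param universe a `metabolic_universe`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_grid_snapshot <- function(env, universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- universe$metabolites$id
  files <- character(0)
  as_grid <- function(v) matrix(v, env$height, env$width, byrow = TRUE)
  for (m in ids) {
    f <- file.path(dir, paste0("pool_", m, ".tsv"))
    write.table(as_grid(env$pools[, m]), f, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    files[paste0("pool_", m)] <- f
  }
  f <- file.path(dir, "occupancy.tsv")
  write.table(as_grid(env$occupant), f, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  files["occupancy"] <- f
  invisible(files)
}
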