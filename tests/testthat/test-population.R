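test_that("the ancestral population is minimally viable by construction", {
  cfg <- sim_config(seed = 42, width = 7, height = 7)
  st <- build_initial_population(cfg)
  u <- st$universe
  expect_equal(population_size(st), 49L)
  expect_true(all(vapply(st$genomes, nrow, 0L) == 6L))
  imp_r <- transport_index(u, "R", FALSE)
  for (g in st$genomes) {
    expect_equal(sum(g[, "type"] == 2), 1L)          # exactly one transporter
    expect_true(imp_r %in% g[, "reaction"])           # the resource importer
    expect_true(is_viable_network(unique(g[, "reaction"]), u))
    pars <- g[, c("promoter", "vmax", "ks")]
    expect_true(all(pars >= 0.01 & pars <= 8))
  }
  ## unique markers, full occupancy, one cell per site
  expect_equal(sort(st$marker), 1:49)
  expect_equal(sort(st$site), 1:49)
  expect_equal(st$env$occupant[st$site], seq_len(49L))
})

test_that("identical configs and seeds give identical trajectories", {
  st1 <- small_population(seed = 9, steps = 25)
  st2 <- small_population(seed = 9, steps = 25)
  expect_identical(st1$vol, st2$vol)
  expect_identical(st1$marker, st2$marker)
  expect_identical(st1$internal, st2$internal)
  expect_identical(st1$genomes, st2$genomes)
  expect_identical(history_frame(st1), history_frame(st2))
  st3 <- small_population(seed = 10, steps = 25)
  expect_false(identical(st1$vol, st3$vol))
})

test_that("starving cells always die and survivors keep their toxic load", {
  st <- small_population(steps = 0)   # unique markers 1..n
  n <- population_size(st)
  st$vol[] <- st$dyn$vol_divide
  starve <- 1:5
  st$vol[starve] <- st$dyn$vol_starve / 2
  marked <- st$marker[starve]
  tox <- seq_len(n) * 0.001
  st$etox <- tox
  death_phase(st)
  expect_false(any(marked %in% st$marker))
  ## survivors retain exactly the e_tox they had accumulated
  expect_equal(st$etox, tox[st$marker])
})

test_that("empirical death rate of clean cells is the intrinsic rate", {
  st <- small_population(seed = 13, steps = 0)
  st$etox[] <- 0
  st$vol[] <- 0.4
  deaths <- 0; cellsteps <- 0
  for (k in 1:700) {
    n <- population_size(st)
    if (n < 10) break
    cellsteps <- cellsteps + n
    st$etox[] <- 0
    death_phase(st)
    deaths <- deaths + st$last_deaths
  }
  phat <- deaths / cellsteps
  se <- sqrt(0.03 * 0.97 / cellsteps)
  expect_lt(abs(phat - 0.03), 2.576 * se + 1e-9)
})

test_that("the reproduction lottery weights competitors by production", {
  ## two adjacent parents with production p and 2p compete for one site;
  ## with a negligible pseudo-entrant the win ratio converges to 1:2
  cfg <- sim_config(seed = 20, width = 3, height = 3, n_init = 9,
                    record_every = 1000)
  base <- build_initial_population(cfg)
  evomicro:::remove_cells(base, 4:9)          # keep three cells
  evomicro:::remove_cells(base, 3)            # two competitors remain
  base$vol[] <- 0.9
  base$production <- c(0.001, 0.002)
  base$b_pop <- 1e-9
  base$dyn$b_pop_floor <- 0
  wins <- c(0, 0)
  for (k in 1:3000) {
    s <- evomicro:::clone_population(base)
    s$streams <- evomicro:::make_rng_streams(k)
    reproduction_phase(s)
    if (s$last_births > 0) {
      ## the first appended child belongs to the first lottery's winner
      winner <- s$marker[3]
      wins[match(winner, base$marker)] <- wins[match(winner, base$marker)] + 1
    }
  }
  expect_gt(sum(wins), 2900)   # pseudo-entrant nearly never wins
  expect_gt(binom.test(wins[2], sum(wins), 2 / 3)$p.value, 1e-4)
})

test_that("reproduction halves volume and resets offspring toxicity", {
  st <- small_population(seed = 15, steps = 8)
  i <- which.max(st$vol)
  st$vol[] <- 0.3          # nobody else can divide
  st$vol[i] <- 0.9
  st$etox[i] <- 2.5
  ## free a neighbouring site
  nb <- st$env$moore[st$site[i], ]
  occ <- st$env$occupant[nb[1]]
  if (occ > 0) evomicro:::remove_cells(st, occ)
  i <- which(st$etox == 2.5)
  st$production[i] <- 100  # certain lottery win
  before_marker <- st$marker[i]
  reproduction_phase(st)
  expect_gte(st$last_births, 1L)
  j <- length(st$vol)
  expect_equal(st$vol[j], 0.45)
  expect_equal(st$etox[j], 0)
  expect_equal(st$lifetime[j], 0L)
  expect_equal(st$marker[j], before_marker)
  expect_equal(st$vol[i], 0.45)
  expect_equal(st$etox[i], 2.5)       # parent keeps its toxic load
})

test_that("no reproduction happens without eligible neighbours", {
  st <- small_population(seed = 16, steps = 3)
  st$vol[] <- st$dyn$vol_divide * 0.5
  evomicro:::remove_cells(st, 1:3)
  reproduction_phase(st)
  expect_equal(st$last_births, 0L)
})

test_that("HGT and discovery happen at their configured rates and update clades", {
  st <- small_population(seed = 17, steps = 0,
                         mutation = mutation_params(p_hgt = 0,
                                                    p_discovery = 0))
  hgt_and_discovery_phase(st)
  expect_equal(st$last_hgt, 0L)
  expect_equal(st$n_discovery_events, 0L)
  ## force discovery for every cell: genomes grow by one, clades may split
  st2 <- small_population(seed = 18, steps = 0,
                          mutation = mutation_params(p_discovery = 1,
                                                     p_hgt = 0))
  len0 <- vapply(st2$genomes, nrow, 0L)
  clades0 <- length(st2$clades$id)
  hgt_and_discovery_phase(st2)
  expect_equal(vapply(st2$genomes, nrow, 0L), len0 + 1L)
  expect_equal(vapply(st2$proteins, length, 0L), len0 + 1L)
  expect_gt(length(st2$clades$id), clades0)
  ## forced HGT: every cell with an occupied neighbour gains one gene
  st3 <- small_population(seed = 19, steps = 0,
                          mutation = mutation_params(p_hgt = 1,
                                                     p_discovery = 0))
  len0 <- vapply(st3$genomes, nrow, 0L)
  hgt_and_discovery_phase(st3)
  expect_equal(st3$last_hgt, population_size(st3))
  expect_equal(vapply(st3$genomes, nrow, 0L), len0 + 1L)
})

test_that("markers renew exactly when one lineage fixes", {
  st <- small_population(seed = 21, steps = 2)
  st$marker[] <- c(5L, rep(7L, population_size(st) - 1L))
  epoch0 <- st$epoch
  renew_markers_if_fixed(st)
  expect_equal(st$epoch, epoch0)        # two markers alive: no renewal
  st$marker[] <- 7L
  renew_markers_if_fixed(st)
  expect_equal(st$epoch, epoch0 + 1L)
  expect_equal(length(unique(st$marker)), population_size(st))
  expect_true(all(st$marker >= st$next_marker - population_size(st)))
})

test_that("stepping preserves the occupancy invariant", {
  st <- small_population(seed = 22, steps = 40)
  expect_false(any(duplicated(st$site)))
  occ <- st$env$occupant
  expect_equal(sort(which(occ > 0)), sort(st$site))
  expect_equal(occ[st$site], seq_along(st$site))
})

test_that("runs resume identically from a snapshot", {
  cfg <- sim_config(seed = 23, width = 6, height = 6, record_every = 5)
  st <- build_initial_population(cfg)
  st <- run_simulation(cfg, state = st, n_steps = 12)
  snap <- tempfile(fileext = ".json")
  save_snapshot(st, snap)
  st_cont <- run_simulation(cfg, state = st, n_steps = 8)
  st_re <- load_snapshot(snap)
  st_re <- run_simulation(cfg, state = st_re, n_steps = 8)
  expect_equal(st_re$vol, st_cont$vol, tolerance = 1e-10)
  expect_identical(st_re$marker, st_cont$marker)
  expect_identical(st_re$site, st_cont$site)
  expect_equal(st_re$internal, st_cont$internal, tolerance = 1e-10)
  expect_identical(vapply(st_re$genomes, nrow, 0L),
                   vapply(st_cont$genomes, nrow, 0L))
})

test_that("extinction ends a run gracefully", {
  cfg <- sim_config(seed = 24, width = 4, height = 4,
                    dynamics = dynamics_params(vol_starve = 0.45,
                                               vol_divide = 0.5),
                    init_vol = 0.46)
  st <- build_initial_population(cfg)
  st$vol[] <- 0.1   # below starvation: everyone dies at once
  st <- run_simulation(cfg, state = st, n_steps = 50)
  expect_equal(st$status, "extinct")
  expect_equal(population_size(st), 0L)
})
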