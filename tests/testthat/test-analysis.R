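test_that("metabolic genotypes ignore copy number and parameters", {
  u <- ref_universe
  g1 <- genome(enzyme_gene(u, 4L, 1, 1, 1))
  g3 <- genome(enzyme_gene(u, 4L, 1, 1, 1), enzyme_gene(u, 4L, 5, 2, 3),
               enzyme_gene(u, 4L, 0.5, 0.5, 0.5))
  expect_identical(metabolic_genotype(g1, u), metabolic_genotype(g3, u))
  expect_equal(sum(metabolic_genotype(g3, u)), 1L)
  expect_equal(metabolic_genotype(genome(), u), rep(FALSE, 59))
  ## importer and exporter of one substrate set different bits
  gi <- genome(transporter_gene(u, "B1", FALSE, 1, 1, 1, 1))
  ge <- genome(transporter_gene(u, "B1", TRUE, 1, 1, 1, 1))
  expect_false(identical(metabolic_genotype(gi, u), metabolic_genotype(ge, u)))
  ## gene order is irrelevant
  g <- simple_cell_genome()
  shuffled <- genome(unclass(g)[c(3, 1, 2), , drop = FALSE])
  expect_identical(metabolic_genotype(g, u), metabolic_genotype(shuffled, u))
})

test_that("topology classification follows the energy substrate", {
  u <- ref_universe
  bits <- function(idx) { b <- logical(59); b[idx] <- TRUE; b }
  r_energy <- match("R -> M2 + 5 E", u$labels)
  b_energy <- match("B1 -> M5 + 3 E", u$labels)
  synth <- match("M2 + M5 -> B1", u$labels)
  expect_equal(classify_topology(bits(c(r_energy, synth)), u),
               "resource_energy")
  expect_equal(classify_topology(bits(c(b_energy, synth)), u), "bb_energy")
  expect_equal(classify_topology(bits(c(r_energy, b_energy)), u), "hybrid")
  expect_equal(classify_topology(bits(synth), u), "none")
  ## community frequency vector honours the presence threshold
  freq <- numeric(59)
  freq[r_energy] <- 0.04      # below 5%: not counted
  freq[b_energy] <- 0.6
  expect_equal(classify_topology(freq, u), "bb_energy")
  freq[r_energy] <- 0.06
  expect_equal(classify_topology(freq, u), "hybrid")
})

test_that("community production sums cell production additively", {
  st <- small_population(seed = 25, steps = 4)
  expect_equal(community_production_rate(st), sum(st$production))
  half <- evomicro:::clone_population(st)
  n <- population_size(st)
  evomicro:::remove_cells(half, 1:(n %/% 2))
  rest <- evomicro:::clone_population(st)
  evomicro:::remove_cells(rest, (n %/% 2 + 1):n)
  expect_equal(community_production_rate(half) + community_production_rate(rest),
               community_production_rate(st))
  empty <- evomicro:::clone_population(st)
  evomicro:::remove_cells(empty, 1:n)
  expect_equal(community_production_rate(empty), 0)
})

test_that("gene frequencies are fractions of cells carrying each reaction", {
  st <- small_population(seed = 26, steps = 0)
  m <- gene_frequency_matrix(st)
  expect_true(all(m >= 0 & m <= 1))
  imp_r <- transport_index(st$universe, "R", FALSE)
  expect_equal(unname(m[1, imp_r]), 1)       # every ancestor imports R
  ## a monomorphic population gives a 0/1 row
  mono <- evomicro:::clone_population(st)
  mono$genotype <- rep(mono$genotype[1], population_size(mono))
  evomicro:::record_history(mono)
  m2 <- gene_frequency_matrix(mono)
  expect_true(all(m2[nrow(m2), ] %in% c(0, 1)))
})

test_that("proteome rows are relative investments that pool gene copies", {
  u <- ref_universe
  st <- small_population(seed = 27, steps = 3)
  m <- proteome_matrix(st)
  sums <- rowSums(m)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
  ## hand-built cell: duplicate genes pool into one column
  st$genomes[[1]] <- genome(enzyme_gene(u, 7L, 1, 1, 1),
                            enzyme_gene(u, 7L, 1, 1, 1),
                            enzyme_gene(u, 9L, 1, 1, 1))
  st$proteins[[1]] <- c(0.3, 0.3, 0.4)
  m <- proteome_matrix(st)
  expect_equal(unname(m[1, 7]), 0.6)
  expect_equal(unname(m[1, 9]), 0.4)
  ## a single-gene cell has one unit entry; zero-protein cells are flagged
  st$genomes[[2]] <- genome(enzyme_gene(u, 3L, 1, 1, 1))
  st$proteins[[2]] <- 0.25
  st$genomes[[3]] <- genome()
  st$proteins[[3]] <- numeric(0)
  m <- proteome_matrix(st)
  expect_equal(unname(m[2, 3]), 1)
  expect_true(3 %in% attr(m, "zero_rows"))
})

test_that("PCA separates constructed clusters deterministically", {
  set.seed(41)
  m <- rbind(matrix(rnorm(50 * 5, mean = 0, sd = 0.05), 50, 5),
             matrix(rnorm(50 * 5, mean = 0, sd = 0.05) + 2, 50, 5))
  p <- pca_scores(m)
  expect_gt(min(p$scores[51:100, 1]) - max(p$scores[1:50, 1]), 0)
  expect_true(all(diff(pca_scores(m, 5)$explained_variance) <= 1e-12))
  ## sign convention: the largest-magnitude loading is positive
  expect_gt(max(p$loadings[, 1]), 0)
  expect_equal(unname(p$loadings[which.max(abs(p$loadings[, 1])), 1]),
               max(abs(p$loadings[, 1])))
  ## full reconstruction reproduces the centred data
  full <- pca_scores(m, 5)
  rec <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(rec - scale(m, scale = FALSE))), 1e-10)
  ## constant matrix: zero variance, no crash
  z <- pca_scores(matrix(1, 4, 3))
  expect_equal(sum(z$explained_variance), 0)
})

## Hand-built state with a scripted clade history for Muller-table tests.
fake_muller_state <- function() {
  st <- new.env(parent = emptyenv())
  class(st) <- "population_state"
  st$clades <- list(id = 1:3, parent = c(NA, 1L, 2L),
                    origin = c(0L, 0L, 500L),
                    genotype = list())
  pop <- function(a, b, c) {
    out <- c(`1` = a, `2` = b, `3` = c)
    out[out > 0]
  }
  st$history <- list(
    step = c(0L, 500L, 1000L, 1500L),
    pop_size = c(100L, 100L, 100L, 100L),
    mean_production = numeric(4), mean_genome_len = numeric(4),
    marker_count = rep(1L, 4), epoch = rep(0L, 4),
    gene_freq = rep(list(numeric(59)), 4),
    clade_abund = list(pop(100, 0, 0), pop(60, 40, 0),
                       pop(50, 46, 4), pop(50, 46, 4)))
  st
}

test_that("Muller tables conserve population and apply the abundance cutoff", {
  st <- fake_muller_state()
  mt <- build_muller_table(st, subsample = 500, cutoff_frac = 0.05)
  ## clade 3 peaks at 4% of the maximum population: folded into clade 2
  expect_setequal(mt$populations$Identity, c("1", "2"))
  totals <- tapply(mt$populations$Population, mt$populations$Generation, sum)
  expect_true(all(totals == 100))
  at1500 <- mt$populations[mt$populations$Generation == 1500, ]
  expect_equal(at1500$Population[at1500$Identity == "2"], 50)  # 46 + 4
  expect_equal(mt$edges, data.frame(Parent = "1", Identity = "2"))
  ## a single surviving clade yields a flat one-identity series
  st$history$clade_abund <- rep(list(c(`1` = 100L)), 4)
  mt1 <- build_muller_table(st, subsample = 500)
  expect_equal(unique(mt1$populations$Identity), "1")
  expect_true(all(mt1$populations$Population == 100))
})

test_that("the clade phylogeny exports as readable Newick", {
  skip_if_not_installed("ape")
  st <- new.env(parent = emptyenv())
  class(st) <- "population_state"
  st$clades <- list(id = 1:4, parent = c(NA, 1L, 1L, NA),
                    origin = c(0L, 100L, 250L, 0L), genotype = list())
  nwk <- clade_newick(st)
  expect_match(nwk, ";$")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("c2", "c3", "c4"))
})

test_that("dependency assays detect obligate and facultative structure", {
  cfg <- sim_config(seed = 30, width = 10, height = 10, record_every = 50,
                    renew_markers = FALSE,
                    mutation = mutation_params(p_dup = 0, p_del = 0,
                                               p_inv = 0, p_transloc = 0,
                                               p_point = 0, p_discovery = 0,
                                               p_hgt = 0))
  st <- fixture_population(make_fixture_crossfeeders(), cfg)
  st <- run_simulation(cfg, state = st, n_steps = 150)
  expect_true(all(c(1, 2) %in% st$marker))
  expect_error(dependency_test(st, 99), "not present")
  out <- dependency_test(st, 1, max_steps = 800, measure_at = 600)
  ## removing one obligate partner dooms the other
  expect_false(out$survived)
  expect_lte(out$steps_run, 800)
  expect_gt(out$production_before, 0)
  ## the original state is untouched by the assay
  expect_true(all(c(1, 2) %in% st$marker))
  ## no-innovation invariant: mutation off, no clades beyond the removal set
  expect_true(all(names(out$survivor_genotypes) %in%
                  as.character(st$clades$id)))
})

test_that("removing the only lineage empties the world immediately", {
  cfg <- sim_config(seed = 31, width = 5, height = 5, record_every = 50,
                    renew_markers = FALSE)
  st <- build_initial_population(cfg)
  st$marker[] <- 1L
  out <- dependency_test(st, 1, max_steps = 10)
  expect_false(out$survived)
  expect_equal(out$steps_run, 0L)
  expect_equal(out$production_after, 0)
})
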