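test_that("stretch lengths are geometric on {1,2,...}", {
  set.seed(1)
  expect_true(all(sample_stretch_length(1.0, 100) == 1L))
  draws <- sample_stretch_length(0.3, 1e5)
  expect_true(all(draws >= 1L))
  ## E[len] = 1/0.3; SE of the mean ~ 0.0088
  expect_lt(abs(mean(draws) - 1 / 0.3), 0.04)
})

test_that("point mutation changes exactly one parameter and respects bounds", {
  u <- ref_universe
  g <- transporter_gene(u, "B1", FALSE, promoter = 4, vmax = 4, ks = 4, ke = 4)
  set.seed(2)
  for (k in 1:200) {
    m <- point_mutate_parameter(g, u)
    diffs <- sum(m[1, c("promoter", "vmax", "ks", "ke", "exporting")] !=
                 g[1, c("promoter", "vmax", "ks", "ke", "exporting")])
    expect_equal(diffs, 1L)
  }
  ## repeated mutation keeps all parameters in range
  m <- enzyme_gene(u, 1L, promoter = 7.9, vmax = 0.011, ks = 1)
  for (k in 1:2000) m <- point_mutate_parameter(m, u)
  pars <- m[1, c("promoter", "vmax", "ks")]
  expect_true(all(pars >= 0.01 & pars <= 8))
})

test_that("flipping the direction flag retargets the transport reaction", {
  u <- ref_universe
  g <- transporter_gene(u, "M3", FALSE, 1, 1, 1, 1)
  set.seed(3)
  flipped <- FALSE
  for (k in 1:100) {
    m <- point_mutate_parameter(g, u)
    if (m[1, "exporting"] != g[1, "exporting"]) {
      flipped <- TRUE
      expect_equal(unname(m[1, "reaction"]), transport_index(u, "M3", TRUE))
    }
  }
  expect_true(flipped)
})

test_that("replication without mutation is the identity", {
  u <- ref_universe
  par <- simple_cell_genome()
  off <- mutation_params(p_dup = 0, p_del = 0, p_inv = 0, p_transloc = 0,
                         p_point = 0)
  res <- replicate_genome(par, off, u)
  expect_identical(unclass(res$genome), unclass(par))
  expect_length(res$events, 0L)
})

test_that("a forced point mutation marks exactly one gene", {
  u <- ref_universe
  par <- genome(enzyme_gene(u, 5L, 1, 1, 1))
  set.seed(4)
  res <- replicate_genome(par, mutation_params(p_dup = 0, p_del = 0,
                                               p_inv = 0, p_transloc = 0,
                                               p_point = 1), u)
  expect_equal(vapply(res$events, `[[`, "", "type"), "point")
  expect_equal(sum(res$genome[1, c("promoter", "vmax", "ks")] !=
                   par[1, c("promoter", "vmax", "ks")]), 1L)
})

test_that("stretch operators preserve gene content as expected", {
  u <- ref_universe
  par <- genome(do.call(rbind, lapply(1:8, function(j)
    enzyme_gene(u, j, promoter = j / 2, vmax = 1, ks = 1))))
  set.seed(5)
  only <- function(which_op) {
    args <- list(p_dup = 0, p_del = 0, p_inv = 0, p_transloc = 0, p_point = 0)
    args[[which_op]] <- 1
    do.call(mutation_params, args)
  }
  ## duplication: parent genes all present, length grows by stretch size
  res <- replicate_genome(par, only("p_dup"), u)
  expect_gt(nrow(res$genome), nrow(par))
  expect_true(all(par[, "promoter"] %in% res$genome[, "promoter"]))
  ev <- res$events[[1]]
  expect_equal(nrow(res$genome), 8L + ev$end - ev$start + 1L)
  ## deletion: result is a subsequence of the parent
  res <- replicate_genome(par, only("p_del"), u)
  expect_lt(nrow(res$genome), 8L)
  expect_true(all(res$genome[, "promoter"] %in% par[, "promoter"]))
  kept <- match(res$genome[, "promoter"], par[, "promoter"])
  expect_true(all(diff(kept) > 0))
  ## inversion: content unchanged, genes outside the stretch untouched
  res <- replicate_genome(par, only("p_inv"), u)
  expect_equal(sort(res$genome[, "promoter"]), sort(par[, "promoter"]))
  ev <- res$events[[1]]
  out <- setdiff(1:8, ev$start:ev$end)
  expect_equal(res$genome[out, "promoter"], par[out, "promoter"])
  expect_equal(res$genome[ev$start:ev$end, "promoter"],
               rev(par[ev$start:ev$end, "promoter"]))
  ## inverting the same stretch again restores the parent
  g2 <- unclass(res$genome)
  g2[ev$start:ev$end, ] <- g2[rev(ev$start:ev$end), , drop = FALSE]
  expect_identical(g2, unclass(par))
  ## translocation: a permutation of the parent
  res <- replicate_genome(par, only("p_transloc"), u)
  expect_equal(sort(res$genome[, "promoter"]), sort(par[, "promoter"]))
})

test_that("discovered genes cover the universe with in-range parameters", {
  u <- ref_universe
  set.seed(6)
  draws <- lapply(1:5000, function(k) discover_gene(u))
  rxns <- vapply(draws, function(g) g[1, "reaction"], 0)
  pars <- t(vapply(draws, function(g) g[1, c("promoter", "vmax", "ks")],
                   numeric(3)))
  expect_true(all(pars >= 0.01 & pars <= 8))
  trans <- vapply(draws, function(g) g[1, "type"], 0) == 2
  exp_flags <- vapply(draws[trans], function(g) g[1, "exporting"] > 0, TRUE)
  expect_setequal(unique(rxns), 1:59)
  ## among transporter draws the direction follows the importer/exporter split
  expect_gt(binom.test(sum(exp_flags), length(exp_flags), 0.5)$p.value, 1e-4)
})

test_that("horizontal copies are uniform over donor genes", {
  u <- ref_universe
  donor <- genome(do.call(rbind, lapply(1:5, function(j)
    enzyme_gene(u, j, promoter = j, vmax = 1, ks = 1))))
  recipient <- genome(enzyme_gene(u, 10L, 1, 1, 1))
  expect_identical(hgt_copy(recipient, genome())$transferred, FALSE)
  set.seed(7)
  picks <- integer(5)
  sizes <- integer(0)
  for (k in 1:5000) {
    res <- hgt_copy(recipient, donor)
    sizes <- c(sizes, nrow(res$genome))
    new_gene <- res$genome[res$genome[, "reaction"] != 10L, , drop = FALSE]
    picks[new_gene[1, "promoter"]] <- picks[new_gene[1, "promoter"]] + 1L
  }
  expect_true(all(sizes == 2L))
  expect_gt(chisq.test(picks)$p.value, 1e-4)
})

test_that("mutation events reveal metabolic genotype changes", {
  u <- ref_universe
  par <- simple_cell_genome()
  off <- mutation_params(p_point = 0.5, p_del = 0.2, p_dup = 0.2)
  set.seed(8)
  for (k in 1:200) {
    res <- replicate_genome(par, off, u)
    changed <- !identical(metabolic_genotype(res$genome, u),
                          metabolic_genotype(par, u))
    ## genotype can only change when a structural (non-point... except
    ## direction flips) event or a deletion/duplication occurred
    if (length(res$events) == 0L) expect_false(changed)
  }
})
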