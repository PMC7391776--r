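## Analysis procedures: metabolic genotypes, clade (Muller) tables, network
## topology classification, lineage-removal dependency assays, production
## rates, gene-frequency and proteome matrices, PCA.

#' Metabolic genotype of a genome
#'
#' The presence/absence vector over the universe's canonical reaction
#' ordering: bit `i` is set iff at least one gene references reaction `i`.
#' Copy number, promoter strength and kinetic parameters are ignored; the
#' importer and exporter of a substrate map to their distinct transport
#' reaction indices.
#'
#' @param genome a `genome`.
#' @param universe a `metabolic_universe`.
#' @return logical vector of length `universe$n_reactions`.
#' @export
metabolic_genotype <- function(genome, universe) {
  genotype_bits(genome, universe)
}

#' Community production rate
#'
#' Sum of the biomass production rate over all living cells (0 for an empty
#' population).
#'
#' @param state a `population_state`.
#' @export
community_production_rate <- function(state) {
  if (!length(state$vol)) return(0)
  sum(state$production)
}

#' Classify metabolic network topology by energy substrate
#'
#' Applies [energy_substrate_class()] to the conversion reactions present in
#' a genotype (or present at frequency >= `freq_threshold` in a community
#' gene-frequency vector): only resource-degrading energy reactions present
#' gives `resource_energy` (the cross-feeding-associated topology), only
#' building-block-degrading gives `bb_energy` (autonomy-associated), both
#' gives `hybrid`, neither `none`.
#'
#' @param x logical genotype vector or numeric frequency vector over the
#'   canonical reaction ordering.
#' @param universe a `metabolic_universe`.
#' @param freq_threshold community-level presence threshold (default 0.05).
#' @return one of `"resource_energy"`, `"bb_energy"`, `"hybrid"`, `"none"`.
#' @export
classify_topology <- function(x, universe, freq_threshold = 0.05) {
  stopifnot(length(x) == universe$n_reactions)
  present <- if (is.logical(x)) x else x >= freq_threshold
  conv <- which(present[seq_len(universe$n_conversions)])
  cls <- energy_substrate_class(universe, conv)
  has_res <- any(cls == "resource_energy")
  has_bb <- any(cls == "bb_energy")
  if (has_res && has_bb) "hybrid"
  else if (has_res) "resource_energy"
  else if (has_bb) "bb_energy"
  else "none"
}

#' Gene frequency matrix over recorded time points
#'
#' One row per (run, recorded step), one column per canonical reaction;
#' entries are the fraction of living cells whose metabolic genotype carries
#' the reaction. This is the input for between-replicate PCA.
#'
#' @param states a `population_state` or list of them.
#' @return numeric matrix with rownames `"<run>:<step>"`.
#' @export
gene_frequency_matrix <- function(states) {
  if (inherits(states, "population_state")) states <- list(states)
  rows <- list()
  for (r in seq_along(states)) {
    h <- states[[r]]$history
    for (k in seq_along(h$step)) {
      rows[[paste0(r, ":", h$step[k])]] <- h$gene_freq[[k]]
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("rxn_", seq_len(ncol(m)))
  m
}

#' Per-cell relative proteome matrix
#'
#' Protein concentrations are pooled by reaction (summing gene copies) and
#' normalised to the cell's total protein concentration, so rows sum to 1
#' for cells with nonzero protein. Zero-protein cells get a zero row and are
#' flagged in the `"zero_rows"` attribute.
#'
#' @param state a `population_state`.
#' @return cells x reactions matrix.
#' @export
proteome_matrix <- function(state) {
  n <- length(state$vol)
  nr <- state$universe$n_reactions
  m <- matrix(0, n, nr, dimnames = list(NULL, paste0("rxn_", seq_len(nr))))
  for (i in seq_len(n)) {
    g <- state$genomes[[i]]
    if (!nrow(g)) next
    for (j in seq_len(nrow(g)))
      m[i, g[j, "reaction"]] <- m[i, g[j, "reaction"]] + state$proteins[[i]][j]
    tot <- sum(m[i, ])
    if (tot > 0) m[i, ] <- m[i, ] / tot
  }
  zero <- which(rowSums(m) == 0)
  attr(m, "zero_rows") <- zero
  m
}

#' Principal component analysis with a deterministic sign convention
#'
#' Centred PCA via [stats::prcomp()]; each component is flipped so that its
#' largest-magnitude loading is positive. A constant matrix yields zero
#' explained variance without error.
#'
#' @param m numeric matrix (>= 2 rows).
#' @param n_components number of components to return.
#' @return list with `scores`, `loadings`, `explained_variance` (fractions).
#' @export
pca_scores <- function(m, n_components = 2L) {
  stopifnot(nrow(m) >= 2L)
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  tot <- sum(p$sdev ^ 2)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained_variance = if (tot > 0) (p$sdev ^ 2 / tot)[seq_len(k)]
                            else rep(0, k))
}

## Nearest ancestor of clade `id` within `kept` (NA if none).
nearest_kept_ancestor <- function(clades, id, kept) {
  p <- clades$parent[match(id, clades$id)]
  while (!is.na(p)) {
    if (p %in% kept) return(p)
    p <- clades$parent[match(p, clades$id)]
  }
  NA_integer_
}

#' Build Muller tables from clade tracking
#'
#' Subsamples the recorded clade abundances every `subsample` steps, removes
#' clades whose maximum abundance never reaches `cutoff_frac` of the maximum
#' population size (folding their abundance into the nearest surviving
#' ancestor, or a synthetic `"ancestral"` identity when none survives), and
#' returns the adjacency and population tables in the stacked-nesting
#' convention (each child emerges from its parent).
#'
#' @param state a `population_state` with recorded history.
#' @param subsample sampling interval in steps (default 500).
#' @param cutoff_frac abundance cutoff as a fraction of maximum population
#'   size (default 0.05).
#' @return list with `edges` (`Parent`, `Identity`) and `populations`
#'   (`Generation`, `Identity`, `Population`) data frames.
#' @export
build_muller_table <- function(state, subsample = 500L, cutoff_frac = 0.05) {
  h <- state$history
  if (!length(h$step)) stop("no recorded history")
  sel <- which(h$step %% subsample == 0L)
  if (!length(sel)) sel <- seq_along(h$step)
  max_pop <- max(h$pop_size)
  cutoff <- cutoff_frac * max_pop

  ## max abundance per clade over the sampled records
  peak <- new.env(parent = emptyenv())
  for (k in sel) {
    ab <- h$clade_abund[[k]]
    for (nm in names(ab)) {
      cur <- peak[[nm]] %||% 0L
      if (ab[[nm]] > cur) peak[[nm]] <- ab[[nm]]
    }
  }
  all_ids <- as.integer(ls(peak))
  kept <- all_ids[vapply(as.character(all_ids),
                         function(nm) peak[[nm]] >= cutoff, TRUE)]

  clades <- state$clades
  target <- function(id) {
    if (id %in% kept) return(as.character(id))
    anc <- nearest_kept_ancestor(clades, id, kept)
    if (is.na(anc)) "ancestral" else as.character(anc)
  }
  map <- vapply(as.character(all_ids),
                function(nm) target(as.integer(nm)), "")
  names(map) <- as.character(all_ids)

  pops <- list()
  idents <- unique(c(if ("ancestral" %in% map) "ancestral",
                     as.character(kept)))
  for (k in sel) {
    ab <- h$clade_abund[[k]]
    acc <- setNames(numeric(length(idents)), idents)
    for (nm in names(ab)) acc[[map[[nm]]]] <- acc[[map[[nm]]]] + ab[[nm]]
    pops[[length(pops) + 1L]] <- data.frame(
      Generation = h$step[k], Identity = idents,
      Population = as.numeric(acc), stringsAsFactors = FALSE)
  }
  populations <- do.call(rbind, pops)

  parent_of <- function(id_chr) {
    if (id_chr == "ancestral") return(NA_character_)
    anc <- nearest_kept_ancestor(clades, as.integer(id_chr), kept)
    if (is.na(anc)) {
      if ("ancestral" %in% idents) "ancestral" else NA_character_
    } else as.character(anc)
  }
  edges <- data.frame(Parent = vapply(idents, parent_of, ""),
                      Identity = idents, stringsAsFactors = FALSE)
  edges <- edges[!is.na(edges$Parent), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, populations = populations)
}

#' Export the clade phylogeny as a Newick string
#'
#' Clade ids label the nodes; branch lengths are origin-step differences
#' between child and parent (clades of unknown parentage attach to a
#' synthetic root at step 0).
#'
#' @param state a `population_state`.
#' @return a Newick string (terminated with `;`).
#' @export
clade_newick <- function(state) {
  cl <- state$clades
  kids <- split(cl$id, factor(cl$parent, levels = cl$id))
  roots <- cl$id[is.na(cl$parent)]
  origin <- setNames(cl$origin, cl$id)
  rec <- function(id, parent_origin) {
    ch <- kids[[as.character(id)]]
    bl <- origin[[as.character(id)]] - parent_origin
    lab <- paste0("c", id, ":", bl)
    if (is.null(ch) || !length(ch)) return(lab)
    paste0("(", paste(vapply(ch, rec, "", parent_origin = origin[[as.character(id)]]),
                      collapse = ","), ")", lab)
  }
  if (length(roots) == 1L) {
    paste0(rec(roots, 0L), ";")
  } else {
    paste0("(", paste(vapply(roots, rec, "", parent_origin = 0L),
                      collapse = ","), ")root:0;")
  }
}

#' Lineage-removal dependency assay
#'
#' Removes every cell of one marker lineage (including its internal
#' metabolites, i.e. without lysis), disables all mutation, discovery and
#' HGT, and continues the simulation for at most `max_steps` steps or to
#' extinction. Community production is recorded immediately before removal
#' and, if the population survives, at `measure_at` steps after removal.
#'
#' @param state a `population_state` snapshot (left untouched; the assay
#'   runs on a copy).
#' @param marker lineage marker id to remove.
#' @param max_steps assay cap (default 2000).
#' @param measure_at when to measure post-removal production (default 1500).
#' @return a `dependency_outcome` list: `removed_marker`, `survived`,
#'   `production_before`, `production_after`, `steps_run`,
#'   `survivor_genotypes` (clade abundance table at the end), and the final
#'   assay `state`.
#' @export
dependency_test <- function(state, marker, max_steps = 2000L,
                            measure_at = 1500L) {
  if (!marker %in% state$marker)
    stop("marker ", marker, " not present in the population")
  assay <- clone_population(state)
  assay$mut <- scale_mutation_params(assay$mut, 0)
  cfg <- assay$config; cfg$renew_markers <- FALSE; assay$config <- cfg
  before <- community_production_rate(assay)
  remove_cells(assay, which(assay$marker == marker))
  after <- NA_real_
  steps <- 0L
  while (steps < max_steps && length(assay$vol) > 0L) {
    step_population(assay)
    steps <- steps + 1L
    if (steps == measure_at) after <- community_production_rate(assay)
  }
  survived <- length(assay$vol) > 0L
  if (survived && steps < measure_at) after <- community_production_rate(assay)
  structure(list(removed_marker = marker,
                 survived = survived,
                 production_before = before,
                 production_after = if (survived) after else 0,
                 steps_run = steps,
                 survivor_genotypes = table(assay$clade),
                 state = assay),
            class = "dependency_outcome")
}

#' @export
print.dependency_outcome <- function(x, ...) {
  cat("<dependency assay: removed marker", x$removed_marker, "->",
      if (x$survived) "partner survived" else "partner extinct",
      sprintf("(%d steps)\n", x$steps_run))
  cat(sprintf("  community production before %.4f, after %.4f\n",
              x$production_before, x$production_after))
  invisible(x)
}
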