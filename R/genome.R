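## Evolvable genomes: gene records with kinetic parameters on a linear
## genome, and the mutation operators (stretch duplication / deletion /
## inversion / translocation, point mutation, gene discovery, HGT).

## All evolvable kinetic parameters live in [PARAM_MIN, PARAM_MAX].
PARAM_MIN <- 0.01
PARAM_MAX <- 8

GENE_COLS <- c("type", "reaction", "substrate", "promoter", "vmax",
               "ks", "ke", "exporting")
GTYPE_ENZYME <- 1
GTYPE_TRANSPORTER <- 2

new_gene_row <- function(type, reaction, substrate, promoter, vmax, ks, ke,
                         exporting) {
  m <- matrix(c(type, reaction, substrate, promoter, vmax, ks, ke, exporting),
              nrow = 1L, dimnames = list(NULL, GENE_COLS))
  m
}

#' Construct an enzyme gene
#'
#' @param universe a `metabolic_universe`.
#' @param conversion conversion reaction index (1..n_conversions).
#' @param promoter,vmax,ks kinetic parameters in `[0.01, 8]`: basal
#'   expression rate, maximum catalytic rate and the shared Michaelis
#'   constant applied to each reactant.
#' @return a 1-row gene matrix.
#' @export
enzyme_gene <- function(universe, conversion, promoter, vmax, ks) {
  stopifnot(conversion >= 1L, conversion <= universe$n_conversions)
  check_params(promoter, vmax, ks)
  new_gene_row(GTYPE_ENZYME, conversion, 0, promoter, vmax, ks, 0, 0)
}

#' Construct a transporter gene
#'
#' @inheritParams enzyme_gene
#' @param substrate metabolite symbol (never the energy carrier).
#' @param exporting logical; transport direction.
#' @param ke Michaelis constant for the energy metabolite that powers
#'   transport.
#' @export
transporter_gene <- function(universe, substrate, exporting, promoter, vmax,
                             ks, ke) {
  check_params(promoter, vmax, ks, ke)
  ridx <- transport_index(universe, substrate, exporting)
  sidx <- match(substrate, universe$metabolites$id)
  new_gene_row(GTYPE_TRANSPORTER, ridx, sidx, promoter, vmax, ks, ke,
               as.numeric(exporting))
}

check_params <- function(...) {
  v <- c(...)
  if (any(v < PARAM_MIN | v > PARAM_MAX))
    stop("kinetic parameters must lie in [", PARAM_MIN, ", ", PARAM_MAX, "]",
         call. = FALSE)
  invisible(v)
}

#' Assemble a genome from genes
#'
#' A genome is an ordered matrix of gene rows; it may be empty (a cell with
#' no functional network starves rather than crashes).
#'
#' @param ... 1-row gene matrices (or a single n-row matrix).
#' @return a `genome` matrix.
#' @export
genome <- function(...) {
  parts <- list(...)
  g <- if (length(parts) == 1L && is.matrix(parts[[1]])) parts[[1]]
       else do.call(rbind, parts)
  if (is.null(g)) g <- matrix(numeric(0), 0L, length(GENE_COLS),
                              dimnames = list(NULL, GENE_COLS))
  structure(g, class = c("genome", "matrix", "array"))
}

empty_genome <- function() genome()

genome_size <- function(g) nrow(g)

#' @export
as.data.frame.genome <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$type <- c("enzyme", "transporter")[df$type]
  df$exporting <- df$exporting > 0
  df
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome with", nrow(x), "genes>\n")
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}

#' Sample a mutation stretch length
#'
#' Stretch lengths are geometrically distributed on `{1, 2, ...}` with
#' success parameter `stretch_p` (mean `1/stretch_p`).
#'
#' @param stretch_p geometric parameter in (0, 1].
#' @param n number of draws.
#' @export
sample_stretch_length <- function(stretch_p, n = 1L) {
  stopifnot(stretch_p > 0, stretch_p <= 1)
  rgeom(n, stretch_p) + 1L
}

#' Default mutation parameters
#'
#' Per-replication stretch-operator probabilities (duplication, deletion,
#' inversion, translocation) of 0.001 each with geometric stretch length
#' parameter 0.3; per-gene per-replication point-mutation probability 0.02;
#' per-cell per-time-step gene discovery probability 0.0001 and horizontal
#' gene transfer probability 0.0005.
#'
#' @param ... overrides of the defaults.
#' @return a `mutation_params` list.
#' @export
mutation_params <- function(...) {
  p <- list(p_dup = 0.001, p_del = 0.001, p_inv = 0.001, p_transloc = 0.001,
            stretch_p = 0.3, p_point = 0.02, p_discovery = 0.0001,
            p_hgt = 0.0005)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown mutation parameter(s): ",
                        paste(bad, collapse = ", "))
  p <- modifyList(p, over)
  rates <- unlist(p)
  if (any(rates < 0 | rates > 1)) stop("mutation probabilities must be in [0,1]")
  structure(p, class = "mutation_params")
}

## Scale all mutation, discovery and HGT rates (0 disables evolution, as in
## dependency assays).
scale_mutation_params <- function(params, factor) {
  for (k in c("p_dup", "p_del", "p_inv", "p_transloc", "p_point",
              "p_discovery", "p_hgt"))
    params[[k]] <- params[[k]] * factor
  params
}

## Reflect log(x) into [log PARAM_MIN, log PARAM_MAX].
reflect_param <- function(x) {
  lo <- log(PARAM_MIN); hi <- log(PARAM_MAX)
  width <- hi - lo
  t <- (log(x) - lo) %% (2 * width)
  t <- ifelse(t > width, 2 * width - t, t)
  exp(lo + t)
}

#' Point-mutate one parameter of a gene
#'
#' One evolvable parameter is chosen uniformly (promoter strength, K_S,
#' v_max; plus K_E and the exporting flag for transporters). Numeric
#' parameters are multiplied by a factor drawn log-uniformly from
#' `[1/2, 2]` and reflected back into `[0.01, 8]`; the boolean direction
#' flag flips (which re-targets the gene to the paired transport reaction).
#'
#' @param gene a 1-row gene matrix.
#' @param universe a `metabolic_universe` (needed to remap the transport
#'   reaction index when the direction flips).
#' @return the mutated 1-row gene matrix.
#' @export
point_mutate_parameter <- function(gene, universe) {
  is_transporter <- gene[1, "type"] == GTYPE_TRANSPORTER
  choices <- if (is_transporter) c("promoter", "ks", "ke", "vmax", "exporting")
             else c("promoter", "ks", "vmax")
  par <- sample(choices, 1L)
  if (par == "exporting") {
    newdir <- gene[1, "exporting"] == 0
    gene[1, "exporting"] <- as.numeric(newdir)
    substrate <- universe$metabolites$id[gene[1, "substrate"]]
    gene[1, "reaction"] <- transport_index(universe, substrate, newdir)
  } else {
    factor <- exp(runif(1, log(0.5), log(2)))
    gene[1, par] <- reflect_param(gene[1, par] * factor)
  }
  gene
}

#' Discover a random gene
#'
#' Innovation is modelled as transfer from an external (off-grid) source: a
#' uniformly random reaction from the universe with all parameters drawn
#' uniformly from their evolvable ranges.
#'
#' @param universe a `metabolic_universe`.
#' @return a 1-row gene matrix.
#' @export
discover_gene <- function(universe) {
  ridx <- sample.int(universe$n_reactions, 1L)
  p <- runif(4, PARAM_MIN, PARAM_MAX)
  if (ridx <= universe$n_conversions)
    return(new_gene_row(GTYPE_ENZYME, ridx, 0, p[1], p[2], p[3], 0, 0))
  tr <- universe$transports[universe$transports$index == ridx, ]
  sidx <- match(tr$substrate, universe$metabolites$id)
  new_gene_row(GTYPE_TRANSPORTER, ridx, sidx, p[1], p[2], p[3], p[4],
               as.numeric(tr$direction == "exporter"))
}

#' Copy one gene horizontally from a donor genome
#'
#' A uniformly chosen donor gene is deep-copied and inserted at a uniformly
#' chosen position of the recipient. An empty donor is a no-op.
#'
#' @param recipient,donor `genome` matrices.
#' @return list with the updated `genome`, a `transferred` flag, and `at`,
#'   the position after which the copy was inserted (0 = front).
#' @export
hgt_copy <- function(recipient, donor) {
  if (nrow(donor) == 0L)
    return(list(genome = recipient, transferred = FALSE, at = NA_integer_))
  gene <- donor[sample.int(nrow(donor), 1L), , drop = FALSE]
  at <- sample.int(nrow(recipient) + 1L, 1L) - 1L   # insert after position `at`
  g <- rbind(head(recipient, at), gene,
             if (at < nrow(recipient)) recipient[(at + 1L):nrow(recipient), ,
                                                 drop = FALSE])
  list(genome = genome(g), transferred = TRUE, at = at)
}

## stretch = start..start+len-1, truncated at genome end
draw_stretch <- function(n, stretch_p) {
  start <- sample.int(n, 1L)
  len <- min(sample_stretch_length(stretch_p), n - start + 1L)
  c(start, start + len - 1L)
}

#' Replicate a genome with mutations
#'
#' Applies, independently and in fixed order, stretch duplication, deletion,
#' inversion and translocation (each a Bernoulli draw at its configured
#' per-replication probability, stretch length geometric), then per-gene
#' point mutations. Returns the child genome together with an event log
#' sufficient to decide whether the child's metabolic genotype changed.
#'
#' @param parent a `genome`.
#' @param params a `mutation_params` list.
#' @param universe a `metabolic_universe`.
#' @return list(genome, events); `events` is a list of records with a
#'   `type` field (`duplication`, `deletion`, `inversion`, `translocation`,
#'   `point`).
#' @export
replicate_genome <- function(parent, params, universe) {
  g <- parent
  events <- list()
  push <- function(type, ...) events[[length(events) + 1L]] <<- list(type = type, ...)

  for (op in c("duplication", "deletion", "inversion", "translocation")) {
    p <- switch(op, duplication = params$p_dup, deletion = params$p_del,
                inversion = params$p_inv, translocation = params$p_transloc)
    if (nrow(g) == 0L || p <= 0 || runif(1) >= p) next
    st <- draw_stretch(nrow(g), params$stretch_p)
    idx <- st[1]:st[2]
    if (op == "duplication") {
      g <- rbind(g[seq_len(st[2]), , drop = FALSE], g[idx, , drop = FALSE],
                 if (st[2] < nrow(g)) g[(st[2] + 1L):nrow(g), , drop = FALSE])
    } else if (op == "deletion") {
      g <- g[-idx, , drop = FALSE]
    } else if (op == "inversion") {
      g[idx, ] <- g[rev(idx), , drop = FALSE]
    } else {
      stretch <- g[idx, , drop = FALSE]
      rest <- g[-idx, , drop = FALSE]
      at <- sample.int(nrow(rest) + 1L, 1L) - 1L
      g <- rbind(head(rest, at), stretch,
                 if (at < nrow(rest)) rest[(at + 1L):nrow(rest), , drop = FALSE])
    }
    push(op, start = st[1], end = st[2])
  }

  if (nrow(g) > 0L && params$p_point > 0) {
    hits <- which(runif(nrow(g)) < params$p_point)
    for (i in hits) {
      g[i, ] <- point_mutate_parameter(g[i, , drop = FALSE], universe)
      push("point", gene = i)
    }
  }
  list(genome = genome(g), events = events)
}

#' Draw a random gene for a given reaction with uniform parameters
#' @keywords internal
random_gene_for_reaction <- function(universe, ridx) {
  p <- runif(4, PARAM_MIN, PARAM_MAX)
  if (ridx <= universe$n_conversions)
    return(new_gene_row(GTYPE_ENZYME, ridx, 0, p[1], p[2], p[3], 0, 0))
  tr <- universe$transports[universe$transports$index == ridx, ]
  sidx <- match(tr$substrate, universe$metabolites$id)
  new_gene_row(GTYPE_TRANSPORTER, ridx, sidx, p[1], p[2], p[3], p[4],
               as.numeric(tr$direction == "exporter"))
}
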