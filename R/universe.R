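## Chemistry: metabolites, reactions, the reference universe, procedural
## universe generation, energy-substrate classification and viability.

#' Parse a reaction equation string
#'
#' Equations use the form `"A + 2 B -> C + 3 E"`: integer stoichiometric
#' coefficients precede metabolite symbols, reactants and products are
#' separated by `->`.
#'
#' @param eq character scalar, the equation.
#' @param metabolite_ids valid metabolite symbols.
#' @return list with named integer vectors `reactants` and `products`.
#' @keywords internal
parse_reaction <- function(eq, metabolite_ids) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed reaction equation: ", eq, call. = FALSE)
  parse_side <- function(side) {
    terms <- strsplit(trimws(side), "+", fixed = TRUE)[[1]]
    out <- integer(0)
    for (term in trimws(terms)) {
      m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z][A-Za-z0-9]*)$", term))[[1]]
      if (length(m) == 0L)
        stop("cannot parse term '", term, "' in reaction: ", eq, call. = FALSE)
      coef <- if (m[2] == "") 1L else as.integer(m[2])
      sym <- m[3]
      if (!sym %in% metabolite_ids)
        stop("unknown metabolite '", sym, "' in reaction: ", eq, call. = FALSE)
      out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + coef
    }
    out
  }
  list(reactants = parse_side(sides[1]), products = parse_side(sides[2]))
}

format_side <- function(x) {
  paste(ifelse(x > 1L, paste(x, names(x)), names(x)), collapse = " + ")
}

#' Format a reaction by canonical index
#' @param universe a `metabolic_universe`.
#' @param index canonical reaction index (1-based).
#' @return character label such as `"R -> M2 + 5 E"` or `"import R"`.
#' @export
reaction_label <- function(universe, index) universe$labels[index]

## Construct and validate a metabolic_universe from parts.
build_universe <- function(name, metabolites, conversion_eqs,
                           importers, exporters) {
  ids <- metabolites$id
  stopifnot(!anyDuplicated(ids))
  mclass <- metabolites$mclass
  if (sum(mclass == "resource") != 1L || sum(mclass == "energy") != 1L)
    stop("universe must have exactly one resource and one energy metabolite")
  if (sum(mclass == "building_block") != 2L)
    stop("universe must have exactly two building blocks")
  energy_id <- ids[mclass == "energy"]
  resource_id <- ids[mclass == "resource"]
  if (any(metabolites$influx[ids != resource_id] > 0))
    stop("influx must be restricted to the resource metabolite")

  conversions <- vector("list", length(conversion_eqs))
  n_met <- length(ids)
  rs <- matrix(0, n_met, length(conversion_eqs), dimnames = list(ids, NULL))
  ps <- rs
  for (i in seq_along(conversion_eqs)) {
    rx <- parse_reaction(conversion_eqs[i], ids)
    if (length(intersect(names(rx$reactants), names(rx$products))))
      stop("reactants and products overlap in: ", conversion_eqs[i])
    if (length(rx$reactants) > 2L)
      stop("more than 2 distinct reactants in: ", conversion_eqs[i])
    conversions[[i]] <- list(index = i, reactants = rx$reactants,
                             products = rx$products)
    rs[names(rx$reactants), i] <- rx$reactants
    ps[names(rx$products), i] <- rx$products
  }

  if (energy_id %in% c(importers, exporters))
    stop("the energy metabolite cannot be transported")
  bad <- setdiff(c(importers, exporters), ids)
  if (length(bad)) stop("unknown transport substrate(s): ",
                        paste(bad, collapse = ", "))
  n_conv <- length(conversions)
  transports <- data.frame(
    index = n_conv + seq_len(length(importers) + length(exporters)),
    substrate = c(importers, exporters),
    direction = rep(c("importer", "exporter"),
                    c(length(importers), length(exporters))),
    stringsAsFactors = FALSE)

  labels <- c(
    vapply(conversions, function(cv)
      paste(format_side(cv$reactants), "->", format_side(cv$products)), ""),
    paste(ifelse(transports$direction == "importer", "import", "export"),
          transports$substrate))

  structure(list(
    name = name,
    metabolites = metabolites,
    conversions = conversions,
    transports = transports,
    reactant_stoich = rs,
    product_stoich = ps,
    labels = labels,
    resource_id = resource_id,
    energy_id = energy_id,
    bb_ids = ids[mclass == "building_block"],
    n_conversions = n_conv,
    n_reactions = n_conv + nrow(transports)
  ), class = "metabolic_universe")
}

#' Load the reference chemical universe
#'
#' Reads the packaged 9-metabolite universe: a single resource `R`, two
#' essential building blocks `B1`/`B2`, the energy carrier `E`, five
#' intermediates `M1..M5`, 43 conversion reactions, and an importer and
#' exporter for every non-energy metabolite (59 reactions in all). The
#' canonical reaction ordering (documented in the fixture file) defines the
#' 59-bit metabolic genotype used throughout.
#'
#' @param path optional path to an alternative universe file in the same
#'   schema.
#' @return a `metabolic_universe` object.
#' @examples
#' u <- load_reference_universe()
#' u$n_reactions   # 59
#' @export
load_reference_universe <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_universe.yaml",
                        package = "evomicro", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  need <- c("name", "metabolites", "conversions", "transports")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("universe file ", path, " is missing entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mets <- do.call(rbind, lapply(raw$metabolites, function(m)
    data.frame(id = m$id, mclass = m$class, diffusion = m$diffusion,
               degradation = m$degradation, toxicity = m$toxicity,
               mass = m$mass, influx = m$influx, stringsAsFactors = FALSE)))
  build_universe(raw$name, mets, unlist(raw$conversions),
                 unlist(raw$transports$importers),
                 unlist(raw$transports$exporters))
}

#' @export
print.metabolic_universe <- function(x, ...) {
  cat("<metabolic_universe '", x$name, "'>\n", sep = "")
  cat(" ", nrow(x$metabolites), "metabolites:",
      paste(x$metabolites$id, collapse = " "), "\n")
  cat(" ", x$n_conversions, "conversion reactions,",
      nrow(x$transports), "transport reactions\n")
  invisible(x)
}

#' Canonical index of a transport reaction
#'
#' @param universe a `metabolic_universe`.
#' @param substrate metabolite symbol (never the energy carrier).
#' @param exporting logical; `FALSE` for the importer.
#' @return integer canonical reaction index.
#' @export
transport_index <- function(universe, substrate, exporting) {
  dir <- ifelse(exporting, "exporter", "importer")
  idx <- universe$transports$index[
    match(paste(substrate, dir),
          paste(universe$transports$substrate, universe$transports$direction))]
  if (anyNA(idx)) stop("no transporter for substrate ", substrate)
  idx
}

#' Classify conversion reactions by energy substrate
#'
#' A conversion is an energy reaction when it yields the energy carrier; its
#' topological class is the substrate it degrades: `resource_energy` when the
#' resource is a reactant, `bb_energy` when a building block is, and `none`
#' otherwise (including energy reactions fed by intermediates). The three
#' classes partition every universe's conversions.
#'
#' @param universe a `metabolic_universe`.
#' @param index conversion indices (default all conversions).
#' @return character vector of classes.
#' @export
energy_substrate_class <- function(universe, index = seq_len(universe$n_conversions)) {
  stopifnot(all(index >= 1L & index <= universe$n_conversions))
  vapply(universe$conversions[index], function(cv) {
    if (!universe$energy_id %in% names(cv$products)) return("none")
    if (universe$resource_id %in% names(cv$reactants)) return("resource_energy")
    if (any(universe$bb_ids %in% names(cv$reactants))) return("bb_energy")
    "none"
  }, "")
}

## Metabolites producible from `start` by closing over the given conversions.
reaction_closure <- function(universe, conversion_idx, start) {
  have <- start
  repeat {
    added <- FALSE
    for (i in conversion_idx) {
      cv <- universe$conversions[[i]]
      if (all(names(cv$reactants) %in% have)) {
        new <- setdiff(names(cv$products), have)
        if (length(new)) {
          have <- c(have, new)
          added <- TRUE
        }
      }
    }
    if (!added) return(have)
  }
}

#' Is a reaction set a viable metabolic network?
#'
#' Viability is the initialisation criterion for minimally viable genomes: the
#' set must contain an importer for the resource, and, closing over its
#' conversion reactions starting from the resource alone, both building blocks
#' and the energy carrier must be producible.
#'
#' @param reaction_set integer vector of canonical reaction indices.
#' @param universe a `metabolic_universe`.
#' @return logical scalar.
#' @export
is_viable_network <- function(reaction_set, universe) {
  stopifnot(all(reaction_set >= 1L & reaction_set <= universe$n_reactions))
  r_import <- transport_index(universe, universe$resource_id, exporting = FALSE)
  if (!r_import %in% reaction_set) return(FALSE)
  conv <- reaction_set[reaction_set <= universe$n_conversions]
  have <- reaction_closure(universe, conv, universe$resource_id)
  all(c(universe$bb_ids, universe$energy_id) %in% have)
}

#' Procedurally generate a random chemical universe
#'
#' Builds a universe with the same skeleton as the reference one (one
#' resource, two building blocks, one energy carrier, `n_intermediates`
#' intermediates, an importer/exporter pair per non-energy metabolite) and
#' `n_conversions` random conversion reactions drawn from the same structural
#' families: single-substrate energy-yielding degradations `A -> B + k E`,
#' two-substrate syntheses `A + B -> C`, and condensations `2 A -> B`.
#' Generation is rejected and retried until both building blocks and the
#' energy carrier are reachable from the resource.
#'
#' @param seed integer seed; the same seed reproduces the same universe.
#' @param n_intermediates number of intermediate metabolites (>= 1).
#' @param n_conversions number of conversion reactions (>= 4).
#' @param max_tries rejection-sampling bound.
#' @return a `metabolic_universe`.
#' @export
generate_universe <- function(seed, n_intermediates, n_conversions,
                              max_tries = 500L) {
  stopifnot(n_intermediates >= 1L, n_conversions >= 4L)
  with_seed(seed, {
    ids <- c("R", "B1", "B2", "E", paste0("M", seq_len(n_intermediates)))
    mets <- data.frame(
      id = ids,
      mclass = c("resource", "building_block", "building_block", "energy",
                 rep("intermediate", n_intermediates)),
      diffusion = round(runif(length(ids), 0.01, 0.05), 3),
      degradation = round(10 ^ runif(length(ids), -4, -2), 4),
      toxicity = round(runif(length(ids), 0.04, 0.16), 4),
      mass = 1.0,
      influx = c(0.002, rep(0, length(ids) - 1L)),
      stringsAsFactors = FALSE)
    non_e <- setdiff(ids, "E")

    draw_conversion <- function() {
      kind <- sample(c("energy", "synthesis", "condense"), 1L,
                     prob = c(0.5, 0.35, 0.15))
      if (kind == "energy") {
        a <- sample(non_e, 1L)
        b <- sample(setdiff(non_e, a), 1L)
        k <- sample(1:5, 1L)
        paste0(a, " -> ", b, if (k == 1L) " + E" else paste0(" + ", k, " E"))
      } else if (kind == "synthesis") {
        ab <- sample(non_e, 2L)
        c_ <- sample(setdiff(non_e, ab), 1L)
        paste0(ab[1], " + ", ab[2], " -> ", c_)
      } else {
        a <- sample(non_e, 1L)
        b <- sample(setdiff(non_e, a), 1L)
        paste0("2 ", a, " -> ", b)
      }
    }

    for (try in seq_len(max_tries)) {
      eqs <- character(0)
      guard <- 0L
      while (length(eqs) < n_conversions && guard < 50L * n_conversions) {
        eq <- draw_conversion()
        if (!eq %in% eqs) eqs <- c(eqs, eq)
        guard <- guard + 1L
      }
      if (length(eqs) < n_conversions) next
      uni <- build_universe(sprintf("generated-seed%d", seed), mets, eqs,
                            importers = non_e, exporters = non_e)
      have <- reaction_closure(uni, seq_len(uni$n_conversions), "R")
      if (all(c("B1", "B2", "E") %in% have)) return(uni)
    }
    stop("could not generate a reachable universe (seed = ", seed,
         ") after ", max_tries, " tries", call. = FALSE)
  })
}
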