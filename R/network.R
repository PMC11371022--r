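#' Chemical species of a radiolysis network
#'
#' @param name Species identifier (plain ASCII; e.g. "e_aq", "O2", "ROO").
#' @param initial Initial concentration in mol/L.
#' @param g_value Radiolytic yield in umol/J: species produced per unit
#'   absorbed dose (1 Gy in unit-density medium produces
#'   \code{g_value} umol/L). Zero for purely secondary species.
#' @param description Free-text description.
#' @param resupply_rate First-order relaxation rate (1/s) pulling the
#'   concentration back toward \code{resupply_conc}; models e.g. oxygen
#'   rediffusion from capillaries. Zero disables the term.
#' @param resupply_conc Equilibrium concentration (mol/L) the relaxation
#'   term targets; defaults to \code{initial}.
#' @return A list of class \code{"rk_species"}.
#' @export
species <- function(name, initial = 0, g_value = 0, description = "",
                    resupply_rate = 0, resupply_conc = initial) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_domain("species 'name' must be a non-empty string")
  check_scalar(initial, "initial", nonneg = TRUE)
  check_scalar(g_value, "g_value", nonneg = TRUE)
  check_scalar(resupply_rate, "resupply_rate", nonneg = TRUE)
  check_scalar(resupply_conc, "resupply_conc", nonneg = TRUE)
  structure(list(name = name, initial = initial, g_value = g_value,
                 description = description,
                 resupply_rate = resupply_rate,
                 resupply_conc = resupply_conc),
            class = "rk_species")
}

# parse one side of an equation string like "2 A + B" into
# (names, stoichiometries); an empty side (inert products) gives zero rows
.parse_side <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt))
    return(list(names = character(0), stoich = numeric(0)))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  terms <- terms[nzchar(terms)]
  names <- character(length(terms))
  stoich <- numeric(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i],
                    regexec("^([0-9]+(?:\\.[0-9]+)?\\s+)?(\\S+)$", terms[i]))[[1L]]
    if (length(m) == 0L)
      stop_domain("cannot parse reaction term: '", terms[i], "'")
    stoich[i] <- if (nzchar(trimws(m[2L]))) as.numeric(trimws(m[2L])) else 1
    names[i] <- m[3L]
  }
  # merge duplicates ("A + A" == "2 A")
  agg <- tapply(stoich, names, sum)
  list(names = names(agg), stoich = as.numeric(agg))
}

#' Mass-action reaction
#'
#' Reactions are written as equation strings, e.g. \code{"R + O2 -> ROO"},
#' \code{"2 OH -> H2O2"} or \code{"ROO ->"} (inert products omitted).
#' Only first- and second-order mass-action kinetics are supported;
#' pseudo-first-order constants absorb any implicit excess partner (e.g.
#' the biomolecule pool attacked by the hydroxyl radical).
#'
#' @param equation Equation string with reactants and products separated
#'   by \code{"->"}.
#' @param rate_constant Mass-action rate constant: 1/s for first order,
#'   L/mol/s for second order. Must be positive.
#' @param source Free-text literature tag carried through YAML round trips.
#' @return A list of class \code{"rk_reaction"}.
#' @export
reaction <- function(equation, rate_constant, source = "") {
  parts <- strsplit(equation, "->", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 2L || !grepl("->", equation))
    stop_domain("reaction equation must contain exactly one '->': '",
                equation, "'")
  lhs <- .parse_side(parts[1L])
  rhs <- if (length(parts) == 2L) .parse_side(parts[2L]) else
    list(names = character(0), stoich = numeric(0))
  if (length(lhs$names) == 0L)
    stop_domain("reaction must have at least one reactant: '", equation, "'")
  order <- sum(lhs$stoich)
  if (!order %in% c(1, 2))
    stop_domain("only first- and second-order reactions are supported ",
                "(got order ", order, " in '", equation, "')")
  check_scalar(rate_constant, "rate_constant", positive = TRUE)
  structure(list(equation = equation,
                 reactants = lhs, products = rhs,
                 order = order,
                 rate_constant = rate_constant,
                 source = source),
            class = "rk_reaction")
}

#' Reaction network
#'
#' Validates that every species referenced by a reaction is declared and
#' assembles the stoichiometry needed by the ODE right-hand side.
#'
#' @param species_list List of \code{\link{species}} objects.
#' @param reactions List of \code{\link{reaction}} objects.
#' @return An object of class \code{"reaction_network"}.
#' @export
reaction_network <- function(species_list, reactions = list()) {
  stopifnot(all(vapply(species_list, inherits, logical(1), "rk_species")),
            all(vapply(reactions, inherits, logical(1), "rk_reaction")))
  nm <- vapply(species_list, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_domain("duplicated species names: ",
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (r in reactions) {
    unknown <- setdiff(c(r$reactants$names, r$products$names), nm)
    if (length(unknown))
      stop_domain("reaction '", r$equation, "' references unknown species: ",
                  paste(unknown, collapse = ", "))
  }
  structure(list(species = species_list, reactions = reactions,
                 species_names = nm),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("  species:", paste(x$species_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a reaction network as YAML
#'
#' The YAML layout has a \code{species} block (name, initial, g_value,
#' optional description / resupply fields) and a \code{reactions} block
#' (equation, rate_constant, optional source tag). Reading and writing
#' round-trip.
#'
#' @param path File path.
#' @return \code{read_network_yaml} returns a
#'   \code{\link{reaction_network}}; \code{write_network_yaml} returns
#'   \code{path} invisibly.
#' @export
read_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$species)) stop_domain("network file has no 'species' block")
  num <- function(x, default = 0) {
    # YAML 1.1 reads unsigned exponents ("1.9e10") as strings; coerce
    if (is.null(x)) default else as.numeric(x)
  }
  sp <- lapply(y$species, function(s) {
    species(name = s$name,
            initial = num(s$initial),
            g_value = num(s$g_value),
            description = s$description %||% "",
            resupply_rate = num(s$resupply_rate),
            resupply_conc = num(s$resupply_conc, num(s$initial)))
  })
  rx <- lapply(y$reactions %||% list(), function(r) {
    reaction(equation = r$equation, rate_constant = num(r$rate_constant),
             source = r$source %||% "")
  })
  reaction_network(sp, rx)
}

#' @rdname read_network_yaml
#' @param network A \code{\link{reaction_network}}.
#' @export
write_network_yaml <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  y <- list(
    species = lapply(network$species, function(s) {
      out <- list(name = s$name, initial = s$initial, g_value = s$g_value)
      if (nzchar(s$description)) out$description <- s$description
      if (s$resupply_rate > 0) {
        out$resupply_rate <- s$resupply_rate
        out$resupply_conc <- s$resupply_conc
      }
      out
    }),
    reactions = lapply(network$reactions, function(r) {
      out <- list(equation = r$equation, rate_constant = r$rate_constant)
      if (nzchar(r$source)) out$source <- r$source
      out
    }))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' The canonical nine-species water-radiolysis network
#'
#' The packaged reaction network behind the FLASH normal-tissue sparing
#' model: hydrated electrons, molecular oxygen, hydrogen peroxide,
#' hydroxyl radicals, hydrogen atoms, molecular hydrogen, superoxide,
#' carbon-centred biomolecule radicals R and peroxyl radicals ROO.
#' Primary radiolytic yields and diffusion-limited radical rate constants
#' follow the standard water-radiolysis literature; enzymatic clearance
#' and biomolecule scavenging enter as pseudo-first-order cellular terms,
#' and oxygen rediffusion as a linear relaxation toward the tissue
#' equilibrium concentration. The file the defaults are read from
#' (\code{extdata/radiolysis_network.yaml}) is editable and source-tagged
#' per line.
#'
#' @param path Optional alternative network YAML file.
#' @return A \code{\link{reaction_network}} with exactly the nine species
#'   above.
#' @export
canonical_network <- function(path = system.file("extdata",
                                                 "radiolysis_network.yaml",
                                                 package = "synflash")) {
  read_network_yaml(path)
}

#' ODE right-hand side of an irradiated reaction network
#'
#' Builds the derivative function d[S]/dt = g_S Dr 1[t < D/Dr] +
#' mass-action terms (+ any resupply relaxation), where the radiolytic
#' production term for species S converts its G-value (umol/J) into
#' mol/L/s at the protocol dose rate and switches off once the dose has
#' been delivered.
#'
#' @param network A \code{\link{reaction_network}}.
#' @param protocol An \code{\link{irradiation_protocol}}.
#' @return A function \code{f(t, y)} returning the named derivative
#'   vector, suitable for \pkg{deSolve}.
#' @export
assemble_rhs <- function(network, protocol) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "irradiation_protocol"))
  nm <- network$species_names
  ns <- length(nm)
  # mol/L/s production while the beam is on
  prod_rate <- vapply(network$species, function(s) s$g_value, numeric(1)) *
    1e-6 * protocol$dose_rate
  res_rate <- vapply(network$species, `[[`, numeric(1), "resupply_rate")
  res_conc <- vapply(network$species, `[[`, numeric(1), "resupply_conc")
  t_irr <- protocol$duration

  # precompute index/stoichiometry tables per reaction
  rx <- lapply(network$reactions, function(r) {
    list(ri = match(r$reactants$names, nm), rs = r$reactants$stoich,
         pi = match(r$products$names, nm), ps = r$products$stoich,
         k = r$rate_constant)
  })

  function(t, y) {
    dy <- numeric(ns)
    if (t < t_irr) dy <- dy + prod_rate
    if (any(res_rate > 0))
      dy <- dy + res_rate * (res_conc - y)
    yc <- pmax(y, 0)  # guard mass-action terms against solver undershoot
    for (r in rx) {
      rate <- r$k * prod(yc[r$ri]^r$rs)
      dy[r$ri] <- dy[r$ri] - r$rs * rate
      if (length(r$pi)) dy[r$pi] <- dy[r$pi] + r$ps * rate
    }
    dy
  }
}
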