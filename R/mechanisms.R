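# Declarative kinetic schemes for TdT nucleotide binding/incorporation and their
# compilation to mass-action ODE systems. Units are uM and s throughout:
# unimolecular constants s^-1, bimolecular constants uM^-1 s^-1.

#' Create a species table entry
#'
#' @param name Identifier, unique within a mechanism.
#' @param role One of `"enzyme"`, `"enzyme_primer"`, `"nucleotide"`, `"complex"`,
#'   `"product_complex"`.
#' @param label Free-text label (e.g. `"[E.DNAss.dNTP]1"`).
#' @param n_enzyme,n_primer,n_nucleotide Moiety composition: how many enzyme,
#'   primer and nucleotide units (free, bound or incorporated) the species carries.
#' @return A one-row data frame.
#' @export
species <- function(name, role, label = name,
                    n_enzyme = 0L, n_primer = 0L, n_nucleotide = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  role <- match.arg(role, c("enzyme", "enzyme_primer", "nucleotide",
                            "complex", "product_complex"))
  data.frame(name = name, role = role, label = label,
             n_enzyme = as.integer(n_enzyme), n_primer = as.integer(n_primer),
             n_nucleotide = as.integer(n_nucleotide), stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' A reaction is at most bimolecular on each side. Rate constants are referred
#' to by name (`"k1"`, `"kpol"`, ...) and resolved against a parameter set when
#' the mechanism is compiled; an irreversible reaction has `rate_rev = NA`.
#'
#' @param reactants,products Character vectors of 1 or 2 species names.
#' @param rate_fwd Name of the forward rate constant.
#' @param rate_rev Name of the reverse rate constant, or `NA` for irreversible.
#' @return A list of class `"kin_reaction"`.
#' @export
reaction <- function(reactants, products, rate_fwd, rate_rev = NA_character_) {
  stopifnot(length(reactants) %in% 1:2, length(products) %in% 1:2,
            is.character(rate_fwd), length(rate_fwd) == 1L)
  structure(list(reactants = reactants, products = products,
                 rate_fwd = rate_fwd, rate_rev = rate_rev),
            class = "kin_reaction")
}

#' Assemble and validate a mechanism
#'
#' Checks that species names are unique, that every reaction references declared
#' species, and that every reaction conserves the enzyme, primer and nucleotide
#' moieties encoded in the species composition columns (so the conservation laws
#' returned by [conserved_moieties()] hold analytically under the mass-action
#' ODEs, independent of any solver).
#'
#' @param name Mechanism identifier.
#' @param species_df Row-bound output of [species()].
#' @param reactions List of [reaction()] objects.
#' @param options Named list of the scheme options the mechanism was built with
#'   (kept for lossless serialization).
#' @return An object of class `"mechanism"`.
#' @export
mechanism <- function(name, species_df, reactions, options = list()) {
  if (anyDuplicated(species_df$name))
    stop("species names must be unique within a mechanism")
  for (rx in reactions) {
    unknown <- setdiff(c(rx$reactants, rx$products), species_df$name)
    if (length(unknown))
      stop("reaction references undeclared species: ", paste(unknown, collapse = ", "))
    for (m in c("n_enzyme", "n_primer", "n_nucleotide")) {
      w <- setNames(species_df[[m]], species_df$name)
      if (sum(w[rx$reactants]) != sum(w[rx$products]))
        stop("reaction does not conserve the ", sub("n_", "", m), " moiety: ",
             paste(rx$reactants, collapse = "+"), " -> ",
             paste(rx$products, collapse = "+"))
    }
  }
  structure(list(name = name, species = species_df, reactions = reactions,
                 options = options),
            class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  cat("<mechanism>", x$name, "-", nrow(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (rx in x$reactions) {
    arrow <- if (is.na(rx$rate_rev)) " -> " else " <=> "
    cat("  ", paste(rx$reactants, collapse = " + "), arrow,
        paste(rx$products, collapse = " + "),
        "  [", rx$rate_fwd,
        if (!is.na(rx$rate_rev)) paste0("/", rx$rate_rev) else "", "]\n", sep = "")
  }
  invisible(x)
}

#' Build one of the built-in TdT kinetic schemes
#'
#' Three schemes describe the stopped-flow observations:
#' * `scheme1` (Trp channel, ddNTP with primer): the preformed enzyme-primer
#'   complex binds ddNTP in two reversible stages, then incorporates it
#'   irreversibly (`kpol`); the extended, dideoxy-terminated primer can only
#'   re-bind a second ddNTP (no second chemistry).
#'   `ED + N <=> C1 <=> C2 -> ED1`, plus `ED1 + N <=> C1b`.
#' * `scheme2` (CPy channel, no primer): free enzyme binds the fluorescent
#'   nucleotide in two reversible stages. `E + N <=> X1 <=> X2`.
#' * `scheme3` (CPy channel, with primer): two-stage binding, irreversible
#'   incorporation (`kpol`), then a first-order transformation of the
#'   post-chemistry complex (`kt`) releasing the extended-primer complex, and an
#'   identical second binding/catalysis cycle ending in a doubly extended primer.
#'   `ED + N <=> C1 <=> C2 -> P -> ED1`, then `ED1 + N <=> C1b <=> C2b -> Pb -> ED2`.
#'
#' By default the second cycle re-uses the cycle-1 rate constants (the printed
#' analyses report a single constant per stage); `independent_cycle2 = TRUE`
#' gives cycle 2 its own constants, suffixed `"_2"`.
#'
#' @param name `"scheme1"`, `"scheme2"` or `"scheme3"`.
#' @param second_cycle Include the second nucleotide-binding cycle (schemes 1, 3).
#' @param second_cycle_two_step Scheme 1 only: give the second binding cycle the
#'   conformational (second) binding stage as well.
#' @param binding_only Scheme 1 only: keep only the two reversible binding steps
#'   (the sub-model used for slowly incorporated ddATP, fitted on truncated traces).
#' @param independent_cycle2 Use separate `"_2"`-suffixed rate constants for cycle 2.
#' @return A [mechanism()].
#' @export
build_scheme <- function(name,
                         second_cycle = TRUE,
                         second_cycle_two_step = FALSE,
                         binding_only = FALSE,
                         independent_cycle2 = FALSE) {
  valid <- c("scheme1", "scheme2", "scheme3")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown scheme '", paste(name, collapse = ","),
         "'; valid schemes: ", paste(valid, collapse = ", "))
  opts <- list(second_cycle = second_cycle,
               second_cycle_two_step = second_cycle_two_step,
               binding_only = binding_only,
               independent_cycle2 = independent_cycle2)
  s2 <- function(k) if (independent_cycle2) paste0(k, "_2") else k

  if (name == "scheme2") {
    sp <- rbind(
      species("E",  "enzyme",     "E",            n_enzyme = 1),
      species("N",  "nucleotide", "dCPyTP",       n_nucleotide = 1),
      species("X1", "complex",    "[E.dCPyTP]1",  n_enzyme = 1, n_nucleotide = 1),
      species("X2", "complex",    "[E.dCPyTP]2",  n_enzyme = 1, n_nucleotide = 1))
    rx <- list(reaction(c("E", "N"), "X1", "k1", "k_minus1"),
               reaction("X1", "X2", "k2", "k_minus2"))
    return(mechanism("scheme2", sp, rx, opts))
  }

  # schemes 1 and 3 share the primer-bound first cycle
  sp <- rbind(
    species("ED", "enzyme_primer", "[E.DNAss]", n_enzyme = 1, n_primer = 1),
    species("N",  "nucleotide", "dNTP", n_nucleotide = 1),
    species("C1", "complex", "[E.DNAss.dNTP]1", 1, 1, 1),
    species("C2", "complex", "[E.DNAss.dNTP]2", 1, 1, 1))
  rx <- list(reaction(c("ED", "N"), "C1", "k1", "k_minus1"),
             reaction("C1", "C2", "k2", "k_minus2"))

  if (name == "scheme1") {
    if (binding_only) return(mechanism("scheme1", sp, rx, opts))
    sp <- rbind(sp, species("ED1", "product_complex", "[E.DNAss+1]", 1, 1, 1))
    rx <- c(rx, list(reaction("C2", "ED1", "kpol")))
    if (second_cycle) {
      sp <- rbind(sp, species("C1b", "complex", "[E.DNAss+1.dNTP]1", 1, 1, 2))
      rx <- c(rx, list(reaction(c("ED1", "N"), "C1b", s2("k1"), s2("k_minus1"))))
      if (second_cycle_two_step) {
        sp <- rbind(sp, species("C2b", "complex", "[E.DNAss+1.dNTP]2", 1, 1, 2))
        rx <- c(rx, list(reaction("C1b", "C2b", s2("k2"), s2("k_minus2"))))
      }
    }
    return(mechanism("scheme1", sp, rx, opts))
  }

  # scheme3
  sp <- rbind(sp,
              species("P",   "product_complex", "[E.DNAss+1]*", 1, 1, 1),
              species("ED1", "product_complex", "[E.DNAss+1]",  1, 1, 1))
  rx <- c(rx, list(reaction("C2", "P", "kpol"),
                   reaction("P", "ED1", "kt")))
  if (second_cycle) {
    sp <- rbind(sp,
                species("C1b", "complex", "[E.DNAss+1.dNTP]1", 1, 1, 2),
                species("C2b", "complex", "[E.DNAss+1.dNTP]2", 1, 1, 2),
                species("Pb",  "product_complex", "[E.DNAss+2]*", 1, 1, 2),
                species("ED2", "product_complex", "[E.DNAss+2]",  1, 1, 2))
    rx <- c(rx, list(reaction(c("ED1", "N"), "C1b", s2("k1"), s2("k_minus1")),
                     reaction("C1b", "C2b", s2("k2"), s2("k_minus2")),
                     reaction("C2b", "Pb", s2("kpol")),
                     reaction("Pb", "ED2", s2("kt"))))
  }
  mechanism("scheme3", sp, rx, opts)
}

#' Rate/equilibrium constants for a scheme
#'
#' @param k1 Forward rate of the first binding stage (uM^-1 s^-1).
#' @param k_minus1 Reverse rate of the first stage (s^-1).
#' @param k2,k_minus2 Forward/reverse rates of the conformational second binding
#'   stage (s^-1).
#' @param kpol Irreversible incorporation rate (s^-1); absent for scheme 2.
#' @param kt Post-catalytic complex transformation rate (s^-1); scheme 3 only.
#' @param ... Further named non-negative constants (e.g. `"_2"`-suffixed
#'   independent second-cycle constants).
#' @return Named numeric vector of class `"rate_parameters"`.
#' @export
rate_parameters <- function(k1, k_minus1, k2, k_minus2, kpol = NULL, kt = NULL, ...) {
  p <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2)
  if (!is.null(kpol)) p <- c(p, kpol = kpol)
  if (!is.null(kt)) p <- c(p, kt = kt)
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("extra rate constants must be named")
    p <- c(p, extra)
  }
  if (any(p < 0)) stop("rate constants must be >= 0")
  structure(p, class = "rate_parameters")
}

#' Names of the rate constants a mechanism requires
#' @param m A [mechanism()].
#' @return Character vector of rate-constant names.
#' @export
required_rates <- function(m) {
  nm <- unlist(lapply(m$reactions, function(rx) c(rx$rate_fwd, rx$rate_rev)))
  unique(nm[!is.na(nm)])
}

# Resolve the per-reaction forward/reverse numeric rates for a mechanism,
# erroring with the missing constant's name.
resolve_rates <- function(m, p) {
  need <- required_rates(m)
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing rate constant(s) for ", m$name, ": ",
         paste(missing, collapse = ", "))
  kf <- vapply(m$reactions, function(rx) unname(p[[rx$rate_fwd]]), 0)
  kr <- vapply(m$reactions, function(rx)
    if (is.na(rx$rate_rev)) 0 else unname(p[[rx$rate_rev]]), 0)
  list(kf = kf, kr = kr)
}

#' Compile a mechanism to a mass-action ODE right-hand side
#'
#' Returns a derivative function in the [deSolve::ode()] signature
#' `function(t, y, parms)`. Fluxes are evaluated in compiled code; the state
#' vector is ordered and named as `m$species$name`. Conserved moieties have zero
#' net derivative by construction of the stoichiometry.
#'
#' @param m A [mechanism()].
#' @param p A [rate_parameters()] set covering [required_rates()].
#' @return Function `(t, y, parms) -> list(dy)`.
#' @export
derive_rhs <- function(m, p) {
  k <- resolve_rates(m, p)
  idx <- function(x) match(x, m$species$name)
  pick <- function(which, j) vapply(m$reactions, function(rx) {
    v <- rx[[which]]
    if (length(v) >= j) idx(v[[j]]) else 0L
  }, 0L)
  r1 <- pick("reactants", 1L); r2 <- pick("reactants", 2L)
  p1 <- pick("products", 1L);  p2 <- pick("products", 2L)
  kf <- k$kf; kr <- k$kr
  function(t, y, parms) {
    list(.massaction_deriv(y, r1, r2, p1, p2, kf, kr))
  }
}

#' Conservation laws of a mechanism
#'
#' Returns the enzyme, primer and nucleotide conservation vectors (weights per
#' species); each inner product with the mass-action right-hand side is
#' identically zero. Moieties absent from the mechanism (e.g. primer in
#' scheme 2) are omitted. Nucleotide weights count bound plus incorporated
#' residues, so e.g. the scheme-3 doubly extended primer complex has weight 2.
#'
#' @param m A [mechanism()].
#' @return Named list of named numeric weight vectors.
#' @export
conserved_moieties <- function(m) {
  out <- list()
  for (mo in c("enzyme", "primer", "nucleotide")) {
    w <- setNames(as.numeric(m$species[[paste0("n_", mo)]]), m$species$name)
    w <- w[w != 0]
    if (length(w)) out[[mo]] <- w
  }
  out
}

#' Stepwise and overall equilibrium constants of two-stage binding
#'
#' Computes `K1 = k1/k_minus1` (uM^-1), `K2 = k2/k_minus2` (dimensionless) and
#' the overall dissociation constant of the two-step binding. With the default
#' `"total"` convention the bound pool counts both complexes,
#' `Kd_total = 1/(K1 * (1 + K2))` — the thermodynamically exact overall Kd.
#' `"final"` instead treats only the second complex as bound,
#' `Kd = 1/(K1 * K2)`.
#'
#' @param p A [rate_parameters()] set with positive `k_minus1`, `k_minus2`.
#' @param convention `"total"` (default) or `"final"`.
#' @return List with `K1`, `K2`, `Kd_total` (uM) and the convention used.
#' @export
equilibrium_summary <- function(p, convention = c("total", "final")) {
  convention <- match.arg(convention)
  if (p[["k_minus1"]] <= 0 || p[["k_minus2"]] <= 0)
    stop("undefined equilibrium: k_minus1 and k_minus2 must be > 0")
  K1 <- unname(p[["k1"]] / p[["k_minus1"]])
  K2 <- unname(p[["k2"]] / p[["k_minus2"]])
  Kd <- if (convention == "total") 1 / (K1 * (1 + K2)) else 1 / (K1 * K2)
  list(K1 = K1, K2 = K2, Kd_total = Kd, convention = convention)
}

#' Serialize a mechanism to a plain-text (YAML) config string
#'
#' Built-in schemes are stored as name + options; custom mechanisms store the
#' full species/reaction tables. [mech_from_config()] inverts this losslessly.
#'
#' @param m A [mechanism()].
#' @return A YAML string.
#' @export
mech_to_config <- function(m) {
  builtin <- m$name %in% c("scheme1", "scheme2", "scheme3")
  cfg <- list(scheme = m$name, options = m$options)
  if (!builtin) {
    cfg$species <- lapply(seq_len(nrow(m$species)), function(i)
      as.list(m$species[i, , drop = FALSE]))
    cfg$reactions <- lapply(m$reactions, function(rx)
      list(reactants = as.list(rx$reactants), products = as.list(rx$products),
           rate_fwd = rx$rate_fwd,
           rate_rev = if (is.na(rx$rate_rev)) NULL else rx$rate_rev))
  }
  yaml::as.yaml(cfg)
}

#' Rebuild a mechanism from its config string
#' @param text YAML produced by [mech_to_config()].
#' @return A [mechanism()].
#' @export
mech_from_config <- function(text) {
  cfg <- yaml::yaml.load(text)
  if (cfg$scheme %in% c("scheme1", "scheme2", "scheme3")) {
    return(do.call(build_scheme, c(list(name = cfg$scheme), cfg$options)))
  }
  sp <- do.call(rbind, lapply(cfg$species, function(s)
    species(s$name, s$role, s$label, s$n_enzyme, s$n_primer, s$n_nucleotide)))
  rx <- lapply(cfg$reactions, function(r)
    reaction(unlist(r$reactants), unlist(r$products), r$rate_fwd,
             if (is.null(r$rate_rev)) NA_character_ else r$rate_rev))
  mechanism(cfg$scheme, sp, rx, cfg$options)
}
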