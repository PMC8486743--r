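#' Specify a loss-of-function mutation
#'
#' A LoF mutation empties (or scales down, for partial degrees) the moiety
#' pool of a protein: the conserved total of every conservation law
#' containing the protein is multiplied by `1 - degree`, which is realised
#' as a projection of the initial state (the protein and every species in
#' the supports of those laws are scaled).  Proteins that undergo
#' degradation are not covered by any law; these are fed by a constant
#' generator pool, and their LoF scales the generator's fixed concentration
#' instead (pass `generator`).
#'
#' @param protein species id of the mutated protein.
#' @param degree fraction of function lost, in \[0, 1\]; 1 = complete loss.
#' @param generator optional id of the constant pool species feeding the
#'   protein's synthesis (e.g. a `p53_generator`), for proteins outside
#'   every conservation law.
#' @return object of class `mutation` with `kind = "LoF"`.
#' @export
lof <- function(protein, degree = 1, generator = NULL) {
  stopifnot(is.character(protein), length(protein) == 1L,
            degree >= 0, degree <= 1)
  structure(list(kind = "LoF", protein = protein, degree = degree,
                 generator = generator),
            class = "mutation")
}

#' Specify a gain-of-function mutation
#'
#' A GoF mutation locks a protein in its active state by removing the
#' reactions that deactivate it (for a phosphoprotein: the forward binding
#' to its phosphatase and the catalytic dephosphorylation step).  The
#' reactions to remove are explicit input -- inferring "deactivation" from
#' topology is biologically ambiguous.  At `degree = 1` the rate constants
#' are zeroed and the corresponding columns of S are zeroed; partial
#' degrees scale the rate constants by `1 - degree` so deactivation still
#' runs, only slower.
#'
#' @param protein species id of the mutated protein (bookkeeping only; the
#'   removal is driven by `reactions`).
#' @param reactions character vector of reaction ids to remove; never
#'   include the reverse direction of a reversible deactivation step, or
#'   the conservation structure of the network would change.
#' @param degree fraction of deactivation removed, in \[0, 1\].
#' @return object of class `mutation` with `kind = "GoF"`.
#' @export
gof <- function(protein, reactions, degree = 1) {
  stopifnot(is.character(protein), length(protein) == 1L,
            degree >= 0, degree <= 1)
  if (length(reactions) == 0L)
    stop("GoF requires a nonempty list of deactivation reactions")
  structure(list(kind = "GoF", protein = protein, degree = degree,
                 reactions = as.character(reactions)),
            class = "mutation")
}

#' @export
print.mutation <- function(x, ...) {
  cat(x$kind, " ", x$protein, " (degree ", x$degree, ")", sep = "")
  if (x$kind == "GoF")
    cat(": remove ", paste(x$reactions, collapse = ", "), sep = "")
  if (!is.null(x$generator)) cat(" via generator ", x$generator, sep = "")
  cat("\n")
  invisible(x)
}

#' Apply a loss-of-function mutation to an initial state
#'
#' The network itself is unchanged; only the initial state moves to a
#' different stoichiometric compatibility class.  For conservation-covered
#' proteins every species in the supports of the containing laws is scaled
#' by `1 - degree` (at degree 1 this is the projection that zeroes the
#' mutated protein and all its compounds).  For generator-fed proteins the
#' generator pool's constant concentration is scaled instead.
#'
#' @param x a [crn].
#' @param x0 initial state (defaults to the network's).
#' @param spec a [lof()] mutation.
#' @param laws conservation laws of `x` (computed if missing).
#' @return the new initial state (named numeric vector).
#' @export
apply_lof <- function(x, x0 = initial_state(x), spec,
                      laws = conservation_laws(x)) {
  stopifnot(inherits(spec, "mutation"), spec$kind == "LoF")
  x0 <- as_state(x, x0)
  hit <- which(vapply(laws, function(l) spec$protein %in% l$support,
                      logical(1)))
  if (length(hit) == 0L) {
    if (is.null(spec$generator)) {
      if (!spec$protein %in% x$species$id)
        stop("unknown species '", spec$protein, "'")
      stop("'", spec$protein, "' is not covered by any conservation law; ",
           "if it is fed by a constant pool, pass its generator species ",
           "(lof(..., generator = ...))")
    }
    if (!spec$generator %in% x$species$id)
      stop("generator species '", spec$generator, "' not in network")
    if (!x$species$constant[match(spec$generator, x$species$id)])
      stop("generator species '", spec$generator, "' is not a constant pool")
    x0[spec$generator] <- x0[spec$generator] * (1 - spec$degree)
    return(x0)
  }
  if (length(hit) > 1L)
    warning("'", spec$protein, "' appears in ", length(hit),
            " conservation laws; all of them are emptied")
  supp <- unique(unlist(lapply(laws[hit], `[[`, "support")))
  x0[supp] <- x0[supp] * (1 - spec$degree)
  x0
}

# Rebuild a crn from species/reactions while preserving removed (zeroed)
# S columns recorded on the network.
rebuild_crn <- function(species, reactions, removed = character(0)) {
  net <- crn(species, reactions)
  removed <- intersect(removed, names(net$k))
  if (length(removed)) {
    net$S[, removed] <- 0L
    net$k[removed] <- 0
    net$removed <- removed
  }
  net
}

#' Apply a gain-of-function mutation to a network
#'
#' Scales the rate constants of the listed deactivation reactions by
#' `1 - degree`; at degree 1 the reactions are removed outright (rate zero
#' and S columns zeroed) and the left null space of the modified matrix is
#' checked, in exact arithmetic, to equal that of the original -- removal
#' that changes the conservation structure (typically a reverse partner
#' wrongly included) is a hard error.
#'
#' @param x a [crn].
#' @param spec a [gof()] mutation.
#' @return the modified network.
#' @export
apply_gof <- function(x, spec) {
  stopifnot(inherits(x, "crn"), inherits(spec, "mutation"),
            spec$kind == "GoF")
  unknown <- setdiff(spec$reactions, names(x$k))
  if (length(unknown))
    stop("GoF of '", spec$protein, "': unknown reactions: ",
         paste(unknown, collapse = ", "))
  net <- x
  if (spec$degree >= 1) {
    S_mod <- net$S
    S_mod[, spec$reactions] <- 0L
    # zeroing columns can only enlarge the left null space; equality of
    # ranks is equality of the spaces
    if (rat_rank(S_mod) != rat_rank(net$S))
      stop("removing reaction(s) ",
           paste(spec$reactions, collapse = ", "),
           " changes the conservation-law structure; ",
           "a reverse partner was probably included in the removal list")
    net$S <- S_mod
    net$k[spec$reactions] <- 0
    net$removed <- union(net$removed, spec$reactions)
  } else {
    net$k[spec$reactions] <- net$k[spec$reactions] * (1 - spec$degree)
  }
  for (id in spec$reactions) {
    j <- match(id, names(net$k))
    net$reactions[[j]]$k <- net$k[[j]]
  }
  net
}

#' Apply a batch of mutations
#'
#' All GoF reaction removals are applied to the network and all LoF
#' projections to the initial state.  The result is independent of the
#' order of the specs (they are canonically sorted before application, so
#' permutations give bit-identical output); LoF supports are taken from the
#' conservation laws of the input network, which GoF removals provably
#' preserve.
#'
#' @param x a [crn].
#' @param x0 initial state.
#' @param specs list of [lof()] / [gof()] mutations.
#' @param laws conservation laws of `x` (computed if missing).
#' @return list with elements `crn` and `x0`.
#' @export
apply_mutations <- function(x, x0 = initial_state(x), specs,
                            laws = conservation_laws(x)) {
  stopifnot(inherits(x, "crn"))
  if (length(specs) == 0L)
    return(list(crn = x, x0 = as_state(x, x0)))
  stopifnot(all(vapply(specs, inherits, logical(1), "mutation")))
  kinds <- vapply(specs, `[[`, "", "kind")
  prots <- vapply(specs, `[[`, "", "protein")
  both <- intersect(prots[kinds == "LoF"], prots[kinds == "GoF"])
  if (length(both))
    stop("conflicting LoF and GoF specs on: ", paste(both, collapse = ", "))
  ord <- order(kinds, prots)
  specs <- specs[ord]
  net <- x
  state <- as_state(x, x0)
  for (sp in specs) {
    if (sp$kind == "GoF") net <- apply_gof(net, sp)
    else state <- apply_lof(x, state, sp, laws = laws)
  }
  list(crn = net, x0 = state)
}

#' Specify a competitive-inhibitor drug
#'
#' The drug reversibly binds the free target into an inactive complex,
#' `target + Drug <-> complex`, with fast binding relative to unbinding.
#' The delivered dose is `alpha` times the conserved total of the target's
#' moiety (the paper-style dosing), or an absolute amount via `dose`.
#'
#' @param target species id of the inhibited protein.
#' @param k1f binding rate constant, (nM s)^-1; default 0.5.
#' @param k1r unbinding rate constant, s^-1; default 0.005.
#' @param alpha dose as a fraction (>= 0) of the target moiety's conserved
#'   total; default 1.
#' @param dose optional absolute initial drug concentration (nM),
#'   overriding `alpha`.
#' @param drug_name species id for the free drug (default `"Drug"`).
#' @param complex_name species id of the drug-target complex (default
#'   `<target>_Drug`).
#' @param law when the target sits in several conservation laws, the index
#'   (into the laws list) of the one whose total defines the dose.
#' @return object of class `drug_spec`.
#' @export
drug_spec <- function(target, k1f = 0.5, k1r = 0.005, alpha = 1,
                      dose = NULL, drug_name = "Drug",
                      complex_name = paste0(target, "_Drug"),
                      law = NULL) {
  stopifnot(k1f >= 0, k1r >= 0, alpha >= 0)
  structure(list(target = target, k1f = k1f, k1r = k1r, alpha = alpha,
                 dose = dose, drug_name = drug_name,
                 complex_name = complex_name, law = law),
            class = "drug_spec")
}

#' Add a competitive inhibitor to a network
#'
#' Extends the network with the free drug and the drug-target complex plus
#' the reversible binding pair, and extends the state with the delivered
#' dose (complex starts at 0).  The drugged network gains exactly one new
#' conservation law, `Drug + complex`.
#'
#' @param x a [crn] (possibly already mutated).
#' @param x_start state from which dosing happens, typically the mutated
#'   equilibrium.
#' @param spec a [drug_spec()].
#' @param laws conservation laws of the pre-drug network used to resolve
#'   the target's conserved total (computed if missing).
#' @return list with elements `crn`, `x0` and `dose` (nM delivered).
#' @export
add_drug <- function(x, x_start = initial_state(x), spec,
                     laws = conservation_laws(x)) {
  stopifnot(inherits(x, "crn"), inherits(spec, "drug_spec"))
  x_start <- as_state(x, x_start)
  if (!spec$target %in% x$species$id)
    stop("drug target '", spec$target, "' not in network")
  if (spec$drug_name %in% x$species$id ||
      spec$complex_name %in% x$species$id)
    stop("species '", spec$drug_name, "' / '", spec$complex_name,
         "' already present")
  dose <- spec$dose
  if (is.null(dose)) {
    hit <- which(vapply(laws, function(l) spec$target %in% l$support,
                        logical(1)))
    if (length(hit) == 0L)
      stop("target '", spec$target, "' is in no conservation law; ",
           "supply an absolute dose")
    if (length(hit) > 1L) {
      if (is.null(spec$law))
        stop("target '", spec$target, "' sits in ", length(hit),
             " conservation laws; pick one with drug_spec(law = ...)")
      hit <- spec$law
    }
    ctot <- sum(laws[[hit]]$gamma * x_start)
    dose <- spec$alpha * ctot
  }
  species <- rbind(x$species,
                   data.frame(id = c(spec$drug_name, spec$complex_name),
                              x0 = c(dose, 0), constant = FALSE))
  bind_id <- paste0(spec$complex_name, "_bind")
  unbind_id <- paste0(spec$complex_name, "_unbind")
  reactions <- c(x$reactions, list(
    list(id = bind_id,
         reactants = stats::setNames(c(1L, 1L),
                                     c(spec$target, spec$drug_name)),
         products = stats::setNames(1L, spec$complex_name),
         k = spec$k1f, reverse_of = unbind_id),
    list(id = unbind_id,
         reactants = stats::setNames(1L, spec$complex_name),
         products = stats::setNames(c(1L, 1L),
                                    c(spec$target, spec$drug_name)),
         k = spec$k1r, reverse_of = bind_id)))
  species$x0[match(x$species$id, species$id)] <- unname(x_start)
  net <- rebuild_crn(species, reactions, removed = x$removed)
  list(crn = net, x0 = initial_state(net), dose = dose)
}

#' Wash the drug out of a drugged network
#'
#' Stops the drug action by zeroing the binding rate constant and adds a
#' first-order degradation reaction for the free drug to model its
#' consumption; re-equilibrating from the drugged equilibrium then returns
#' the network to the mutated-cell equilibrium.
#'
#' @param x a drugged [crn] (output of [add_drug()]).
#' @param spec the same [drug_spec()] used to add the drug.
#' @param k_deg degradation rate constant for the free drug, s^-1.  With
#'   `k_deg = 0` drug sequestered in the complex dissociates but free drug
#'   persists; this is flagged with a warning.
#' @return the modified network.
#' @export
washout <- function(x, spec, k_deg = 0.01) {
  stopifnot(inherits(x, "crn"), inherits(spec, "drug_spec"))
  bind_id <- paste0(spec$complex_name, "_bind")
  if (!spec$drug_name %in% x$species$id || !bind_id %in% names(x$k))
    stop("drug '", spec$drug_name, "' is not present in this network")
  if (k_deg == 0)
    warning("k_deg = 0: free drug persists after washout")
  reactions <- x$reactions
  j <- match(bind_id, names(x$k))
  reactions[[j]]$k <- 0
  reactions <- c(reactions, list(
    list(id = paste0(spec$drug_name, "_degradation"),
         reactants = stats::setNames(1L, spec$drug_name),
         products = integer(0),
         k = k_deg, reverse_of = NA_character_)))
  rebuild_crn(x$species, reactions, removed = x$removed)
}

#' Read mutation and drug specifications from a config file
#'
#' YAML or JSON with top-level keys `mutations` (list of `{kind, protein,
#' degree, reactions | generator}`) and `drugs` (list of `{target, k1f,
#' k1r, alpha, dose, drug_name, complex_name}`).  Reaction ids must match
#' the loaded network.
#'
#' @param path config file; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return list with elements `mutations` (list of [lof()]/[gof()]) and
#'   `drugs` (list of [drug_spec()]).
#' @export
read_perturbations <- function(path) {
  if (!file.exists(path)) stop("perturbation file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  muts <- lapply(cfg$mutations, function(m) {
    kind <- tolower(m$kind %||% stop("mutation without 'kind'"))
    degree <- m$degree %||% 1
    if (kind == "lof") lof(m$protein, degree, generator = m$generator)
    else if (kind == "gof") gof(m$protein, unlist(m$reactions), degree)
    else stop("unknown mutation kind '", m$kind, "'")
  })
  drugs <- lapply(cfg$drugs, function(d)
    drug_spec(d$target,
              k1f = d$k1f %||% 0.5, k1r = d$k1r %||% 0.005,
              alpha = d$alpha %||% 1, dose = d$dose,
              drug_name = d$drug_name %||% "Drug",
              complex_name = d$complex_name %||% paste0(d$target, "_Drug"),
              law = d$law))
  list(mutations = muts, drugs = drugs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
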