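#' Construct a chemical reaction network
#'
#' A `crn` bundles a species table, a reaction list with mass-action rate
#' constants, and the derived n x r stoichiometric matrix S so that the
#' dynamics are x' = S v(x, k) with v_j = k_j * prod_i x_i^(reactant
#' stoichiometry of i in j).  Concentrations are in nM, rate constants in
#' s^-1 (first order) or (nM s)^-1 (second order).
#'
#' Reversible reactions are always stored as two irreversible reactions
#' linked through `reverse_of`, so that each direction carries its own rate
#' constant and can be removed independently (as gain-of-function mutations
#' require).  Species flagged `constant` are generator pools whose
#' concentration is held fixed: their rows of S are forced to zero, so they
#' drive fluxes but never change.
#'
#' @param species data.frame with columns `id` (character, unique), `x0`
#'   (numeric, nM, >= 0) and optionally `constant` (logical, default FALSE).
#' @param reactions list of reactions, each a list with fields `id`
#'   (character, unique), `reactants` (named integer vector, positive
#'   stoichiometries; may be empty for pure synthesis), `products` (same; may
#'   be empty for pure degradation), `k` (numeric >= 0) and optionally
#'   `reverse_of` (id of the paired direction, or NA).
#'
#' @return An object of class `crn` with elements `species` (data.frame),
#'   `reactions` (list), `S` (n x r integer matrix, dimnames species x
#'   reactions) and `k` (named numeric vector of length r).
#' @examples
#' net <- crn(
#'   species = data.frame(id = c("A", "B", "C"), x0 = c(1, 1, 0)),
#'   reactions = list(
#'     list(id = "bind",    reactants = c(A = 1, B = 1), products = c(C = 1),
#'          k = 1, reverse_of = "unbind"),
#'     list(id = "unbind",  reactants = c(C = 1), products = c(A = 1, B = 1),
#'          k = 1, reverse_of = "bind")
#'   )
#' )
#' crn_rhs(net, c(1, 1, 0))
#' @export
crn <- function(species, reactions) {
  stopifnot(is.data.frame(species), all(c("id", "x0") %in% names(species)))
  species$id <- as.character(species$id)
  if (anyDuplicated(species$id))
    stop("duplicated species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (any(!is.finite(species$x0)) || any(species$x0 < 0))
    stop("initial concentrations must be finite and >= 0")
  if (is.null(species$constant)) species$constant <- FALSE
  species$constant <- as.logical(species$constant)
  rownames(species) <- NULL

  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rids))
    stop("duplicated reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  n <- nrow(species)
  r <- length(reactions)
  S  <- matrix(0L, n, r, dimnames = list(species$id, rids))
  Rm <- matrix(0L, n, r, dimnames = list(species$id, rids))  # reactant orders
  k  <- numeric(r)
  names(k) <- rids

  for (j in seq_len(r)) {
    rx <- reactions[[j]]
    for (side in c("reactants", "products")) {
      st <- rx[[side]]
      if (length(st) == 0L) next
      if (is.null(names(st)) || any(names(st) == ""))
        stop("reaction '", rx$id, "': ", side, " must be a named vector")
      unknown <- setdiff(names(st), species$id)
      if (length(unknown))
        stop("reaction '", rx$id, "' references unknown species: ",
             paste(unknown, collapse = ", "))
      if (any(st <= 0) || any(st != round(st)))
        stop("reaction '", rx$id, "': stoichiometries must be positive integers")
    }
    if (identical(sort_stoich(rx$reactants), sort_stoich(rx$products)))
      stop("reaction '", rx$id, "': reactants and products are identical")
    if (is.null(rx$k) || is.na(rx$k) || rx$k < 0)
      stop("reaction '", rx$id, "': rate constant missing or negative")
    for (sp in names(rx$reactants)) {
      S[sp, j]  <- S[sp, j] - as.integer(rx$reactants[[sp]])
      Rm[sp, j] <- Rm[sp, j] + as.integer(rx$reactants[[sp]])
    }
    for (sp in names(rx$products))
      S[sp, j] <- S[sp, j] + as.integer(rx$products[[sp]])
    k[j] <- rx$k
    reactions[[j]]$reverse_of <-
      if (is.null(rx$reverse_of) || is.na(rx$reverse_of)) NA_character_
      else as.character(rx$reverse_of)
  }

  # reverse_of must be symmetric between the pair
  for (j in seq_len(r)) {
    rev <- reactions[[j]]$reverse_of
    if (is.na(rev)) next
    jj <- match(rev, rids)
    if (is.na(jj))
      stop("reaction '", rids[j], "': reverse_of names unknown reaction '", rev, "'")
    if (!identical(reactions[[jj]]$reverse_of, rids[j]))
      stop("reverse_of link between '", rids[j], "' and '", rev, "' is not symmetric")
  }

  # constant-pool species never change: zero their rows of S
  S[species$constant, ] <- 0L

  structure(list(species = species, reactions = reactions,
                 S = S, R = Rm, k = k),
            class = "crn")
}

sort_stoich <- function(st) {
  if (length(st) == 0L) return(integer(0))
  st <- st[order(names(st))]
  storage.mode(st) <- "integer"
  st
}

#' Stoichiometric matrix of a network
#'
#' Entry (i, j) is the net number of molecules of species i produced by one
#' firing of reaction j (products minus reactants); rows of constant-pool
#' species are zero.
#'
#' @param x a [crn].
#' @return integer matrix, n species x r reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(x) {
  stopifnot(inherits(x, "crn"))
  x$S
}

#' Mass-action reaction fluxes
#'
#' @param x a [crn].
#' @param conc numeric vector of length n, concentrations in nM, >= 0
#'   (ordered as `x$species$id`, names optional).
#' @return named numeric vector of length r, v_j = k_j * prod_i
#'   conc_i^(reactant stoichiometry); always >= 0.
#' @export
mass_action_flux <- function(x, conc) {
  stopifnot(inherits(x, "crn"))
  conc <- as_state(x, conc)
  if (any(conc < 0))
    stop("negative concentration: ",
         paste(x$species$id[conc < 0], collapse = ", "))
  # conc^0 == 1 even at conc == 0, so x^R handles absent reactants
  v <- x$k * apply(conc ^ x$R, 2L, prod)
  v
}

#' Right-hand side of the mass-action ODE system
#'
#' Evaluates x' = S v(x, k).  Components belonging to constant-pool species
#' are exactly zero (their rows of S are zero).
#'
#' @inheritParams mass_action_flux
#' @return named numeric vector of length n.
#' @export
crn_rhs <- function(x, conc) {
  stopifnot(inherits(x, "crn"))
  drop(x$S %*% mass_action_flux(x, conc))
}

# Coerce a user-supplied state to the network's species order.
as_state <- function(x, conc) {
  n <- nrow(x$species)
  if (!is.null(names(conc)) && all(nzchar(names(conc)))) {
    miss <- setdiff(x$species$id, names(conc))
    if (length(miss))
      stop("state is missing species: ", paste(miss, collapse = ", "))
    conc <- conc[x$species$id]
  } else if (length(conc) != n) {
    stop("state has length ", length(conc), ", expected ", n)
  }
  conc <- as.numeric(conc)
  names(conc) <- x$species$id
  conc
}

#' Initial state of a network
#'
#' @param x a [crn].
#' @return named numeric vector of the species' initial concentrations (nM).
#' @export
initial_state <- function(x) {
  stopifnot(inherits(x, "crn"))
  stats::setNames(x$species$x0, x$species$id)
}

#' @export
print.crn <- function(x, ...) {
  n <- nrow(x$species); r <- length(x$reactions)
  npool <- sum(x$species$constant)
  nrev <- sum(!is.na(vapply(x$reactions, `[[`, "", "reverse_of"))) / 2
  cat("Mass-action reaction network: ", n, " species, ", r, " reactions\n",
      sep = "")
  if (npool) cat("  constant generator pools: ",
                 paste(x$species$id[x$species$constant], collapse = ", "), "\n",
                 sep = "")
  cat("  reversible pairs: ", nrev, ", irreversible: ", r - 2 * nrev, "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.crn <- function(object, ...) {
  laws <- conservation_laws(object)
  out <- list(
    n_species = nrow(object$species),
    n_reactions = length(object$reactions),
    n_constant_pools = sum(object$species$constant),
    n_laws = length(laws),
    uncovered = uncovered_species(object, laws)
  )
  class(out) <- "summary.crn"
  out
}

#' @export
print.summary.crn <- function(x, ...) {
  cat("Species:   ", x$n_species,
      if (x$n_constant_pools) paste0(" (", x$n_constant_pools, " constant pools)"),
      "\n", sep = "")
  cat("Reactions: ", x$n_reactions, "\n", sep = "")
  cat("Moiety conservation laws: ", x$n_laws, "\n", sep = "")
  if (length(x$uncovered))
    cat("Species outside every law: ",
        paste(x$uncovered, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Human-readable "A + 2 B -> C" form of one reaction (used by writer & print)
format_reaction <- function(rx) {
  side <- function(st) {
    if (length(st) == 0L) return("0")
    paste(ifelse(st == 1L, names(st), paste(st, names(st))), collapse = " + ")
  }
  paste(side(rx$reactants), "->", side(rx$products))
}
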