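#' Moiety conservation laws of a network
#'
#' Computes a generating set of the moiety conservation laws: independent
#' vectors of nonnegative integers `gamma` with `gamma' S = 0` exactly, so
#' that the aggregate `gamma' x(t)` is constant along every trajectory.  The
#' computation runs in exact rational arithmetic (rank and null-space
#' decisions never depend on a floating-point tolerance) and the basis is
#' then driven to nonnegative integers by positive combinations; if that
#' search fails the signed basis is returned with a warning and attribute
#' `nonnegative = FALSE`.
#'
#' Constant generator-pool species have zero rows in S, so each would
#' contribute a trivial singleton law; these are suppressed from the result
#' and listed in the `suppressed_pools` attribute.
#'
#' Generators are canonicalised: gcd of the coefficients is 1, the basis is
#' ordered by support size then by the first species in the support, so the
#' output is reproducible across runs.
#'
#' @param x a [crn].
#' @return list of `conservation_law` objects, each with elements `gamma`
#'   (named integer vector over all species) and `support` (character);
#'   attributes `nullity` (dimension of the full left null space, including
#'   suppressed pool laws) and `suppressed_pools`.
#' @examples
#' fx <- toy_binding()
#' conservation_laws(fx$crn)
#' @export
conservation_laws <- function(x) {
  stopifnot(inherits(x, "crn"))
  S <- x$S
  n <- nrow(S)
  nullity <- n - rat_rank(S)
  nonneg_ok <- TRUE
  B <- matrix(0, 0L, n)
  if (nullity > 0L) {
    rays <- nonneg_leftnull(S)
    if (!is.null(rays) && nrow(rays) > 0L) {
      # reproducible greedy selection of an independent generating subset
      sizes <- apply(rays, 1L, function(g) sum(g != 0))
      firsts <- apply(rays, 1L, function(g) which(g != 0)[1L])
      rays <- rays[order(sizes, firsts), , drop = FALSE]
      for (i in seq_len(nrow(rays))) {
        if (nrow(B) == nullity) break
        cand <- rbind(B, rays[i, ])
        if (rat_rank(cand) > nrow(B)) B <- cand
      }
    }
    if (nrow(B) < nullity) {
      warning("no nonnegative integer generating set found; ",
              "returning a signed rational basis (flagged)")
      B <- rat_nullspace(t(S))
      nonneg_ok <- FALSE
    }
  }
  # verify exactness in integer arithmetic
  if (nullity > 0L && any(B %*% S != 0))
    stop("internal error: computed generator fails gamma' S = 0 exactly")

  const_idx <- which(x$species$constant)
  keep <- rep(TRUE, nullity)
  suppressed <- character(0)
  for (i in seq_len(nullity)) {
    supp <- which(B[i, ] != 0)
    if (length(supp) > 0L && all(supp %in% const_idx)) {
      keep[i] <- FALSE
      suppressed <- c(suppressed, x$species$id[supp])
    }
  }
  B <- B[keep, , drop = FALSE]

  laws <- lapply(seq_len(nrow(B)), function(i) {
    gamma <- stats::setNames(B[i, ], x$species$id)
    structure(list(gamma = gamma,
                   support = x$species$id[gamma != 0]),
              class = "conservation_law")
  })
  # canonical order: support size, then position of first support species
  if (length(laws) > 1L) {
    sizes <- vapply(laws, function(l) length(l$support), integer(1))
    firsts <- vapply(laws, function(l) match(l$support[1L], x$species$id),
                     integer(1))
    seconds <- vapply(laws, function(l)
      if (length(l$support) > 1L) match(l$support[2L], x$species$id) else 0L,
      integer(1))
    laws <- laws[order(sizes, firsts, seconds)]
  }
  structure(laws, nullity = nullity,
            suppressed_pools = unique(suppressed),
            nonnegative = nonneg_ok)
}

#' @export
print.conservation_law <- function(x, ...) {
  g <- x$gamma[x$gamma != 0]
  cat("Conservation law: ",
      paste(ifelse(g == 1, names(g), paste0(g, " ", names(g))),
            collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Conserved totals of a state
#'
#' For each law, the aggregate concentration `c_j = gamma_j' x0` (nM) that
#' stays fixed along trajectories and labels the stoichiometric
#' compatibility class SC(c).
#'
#' @param laws list of conservation laws from [conservation_laws()].
#' @param x0 concentration vector (nM), same species order as the network.
#' @return numeric vector of length `length(laws)`.
#' @export
conservation_totals <- function(laws, x0) {
  if (length(laws) == 0L) return(numeric(0))
  n <- length(laws[[1L]]$gamma)
  if (length(x0) != n)
    stop("state has length ", length(x0), ", laws expect ", n)
  vapply(laws, function(l) sum(l$gamma * as.numeric(x0)), numeric(1))
}

#' Species not covered by any conservation law
#'
#' Species with a zero coefficient in every generator; in signalling
#' networks these are the species that undergo degradation or exchange
#' matter with the environment.  Constant generator pools are not counted
#' (their laws are suppressed by construction).
#'
#' @param x a [crn].
#' @param laws output of [conservation_laws()] for `x` (computed if missing).
#' @return character vector of species ids.
#' @export
uncovered_species <- function(x, laws = conservation_laws(x)) {
  stopifnot(inherits(x, "crn"))
  covered <- unique(unlist(lapply(laws, `[[`, "support")))
  setdiff(x$species$id[!x$species$constant], covered)
}

#' Distance from a stoichiometric compatibility class
#'
#' `max_j |gamma_j' x - c_j| / max(1, |c_j|)`: zero (up to tolerance) iff
#' `x` lies in SC(c).  Used as a drift diagnostic for integrated
#' trajectories.
#'
#' @param laws list of conservation laws.
#' @param x concentration vector.
#' @param c0 vector of reference totals, as from [conservation_totals()].
#' @return nonnegative scalar.
#' @export
class_distance <- function(laws, x, c0) {
  if (length(laws) == 0L) return(0)
  if (length(c0) != length(laws))
    stop("totals have length ", length(c0), ", expected ", length(laws))
  cx <- conservation_totals(laws, x)
  max(abs(cx - c0) / pmax(1, abs(c0)))
}

#' Export conservation laws as CSV
#'
#' One row per (law, species) pair with a nonzero coefficient, plus the
#' law's conserved total when a reference state is supplied.
#'
#' @param laws list of conservation laws.
#' @param path output file.
#' @param x0 optional reference state used to compute totals.
#' @return invisibly, the exported data.frame.
#' @export
write_laws_csv <- function(laws, path, x0 = NULL) {
  totals <- if (!is.null(x0)) conservation_totals(laws, x0) else
    rep(NA_real_, length(laws))
  rows <- do.call(rbind, lapply(seq_along(laws), function(j) {
    g <- laws[[j]]$gamma
    g <- g[g != 0]
    data.frame(law = j, species = names(g), coefficient = as.integer(g),
               total = totals[j])
  }))
  if (is.null(rows))
    rows <- data.frame(law = integer(0), species = character(0),
                       coefficient = integer(0), total = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
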