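#' Relative-difference profile between two equilibria
#'
#' For every species, `delta_i = (x_mut_i - x_ref_i) / x_ref_i`: the
#' relative change of the concentration at the perturbed equilibrium with
#' respect to the reference (physiological) one.  `delta = -1` means the
#' species' function is completely shut down.  Species whose reference
#' concentration sits below `floor` get an undefined (NA, flagged) delta
#' rather than a division blow-up; they are never silently reported as 0.
#'
#' @param x_mut perturbed equilibrium concentrations (named or in reference
#'   order).
#' @param x_ref reference equilibrium concentrations, >= 0.
#' @param threshold significance threshold on `|delta|` (default 0.03).
#' @param floor reference concentrations below this (nM, default 1e-12)
#'   make delta undefined.
#' @return object of class `delta_profile`: data.frame with columns
#'   `species`, `x_ref`, `x_mut`, `delta`, `defined`, `significant`;
#'   attribute `threshold`.
#' @export
delta_profile <- function(x_mut, x_ref, threshold = 0.03, floor = 1e-12) {
  if (length(x_mut) != length(x_ref))
    stop("x_mut and x_ref have different lengths")
  if (any(x_ref < 0)) stop("x_ref must be >= 0")
  ids <- names(x_ref) %||% names(x_mut) %||%
    paste0("species_", seq_along(x_ref))
  if (!is.null(names(x_mut)) && !is.null(names(x_ref)))
    x_mut <- x_mut[names(x_ref)]
  defined <- x_ref >= floor
  delta <- rep(NA_real_, length(x_ref))
  delta[defined] <- (x_mut[defined] - x_ref[defined]) / x_ref[defined]
  significant <- defined & !is.na(delta) & abs(delta) > threshold
  out <- data.frame(species = ids,
                    x_ref = as.numeric(x_ref),
                    x_mut = as.numeric(x_mut),
                    delta = as.numeric(delta),
                    defined = defined,
                    significant = significant,
                    row.names = NULL)
  structure(out, class = c("delta_profile", "data.frame"),
            threshold = threshold)
}

#' @export
print.delta_profile <- function(x, ...) {
  cat("Delta profile over ", nrow(x), " species; |delta| > ",
      attr(x, "threshold"), " in ", sum(x$significant), " (",
      format(affected_fraction(x), digits = 3), "%)",
      if (any(!x$defined)) paste0("; undefined: ", sum(!x$defined)),
      "\n", sep = "")
  top <- x[order(-abs(ifelse(is.na(x$delta), 0, x$delta))), ]
  print.data.frame(utils::head(top, 8L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fraction of species significantly affected by a perturbation
#'
#' `100 * #significant / n`, counting species with undefined delta as not
#' significant.
#'
#' @param profile a [delta_profile()].
#' @return percentage in \[0, 100\].
#' @export
affected_fraction <- function(profile) {
  stopifnot(inherits(profile, "delta_profile"))
  100 * sum(profile$significant) / nrow(profile)
}

#' Export a delta report as CSV
#'
#' @param profile a [delta_profile()].
#' @param path output file.
#' @return invisibly, the exported data.frame.
#' @export
write_delta_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(as.data.frame(profile))
}

#' Flux decomposition of one species' dynamics along a trajectory
#'
#' For each reaction touching the species, the signed contribution
#' `S[species, j] * v_j(x(t))` to its derivative; the two directions of a
#' reversible pair are summed into a single net trace.  At every sampled
#' time the traces add up to the species' ODE right-hand side, so the
#' decomposition shows which reactions drive a concentration up or down.
#'
#' @param x a [crn].
#' @param traj a trajectory from [trajectory()].
#' @param species species id.
#' @return list of class `flux_trace` entries, each with `reactions`
#'   (character, 1 or 2 ids), `t`, and `value` (signed nM/s contribution);
#'   attribute `total` holds the summed derivative at each time.  Empty
#'   list for a species with no incident reactions.
#' @export
flux_traces <- function(x, traj, species) {
  stopifnot(inherits(x, "crn"), inherits(traj, "crn_trajectory"))
  if (!species %in% x$species$id) stop("unknown species '", species, "'")
  srow <- x$S[species, ]
  inc <- which(srow != 0)
  if (length(inc) == 0L)
    return(structure(list(), class = "flux_trace_set",
                     total = rep(0, length(traj$t)), species = species))
  V <- apply(traj$X, 2L, function(xx) mass_action_flux(x, xx))  # r x T
  rids <- names(x$k)
  revs <- vapply(x$reactions, `[[`, "", "reverse_of")
  seen <- character(0)
  traces <- list()
  for (j in inc) {
    id <- rids[j]
    if (id %in% seen) next
    partner <- revs[j]
    if (!is.na(partner) && partner %in% rids[inc]) {
      jj <- match(partner, rids)
      value <- srow[j] * V[j, ] + srow[jj] * V[jj, ]
      ids <- c(id, partner)
      seen <- c(seen, id, partner)
    } else {
      value <- srow[j] * V[j, ]
      ids <- id
      seen <- c(seen, id)
    }
    traces[[length(traces) + 1L]] <-
      list(reactions = ids, t = traj$t, value = as.numeric(value))
  }
  total <- Reduce(`+`, lapply(traces, `[[`, "value"))
  structure(traces, class = "flux_trace_set", total = total,
            species = species)
}

#' @export
print.flux_trace_set <- function(x, ...) {
  cat("Flux decomposition of '", attr(x, "species"), "': ", length(x),
      " trace(s)\n", sep = "")
  for (tr in x)
    cat("  ", paste(tr$reactions, collapse = " / "),
        ": final ", signif(tr$value[length(tr$value)], 4), " nM/s\n",
        sep = "")
  invisible(x)
}

#' Export flux traces as CSV
#'
#' Long format: time, reaction id(s), signed flux (nM/s).
#'
#' @param traces a `flux_trace_set` from [flux_traces()].
#' @param path output file.
#' @return invisibly, the exported data.frame.
#' @export
write_flux_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time = tr$t,
               reactions = paste(tr$reactions, collapse = "+"),
               flux = tr$value)))
  if (is.null(rows))
    rows <- data.frame(time = numeric(0), reactions = character(0),
                       flux = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Bi-symmetric log transform
#'
#' `sign(v) * log10(1 + |v|/C)`: odd, strictly increasing, linear near 0
#' and logarithmic in the tails; the standard display scale for
#' relative-difference profiles spanning orders of magnitude in both signs.
#'
#' @param v numeric vector.
#' @param C positive scale constant; default `1/ln(10)` so the transform
#'   has unit slope at 0 in base-10 units.
#' @return transformed vector.
#' @export
bisymlog <- function(v, C = 1 / log(10)) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a positive scalar")
  sign(v) * log10(1 + abs(v) / C)
}

#' Dose titration of a competitive inhibitor
#'
#' For each dose fraction `alpha`, adds the drug to the mutated network at
#' the mutated equilibrium, re-equilibrates, and profiles the result
#' against the physiological equilibrium.  The restoration score counts
#' species whose concentration is brought back within the significance
#' threshold of its physiological value (drug and complex excluded); the
#' ranking of scores across alphas, not their absolute value, is the
#' useful read-out.
#'
#' @param x mutated [crn].
#' @param x_mut_eq equilibrium of the mutated network.
#' @param x_phys_eq equilibrium of the physiological network (same species
#'   as `x`).
#' @param spec a [drug_spec()]; its `alpha` is overridden by `alphas`.
#' @param alphas dose fractions to sweep (default `c(1, 0.75, 0.5, 0.25)`).
#' @param threshold significance threshold for restoration (default 0.03).
#' @param laws conservation laws of `x` (computed if missing).
#' @param ... passed to [find_equilibrium()].
#' @return object of class `titration`: data.frame (`alpha`, `dose`,
#'   `score`, `affected`, `converged`) sorted by alpha, with the per-alpha
#'   [delta_profile()]s in attribute `profiles` and the maximizing alpha in
#'   attribute `best_alpha`.
#' @export
titrate <- function(x, x_mut_eq, x_phys_eq, spec,
                    alphas = c(1, 0.75, 0.5, 0.25), threshold = 0.03,
                    laws = conservation_laws(x), ...) {
  stopifnot(inherits(x, "crn"), inherits(spec, "drug_spec"))
  x_mut_eq <- as_state(x, x_mut_eq)
  x_phys_eq <- as_state(x, x_phys_eq)
  res <- data.frame(alpha = numeric(0), dose = numeric(0),
                    score = integer(0), affected = numeric(0),
                    converged = logical(0))
  profiles <- list()
  for (a in sort(alphas)) {
    if (a == 0) {
      prof <- delta_profile(x_mut_eq, x_phys_eq, threshold = threshold)
      dose <- 0; conv <- TRUE
    } else {
      sp <- spec; sp$alpha <- a; sp$dose <- NULL
      if (!is.null(spec$dose)) sp$dose <- a * spec$dose
      drugged <- add_drug(x, x_mut_eq, sp, laws = laws)
      eq <- find_equilibrium(drugged$crn, drugged$x0, ...)
      keep <- x$species$id     # exclude drug and complex
      prof <- delta_profile(eq$x_eq[keep], x_phys_eq, threshold = threshold)
      dose <- drugged$dose; conv <- eq$converged
    }
    score <- sum(prof$defined & !is.na(prof$delta) &
                   abs(prof$delta) <= threshold)
    res <- rbind(res, data.frame(alpha = a, dose = dose, score = score,
                                 affected = affected_fraction(prof),
                                 converged = conv))
    profiles[[as.character(a)]] <- prof
  }
  structure(res, class = c("titration", "data.frame"),
            profiles = profiles,
            best_alpha = res$alpha[which.max(res$score)])
}

#' @export
print.titration <- function(x, ...) {
  cat("Drug titration over", nrow(x), "dose fractions",
      "(score = species restored within the threshold):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("best alpha:", attr(x, "best_alpha"), "\n")
  invisible(x)
}
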