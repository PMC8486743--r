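# Fast closure evaluating v(x,k) and S v for deSolve; avoids per-call
# validation and the dense x^R power matrix.
make_rhs <- function(net) {
  S <- net$S
  k <- net$k
  r <- length(k)
  ridx <- vector("list", r)
  rpow <- vector("list", r)
  for (j in seq_len(r)) {
    idx <- which(net$R[, j] != 0L)
    ridx[[j]] <- idx
    rpow[[j]] <- net$R[idx, j]
  }
  flux <- function(y) {
    v <- k
    for (j in seq_len(r)) {
      idx <- ridx[[j]]
      if (length(idx)) v[j] <- v[j] * prod(y[idx] ^ rpow[[j]])
    }
    v
  }
  list(
    flux = flux,
    deriv = function(t, y, parms) {
      y[y < 0] <- 0
      list(drop(S %*% flux(y)))
    }
  )
}

#' Steady-state residual
#'
#' `||S v(x, k)||_inf / max(1, ||x||_inf)`: the scaled size of the ODE
#' right-hand side, zero at an exact equilibrium.
#'
#' @param x a [crn].
#' @param conc concentration vector (nM).
#' @return nonnegative scalar.
#' @export
steady_residual <- function(x, conc) {
  dx <- crn_rhs(x, conc)
  max(abs(dx)) / max(1, max(abs(conc)))
}

#' Integrate a network to its asymptotic equilibrium
#'
#' Integrates the stiff mass-action system x' = S v(x, k) on geometrically
#' growing horizons until the state stops moving, and certifies the result:
#' residual of the right-hand side, drift of the conserved totals, and a
#' convergence flag.  Non-convergence within the horizon cap is reported,
#' never silently truncated.
#'
#' @param x a [crn].
#' @param x0 initial concentrations (nM); defaults to the network's own.
#' @param laws conservation laws of `x` (computed if missing) used for the
#'   drift diagnostic.
#' @param rtol,atol relative / absolute integration tolerances (defaults
#'   1e-8 and 1e-12 nM).
#' @param horizon first integration horizon in seconds (default 1e5); it is
#'   doubled until convergence.
#' @param horizon_cap stop doubling beyond this time (default 1e9 s).
#' @param residual_tol converged requires [steady_residual()] at or below
#'   this (default 1e-9).
#' @param change_tol converged additionally requires the componentwise
#'   relative change of x between successive horizons at or below this
#'   (default 1e-8).
#' @param method deSolve integrator (default `"lsoda"`, a stiff
#'   variable-order multistep family).
#' @return object of class `crn_equilibrium`: `x_eq` (named vector, >= 0),
#'   `residual`, `t_final`, `conservation_drift`, `converged`, `clipped`
#'   (total negative undershoot removed).
#' @examples
#' fx <- toy_binding()
#' eq <- find_equilibrium(fx$crn)
#' eq$x_eq["C"]        # (3 - sqrt(5)) / 2 for unit constants and totals
#' @export
find_equilibrium <- function(x, x0 = initial_state(x), laws = NULL,
                             rtol = 1e-8, atol = 1e-12,
                             horizon = 1e5, horizon_cap = 1e9,
                             residual_tol = 1e-9, change_tol = 1e-8,
                             method = "lsoda") {
  stopifnot(inherits(x, "crn"))
  x0 <- as_state(x, x0)
  if (any(x0 < 0)) stop("initial concentrations must be >= 0")
  if (is.null(laws)) laws <- conservation_laws(x)
  c0 <- conservation_totals(laws, x0)
  fns <- make_rhs(x)

  y <- x0
  t_now <- 0
  clipped <- 0
  converged <- FALSE
  repeat {
    t_next <- if (t_now == 0) horizon else t_now * 2
    sol <- deSolve::ode(y = y, times = c(t_now, t_next), func = fns$deriv,
                        parms = NULL, method = method,
                        rtol = rtol, atol = atol)
    y_new <- sol[nrow(sol), -1L]
    neg <- y_new < 0
    clipped <- clipped + sum(-y_new[neg])
    y_new[neg] <- 0
    names(y_new) <- x$species$id
    change <- max(abs(y_new - y) / pmax(abs(y), 1))
    y <- y_new
    t_now <- t_next
    res <- steady_residual(x, y)
    if (res <= residual_tol && change <= change_tol) {
      converged <- TRUE
      break
    }
    if (t_now >= horizon_cap) break
  }
  if (clipped > nrow(x$species) * 1e-9)
    warning("integrator undershoot clipped: total ", signif(clipped, 3), " nM")
  structure(list(x_eq = y,
                 residual = steady_residual(x, y),
                 t_final = t_now,
                 conservation_drift = class_distance(laws, y, c0),
                 converged = converged,
                 clipped = clipped),
            class = "crn_equilibrium")
}

#' @export
print.crn_equilibrium <- function(x, ...) {
  cat("Equilibrium (", if (x$converged) "converged" else "NOT converged",
      ") at t = ", format(x$t_final, scientific = TRUE), " s\n", sep = "")
  cat("  residual: ", signif(x$residual, 3),
      "   conservation drift: ", signif(x$conservation_drift, 3), "\n",
      sep = "")
  print(utils::head(sort(x$x_eq, decreasing = TRUE), 10L))
  invisible(x)
}

#' Time course of a network
#'
#' Solves x' = S v(x, k) on a user grid with the same solver settings as
#' [find_equilibrium()].
#'
#' @inheritParams find_equilibrium
#' @param t_grid sorted nonnegative times (s).
#' @return object of class `crn_trajectory`: `t` (times) and `X`
#'   (n x length(t) concentration matrix, species in rows).
#' @export
trajectory <- function(x, x0 = initial_state(x), t_grid,
                       rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  stopifnot(inherits(x, "crn"))
  x0 <- as_state(x, x0)
  if (any(x0 < 0)) stop("initial concentrations must be >= 0")
  if (is.unsorted(t_grid)) stop("t_grid must be sorted")
  if (length(t_grid) == 1L && t_grid[1L] == 0) {
    X <- matrix(x0, ncol = 1L, dimnames = list(x$species$id, NULL))
    return(structure(list(t = t_grid, X = X), class = "crn_trajectory"))
  }
  fns <- make_rhs(x)
  times <- t_grid
  prepend <- FALSE
  if (times[1L] > 0) { times <- c(0, times); prepend <- TRUE }
  sol <- try(deSolve::ode(y = x0, times = times, func = fns$deriv,
                          parms = NULL, method = method,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("ODE solver failed: ", attr(sol, "condition")$message)
  if (nrow(sol) < length(times))
    stop("ODE solver stopped early at t = ", sol[nrow(sol), 1L], " s")
  X <- t(sol[, -1L, drop = FALSE])
  if (prepend) X <- X[, -1L, drop = FALSE]
  X[X < 0] <- 0
  rownames(X) <- x$species$id
  structure(list(t = t_grid, X = X), class = "crn_trajectory")
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("Trajectory: ", nrow(x$X), " species sampled at ", length(x$t),
      " times in [", x$t[1L], ", ", x$t[length(x$t)], "] s\n", sep = "")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj a `crn_trajectory`.
#' @param path output file.
#' @param species which species columns to include (default all).
#' @return invisibly, the exported data.frame (time + one column/species).
#' @export
write_trajectory_csv <- function(traj, path, species = rownames(traj$X)) {
  missing <- setdiff(species, rownames(traj$X))
  if (length(missing))
    stop("unknown species: ", paste(missing, collapse = ", "))
  df <- data.frame(time = traj$t,
                   t(traj$X[species, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export an equilibrium as CSV
#'
#' @param eq a `crn_equilibrium`.
#' @param path output file.
#' @return invisibly, the exported two-column data.frame.
#' @export
write_equilibrium_csv <- function(eq, path) {
  df <- data.frame(species = names(eq$x_eq), concentration = unname(eq$x_eq))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
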