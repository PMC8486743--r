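# Exact rational linear algebra on integer matrices.
#
# Numerators and denominators are stored in doubles, which represent
# integers exactly up to 2^53; every operation reduces by the gcd and a
# guard aborts well before that bound, so rank and null-space decisions are
# exact, never floating-point.

RAT_MAX <- 2^48

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

gcd_vec <- function(v) {
  g <- 0
  for (x in v) { g <- gcd2(g, x); if (g == 1) break }
  g
}

rat_check <- function(num, den) {
  if (any(abs(num) > RAT_MAX) || any(den > RAT_MAX))
    stop("exact rational arithmetic overflow; stoichiometric entries too large")
}

# Reduced row echelon form of an integer matrix, exact.
# Returns list(num, den, pivots, rank).
rat_rref <- function(A) {
  m <- nrow(A); n <- ncol(A)
  num <- matrix(as.numeric(A), m, n)
  den <- matrix(1, m, n)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(num[row:m, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) {
      num[c(piv, row), ] <- num[c(row, piv), ]
      den[c(piv, row), ] <- den[c(row, piv), ]
    }
    # scale pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(n)) {
      nn <- num[row, j] * pd; dd <- den[row, j] * pn
      if (dd < 0) { nn <- -nn; dd <- -dd }
      g <- gcd2(nn, dd); if (g > 1) { nn <- nn / g; dd <- dd / g }
      if (nn == 0) dd <- 1
      num[row, j] <- nn; den[row, j] <- dd
    }
    rat_check(num[row, ], den[row, ])
    # eliminate in all other rows
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(n)) {
        # a_ij <- a_ij - (fn/fd) * a_rj
        nn <- num[i, j] * fd * den[row, j] - fn * num[row, j] * den[i, j]
        dd <- den[i, j] * fd * den[row, j]
        if (dd < 0) { nn <- -nn; dd <- -dd }
        g <- gcd2(nn, dd); if (g > 1) { nn <- nn / g; dd <- dd / g }
        if (nn == 0) dd <- 1
        num[i, j] <- nn; den[i, j] <- dd
      }
      rat_check(num[i, ], den[i, ])
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

# Exact rank of an integer matrix.
rat_rank <- function(A) {
  if (length(A) == 0L || nrow(A) == 0L || ncol(A) == 0L) return(0L)
  rat_rref(A)$rank
}

# Integer basis of the null space of integer matrix M (solutions of M y = 0).
# Rows of the returned matrix are basis vectors with gcd 1 and sign
# normalised so the first nonzero entry is positive.
rat_nullspace <- function(M) {
  n <- ncol(M)
  if (nrow(M) == 0L) {
    B <- diag(1, n)
    return(B)
  }
  rr <- rat_rref(M)
  free <- setdiff(seq_len(n), rr$pivots)
  if (length(free) == 0L) return(matrix(0, 0L, n))
  B <- matrix(0, length(free), n)
  for (b in seq_along(free)) {
    f <- free[b]
    # rational solution: y_f = 1, y_{pivot_i} = -rref[i, f]
    nn <- rep(0, n); dd <- rep(1, n)
    nn[f] <- 1
    for (i in seq_along(rr$pivots)) {
      p <- rr$pivots[i]
      nn[p] <- -rr$num[i, f]
      dd[p] <- rr$den[i, f]
    }
    l <- 1
    for (d in unique(dd)) l <- l / gcd2(l, d) * d   # lcm
    y <- nn * (l / dd)
    g <- gcd_vec(y)
    if (g > 1) y <- y / g
    first <- which(y != 0)[1L]
    if (y[first] < 0) y <- -y
    B[b, ] <- y
  }
  rat_check(B, abs(B) + 1)
  B
}

# Are the row spaces of two integer matrices equal (exact)?
rat_rowspace_equal <- function(A, B) {
  if (ncol(A) != ncol(B)) return(FALSE)
  ra <- rat_rank(A); rb <- rat_rank(B)
  ra == rb && rat_rank(rbind(A, B)) == ra
}

# Nonnegative integer generators of {gamma >= 0 : gamma' S = 0} by the
# tableau (double-description) algorithm: start from [I | S] and process
# the S columns one by one, keeping rows with a zero in the column plus
# every positive pairwise combination of rows with opposite signs.  Rows
# are reduced by their gcd and pruned to support-minimal ones, so the
# result is the set of extreme rays of the cone.  Returns NULL if the
# tableau outgrows `max_rows` (combinatorial blow-up).
nonneg_leftnull <- function(S, max_rows = 20000L) {
  n <- nrow(S); r <- ncol(S)
  Tb <- cbind(diag(1, n), S)
  for (cc in seq_len(r)) {
    col <- Tb[, n + cc]
    zero <- which(col == 0); pos <- which(col > 0); neg <- which(col < 0)
    rows <- vector("list", length(zero) + length(pos) * length(neg))
    m <- 0L
    for (i in zero) { m <- m + 1L; rows[[m]] <- Tb[i, ] }
    for (i in pos) for (j in neg) {
      row <- (-col[j]) * Tb[i, ] + col[i] * Tb[j, ]
      g <- gcd_vec(row)
      if (g > 1) row <- row / g
      rat_check(row, 1)
      m <- m + 1L; rows[[m]] <- row
    }
    if (m == 0L) return(matrix(0, 0L, n))
    if (m > max_rows) return(NULL)
    Tb <- do.call(rbind, rows[seq_len(m)])
    # prune duplicates and rows whose support strictly contains another's
    supp <- lapply(seq_len(nrow(Tb)), function(i) which(Tb[i, seq_len(n)] != 0))
    keep <- rep(TRUE, nrow(Tb))
    ord <- order(lengths(supp))
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        if (b <= a) next
        j <- ord[b]
        if (keep[j] && all(supp[[i]] %in% supp[[j]])) {
          if (length(supp[[j]]) > length(supp[[i]]) ||
              identical(Tb[i, ], Tb[j, ])) keep[j] <- FALSE
        }
      }
    }
    Tb <- Tb[keep, , drop = FALSE]
  }
  Tb[, seq_len(n), drop = FALSE]
}
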