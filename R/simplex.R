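# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves  min (or max)  obj'v   subject to   Aeq v = beq,  lower <= v <= upper.
# All bounds must be finite. Small flux-balance problems (tens to a few hundred
# variables) are the intended regime; the tableau is dense and vectorised.

# one simplex phase: Tm is the tableau (rhs in last column, always >= 0),
# basis[i] is the column basic in row i, costs the full cost vector (length =
# ncol(Tm) - 1), allowed marks columns permitted to enter.
.simplex_phase <- function(Tm, basis, costs, allowed, tol = 1e-9) {
  ncols <- ncol(Tm) - 1L
  rhs_col <- ncol(Tm)
  # reduced costs r = c - c_B' T
  cb <- costs[basis]
  red <- costs[seq_len(ncols)] - as.numeric(cb %*% Tm[, seq_len(ncols), drop = FALSE])
  repeat {
    cand_in <- which(allowed & red < -tol)
    if (!length(cand_in)) break
    enter <- cand_in[1L]                       # Bland: smallest eligible index
    col <- Tm[, enter]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", Tm = Tm, basis = basis))
    }
    ratios <- Tm[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol]
    leave <- ties[which.min(basis[ties])]      # Bland: smallest basic index leaves
    piv <- Tm[leave, enter]
    Tm[leave, ] <- Tm[leave, ] / piv
    fac <- Tm[, enter]
    fac[leave] <- 0
    Tm <- Tm - outer(fac, Tm[leave, ])
    red <- red - red[enter] * Tm[leave, seq_len(ncols)]
    basis[leave] <- enter
    # guard against numerical drift below zero on the rhs
    neg <- Tm[, rhs_col] < 0
    if (any(neg)) Tm[neg, rhs_col] <- pmax(Tm[neg, rhs_col], -tol)
  }
  list(status = "optimal", Tm = Tm, basis = basis)
}

# Solve the bounded-variable LP. Returns list(status, x, value) where
# status is "optimal", "infeasible" or "unbounded".
simplex_solve <- function(obj, Aeq, beq, lower, upper,
                          maximize = FALSE, tol = 1e-9) {
  Aeq <- as.matrix(Aeq)
  n <- length(obj)
  m <- nrow(Aeq)
  stopifnot(ncol(Aeq) == n, length(beq) == m,
            length(lower) == n, length(upper) == n,
            all(is.finite(lower)), all(is.finite(upper)))
  if (any(upper < lower - 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  cvec <- if (maximize) -obj else obj

  # shift x = v - lower so x >= 0; add slack rows for x <= ub
  b_eq <- as.numeric(beq - Aeq %*% lower)
  ub <- pmax(upper - lower, 0)

  # drop fixed variables (ub == 0) from the tableau entirely
  free <- which(ub > 1e-12)
  nf <- length(free)
  Af <- Aeq[, free, drop = FALSE]
  cf <- cvec[free]
  ubf <- ub[free]

  # rows: m equalities (sign-adjusted to rhs >= 0, artificial each)
  #       nf bound rows x_i + s_i = ub_i (slack basic)
  sgn <- ifelse(b_eq < 0, -1, 1)
  Af2 <- Af * sgn
  b2 <- b_eq * sgn

  nrows <- m + nf
  ncols <- nf + nf + m            # vars, bound slacks, artificials
  Tm <- matrix(0, nrows, ncols + 1L)
  if (m > 0) {
    Tm[seq_len(m), seq_len(nf)] <- Af2
    Tm[cbind(seq_len(m), nf + nf + seq_len(m))] <- 1
    Tm[seq_len(m), ncols + 1L] <- b2
  }
  if (nf > 0) {
    Tm[cbind(m + seq_len(nf), seq_len(nf))] <- 1
    Tm[cbind(m + seq_len(nf), nf + seq_len(nf))] <- 1
    Tm[m + seq_len(nf), ncols + 1L] <- ubf
  }
  basis <- c(nf + nf + seq_len(m), nf + seq_len(nf))[seq_len(nrows)]
  if (m == 0) basis <- nf + seq_len(nf)

  art_cols <- if (m > 0) nf + nf + seq_len(m) else integer(0)

  # phase 1: minimise sum of artificials
  c1 <- numeric(ncols)
  c1[art_cols] <- 1
  ph1 <- .simplex_phase(Tm, basis, c1, allowed = rep(TRUE, ncols), tol = tol)
  if (ph1$status != "optimal") {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  Tm <- ph1$Tm; basis <- ph1$basis
  art_val <- sum(Tm[basis %in% art_cols, ncol(Tm)])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # drive residual basic artificials out (degenerate pivots); redundant rows stay
  for (r in which(basis %in% art_cols)) {
    piv_cols <- which(abs(Tm[r, seq_len(nf + nf)]) > 1e-8)
    if (length(piv_cols)) {
      enter <- piv_cols[1L]
      piv <- Tm[r, enter]
      Tm[r, ] <- Tm[r, ] / piv
      fac <- Tm[, enter]; fac[r] <- 0
      Tm <- Tm - outer(fac, Tm[r, ])
      basis[r] <- enter
    }
  }

  # phase 2: original objective, artificials barred from entering
  c2 <- numeric(ncols)
  c2[seq_len(nf)] <- cf
  allowed <- rep(TRUE, ncols)
  allowed[art_cols] <- FALSE
  ph2 <- .simplex_phase(Tm, basis, c2, allowed = allowed, tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  Tm <- ph2$Tm; basis <- ph2$basis

  xf <- numeric(nf)
  in_vars <- basis <= nf
  xf[basis[in_vars]] <- Tm[in_vars, ncol(Tm)]
  x <- lower
  x[free] <- x[free] + xf
  value <- sum(obj * x)
  list(status = "optimal", x = x, value = value)
}
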