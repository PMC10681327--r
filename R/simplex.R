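# Dense two-phase revised simplex with Bland's rule.
#
# Solves   min c'x   s.t.  A x = b,  x >= 0   (standard form).
# Problems here are tiny (tens of rows/columns), so each iteration solves
# the basis system directly; Bland's anti-cycling rule makes the pivot
# sequence — and hence the returned vertex — deterministic, which the
# basis-tracking layer relies on for reproducible degenerate tie-breaks.

simplex_standard <- function(cc, A, b, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  sgn <- ifelse(b < 0, -1, 1)
  A <- A * sgn; b <- b * sgn
  # phase 1: artificial variables form the starting basis
  A1 <- cbind(A, diag(m))
  art_cols <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  res <- simplex_iterate(c1, A1, b, basis = art_cols, tol = tol,
                         max_iter = max_iter, forbidden = integer())
  if (res$status != "optimal") return(res)
  if (res$value > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  # phase 2: original cost; artificials stay with zero cost but may never
  # re-enter, and are pushed out by the extended ratio test if basic
  c2 <- c(cc, rep(0, m))
  res <- simplex_iterate(c2, A1, b, basis = res$basis, tol = tol,
                         max_iter = max_iter, forbidden = art_cols)
  if (res$status != "optimal") return(res)
  list(status = "optimal", x = res$x[seq_len(n)], value = res$value,
       basis = res$basis)
}

simplex_iterate <- function(cc, A, b, basis, tol, max_iter, forbidden) {
  n <- ncol(A)
  is_art <- seq_len(n) %in% forbidden
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv))
      return(list(status = "error", x = NULL, value = NA_real_,
                  message = "singular working basis"))
    xB <- as.vector(Binv %*% b)
    yT <- as.vector(cc[basis] %*% Binv)
    red <- cc - as.vector(yT %*% A)
    elig <- red < -tol & !(seq_len(n) %in% basis) & !is_art
    enter <- which(elig)[1]                                   # Bland
    if (is.na(enter)) {
      x <- numeric(n); x[basis] <- xB
      return(list(status = "optimal", x = x, value = sum(cc * x),
                  basis = basis))
    }
    d <- as.vector(Binv %*% A[, enter])
    pos <- which(d > tol)
    # an artificial basic at zero may leave on a pivot of either sign
    art_zero <- which(is_art[basis] & abs(xB) <= tol & abs(d) > tol)
    if (length(pos) == 0L && length(art_zero) == 0L)
      return(list(status = "unbounded", x = NULL, value = NA_real_))
    ratio <- rep(Inf, length(basis))
    ratio[pos] <- xB[pos] / d[pos]
    ratio[art_zero] <- 0
    rmin <- min(ratio)
    cand <- which(ratio <= rmin + tol)
    leave <- cand[which.min(basis[cand])]                     # Bland
    basis[leave] <- enter
  }
  list(status = "error", x = NULL, value = NA_real_,
       message = "simplex iteration limit reached")
}

# Row-form interface used by the FBA layer: optimize obj.x over free x
# subject to eq/upper/lower rows. Splits x = p - q, adds slack variables,
# and calls the standard-form solver.
simplex_rows <- function(obj, coeff, kind, rhs, maximize = TRUE,
                         cost = NULL) {
  n <- length(obj)
  nr <- length(kind)
  slack <- diag(ifelse(kind == "upper", 1,
                       ifelse(kind == "lower", -1, 0)), nr, nr)
  use_slack <- which(kind != "eq")
  A <- cbind(coeff, -coeff, slack[, use_slack, drop = FALSE])
  if (is.null(cost)) cost <- c(obj, -obj)
  cc <- c(if (maximize) -cost else cost, rep(0, length(use_slack)))
  res <- simplex_standard(cc, A, rhs)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_,
                message = res$message))
  x <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  list(status = "optimal", x = unname(x), value = sum(obj * x))
}
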