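# Independent oracles for the DEA linear programs and OLS fits.

# All non-negative integer compositions of `steps` into J parts, as a
# matrix of simplex weights (rows sum to 1). Enumerated recursively.
simplex_grid <- function(J, steps) {
  compositions <- function(parts, total) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(k) {
      cbind(k, compositions(parts - 1, total - k))
    }))
  }
  compositions(J, steps) / steps
}

# Brute-force output-expansion factor over the weight simplex grid:
# max over grid z with X'z <= x0 + slack of min_m (Y'z)_m / y0_m.
# Returns -Inf when no grid point is feasible.
grid_theta <- function(X, Y, x0, y0, steps, slack = 0) {
  Z <- simplex_grid(nrow(X), steps)
  ZX <- Z %*% X
  feas <- rowSums(sweep(ZX, 2, x0 + slack, `>`)) == 0
  if (!any(feas)) return(-Inf)
  ZY <- Z[feas, , drop = FALSE] %*% Y
  pos <- which(y0 > 0)
  ratios <- sweep(ZY[, pos, drop = FALSE], 2, y0[pos], `/`)
  max(apply(ratios, 1, min))
}

# Two-sided bracket for the true optimum theta* from pure grid
# enumeration: a strict-feasibility grid maximum (lower bound) and a
# slack-feasibility grid maximum plus the rounding error bound (upper
# bound). Any z in the simplex has a grid neighbour within L1 distance
# 2*J*h, which perturbs each input constraint by at most 2*J*h*max_j X_jn
# and the objective by at most 2*J*h*K_Y.
grid_bracket <- function(X, Y, x0, y0, steps) {
  J <- nrow(X)
  h <- 1 / steps
  delta <- 2 * J * h
  K_Y <- max(apply(Y, 2, max)[y0 > 0] / y0[y0 > 0])
  lower <- grid_theta(X, Y, x0, y0, steps)
  upper <- grid_theta(X, Y, x0, y0, steps,
                      slack = delta * apply(X, 2, max)) + delta * K_Y
  c(lower = lower, upper = upper)
}

# Feasibility certificate for an LP solution: the reported weights must
# lie on the simplex, respect the input constraints and attain theta.
check_lp_certificate <- function(z, theta, X, Y, x0, y0, tol = 1e-7) {
  expect_true(all(z >= -tol))
  expect_equal(sum(z), 1, tolerance = tol)
  expect_true(all(drop(z %*% X) <= x0 + tol * (1 + abs(x0))))
  pos <- y0 > 0
  attained <- min(drop(z %*% Y)[pos] / y0[pos])
  expect_gte(attained, theta - tol)
}

# Closed-form least squares via the normal equations.
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))
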