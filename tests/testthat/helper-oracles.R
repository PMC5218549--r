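# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# --- brute-force Delaunay edge oracle -------------------------------------
# (i, j) is a Delaunay edge iff some circumcircle through i, j and a third
# point contains no other point strictly inside. O(n^4), fine for n <= 50.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), r2 = (ax - ux)^2 + (ay - uy)^2)
}

brute_delaunay_edges <- function(xy) {
  n <- nrow(xy)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        cc <- circumcircle(xy[i, ], xy[j, ], xy[k, ])
        if (is.null(cc)) next
        d2 <- (xy[, 1] - cc$center[1])^2 + (xy[, 2] - cc$center[2])^2
        inside <- d2 < cc$r2 * (1 - 1e-9)
        inside[c(i, j, k)] <- FALSE
        if (!any(inside)) { adj[i, j] <- adj[j, i] <- TRUE; break }
      }
    }
  }
  adj
}

# --- exhaustive grid-search probit oracle ---------------------------------
# maximizes the probit log-likelihood over a 2-D grid (intercept, slope),
# coarse pass then 1e-3 fine pass
grid_probit_oracle <- function(y, x1, coarse = seq(-3, 3, by = 0.05),
                               fine_step = 1e-3, fine_halfwidth = 0.06) {
  loglik <- function(b0, b1) {
    p <- pnorm(b0 + b1 * x1)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- c(NA, NA); best_ll <- -Inf
  search <- function(g0, g1) {
    for (b0 in g0) for (b1 in g1) {
      v <- loglik(b0, b1)
      if (v > best_ll) { best_ll <<- v; best <<- c(b0, b1) }
    }
  }
  search(coarse, coarse)
  fine <- function(center) seq(center - fine_halfwidth, center + fine_halfwidth,
                               by = fine_step)
  search(fine(best[1]), fine(best[2]))
  list(beta = best, loglik = best_ll)
}

# --- finite-difference oracle for the SAR effects matrix ------------------
# p_i(X) = Phi([(I - rho W)^-1 X beta]_i); central difference in x[j, r]
fd_effects_oracle <- function(r, beta, rho, wm, x, h = 1e-6) {
  n <- nrow(x)
  a_inv <- solve(diag(n) - rho * as.matrix(wm))
  probs <- function(xx) pnorm(drop(a_inv %*% (xx %*% beta)))
  s <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    xp <- x; xp[j, r] <- xp[j, r] + h
    xm <- x; xm[j, r] <- xm[j, r] - h
    s[, j] <- (probs(xp) - probs(xm)) / (2 * h)
  }
  s
}

# --- independent Albert-Chib probit Gibbs sampler -------------------------
# data-augmented probit (no spatial structure), coded separately from the
# package's sampler: z | beta truncated normal, beta | z conjugate normal
albert_chib_oracle <- function(y, x, n_draws, burn_in, beta_var = 100,
                               seed = 1) {
  set.seed(seed)
  n <- nrow(x); k <- ncol(x)
  prec <- crossprod(x) + diag(1 / beta_var, k)
  v <- solve(prec)
  ch <- chol(v)
  beta <- rep(0, k)
  keep <- matrix(NA_real_, n_draws - burn_in, k)
  rtrunc <- function(m, positive) {
    lo <- pnorm(-m)  # P(N(0,1) <= -m): mass of z = m + q below zero
    if (positive) m + qnorm(lo + runif(1) * (1 - lo))  # z > 0
    else          m + qnorm(runif(1) * lo)             # z <= 0
  }
  z <- ifelse(y == 1, 0.5, -0.5)
  for (it in seq_len(n_draws)) {
    eta <- drop(x %*% beta)
    for (i in seq_len(n)) z[i] <- rtrunc(eta[i], y[i] == 1)
    bbar <- v %*% crossprod(x, z)
    beta <- drop(bbar + t(ch) %*% rnorm(k))
    if (it > burn_in) keep[it - burn_in, ] <- beta
  }
  colnames(keep) <- colnames(x)
  keep
}

mcse_bm <- function(x, n_batches = 25) {
  n <- length(x)
  nb <- max(2, min(n_batches, floor(n / 10)))
  size <- floor(n / nb)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  sd(bm) / sqrt(nb)
}

# path to the deposited survey spreadsheet, when a user has supplied it
deposited_survey_path <- function() {
  p <- getOption("sarprobit.s1_path", Sys.getenv("SARPROBIT_S1", ""))
  if (!nzchar(p) || !file.exists(p)) {
    stop("deposited S1 survey spreadsheet not available; ",
         "set options(sarprobit.s1_path=) or SARPROBIT_S1 to its location")
  }
  p
}
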