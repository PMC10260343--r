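# Independent oracles used across the suite. These re-derive expected
# values by brute force or generic root-finding and never share code with
# the implementation paths they check.

# indifference-interval skeleton via generic root-finding on each step
oracle_skeleton <- function(target, halfwidth, prior_mtd, n_levels) {
  q <- numeric(n_levels)
  q[prior_mtd] <- target
  if (prior_mtd < n_levels) {
    for (k in prior_mtd:(n_levels - 1)) {
      astar <- uniroot(function(a) q[k]^a - (target - halfwidth),
                       c(1e-8, 1e8), tol = 1e-14)$root
      q[k + 1] <- uniroot(function(p) p^astar - (target + halfwidth),
                          c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    }
  }
  if (prior_mtd > 1) {
    for (k in prior_mtd:2) {
      astar <- uniroot(function(a) q[k]^a - (target + halfwidth),
                       c(1e-8, 1e8), tol = 1e-14)$root
      q[k - 1] <- uniroot(function(p) p^astar - (target - halfwidth),
                          c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    }
  }
  q
}

# direct per-patient log-likelihood summation
oracle_loglik <- function(p, y, a) {
  lam <- exp(a)
  sum(ifelse(y == 1, log(p^lam), log(1 - p^lam)))
}

# weighted isotonic fit by exhaustive search over contiguous level sets:
# every monotone solution is piecewise constant on blocks at the blocks'
# weighted means, so enumerate all 2^(n-1) block partitions
oracle_pava <- function(v, w) {
  n <- length(v)
  if (n == 1) return(v)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * v[idx]) / sum(w[idx])
    }
    if (any(diff(fit) < -1e-12)) next
    sse <- sum(w * (v - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# interim data of the worked example: four DLT-free patients on row-1
# levels 1-4, then a DLT at row-1 level 5
interim_state <- function() {
  trial_state(data.frame(patient = 1:5, row = 1L, level = 1:5,
                         dlt = c(0L, 0L, 0L, 0L, 1L)), dose_grid(7))
}

# minimal single-row two-stage ML-CRM simulator, used only to cross-check
# the sample-size calculator's PCS prediction
sim_single_row_crm_pcs <- function(n, n_doses, target, psi, n_rep) {
  skel <- lee_cheung_skeleton(target, 0.05, ceiling(n_doses / 2), n_doses)
  pcs <- vapply(seq_len(n_doses), function(nu) {
    pt <- plogis(qlogis(target) + (seq_len(n_doses) - nu) * log(psi))
    hits <- vapply(seq_len(n_rep), function(rep) {
      fit_rec <- function(ntr, ndlt) {
        idx <- which(ntr > 0)
        ah <- optimize(function(a) {
          lam <- exp(a)
          sum(ndlt[idx] * lam * log(skel[idx]) +
                (ntr[idx] - ndlt[idx]) * log1p(-skel[idx]^lam))
        }, c(-10, 10), maximum = TRUE)$maximum
        which.min(abs(skel^exp(ah) - target))
      }
      ntr <- ndlt <- integer(n_doses); cur <- 1L
      for (i in seq_len(n)) {
        ntr[cur] <- ntr[cur] + 1L
        ndlt[cur] <- ndlt[cur] + as.integer(runif(1) < pt[cur])
        if (sum(ndlt) > 0 && sum(ndlt) < sum(ntr)) {
          cur <- fit_rec(ntr, ndlt)
        } else if (sum(ndlt) == 0L) {
          cur <- min(cur + 1L, n_doses)
        }
      }
      if (sum(ndlt) == 0 || sum(ndlt) == sum(ntr)) return(FALSE)
      fit_rec(ntr, ndlt) == nu
    }, logical(1))
    mean(hits)
  }, numeric(1))
  mean(pcs)
}
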