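# Independent oracles and fixture builders used across the test files.

DAY <- 86400

# build a layer_network directly from a symmetric matrix
lnet <- function(A, layer_index = 1L) {
  structure(list(layer_index = layer_index, ids = rownames(A), A = A),
            class = "layer_network")
}

sym <- function(n, ids = paste0("n", seq_len(n))) {
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A
}

# sweep-line oracle: total pairwise co-occupancy seconds summed over all
# pairs, computed from box-occupancy segments, never from contact_time()
sweep_total_overlap <- function(visits) {
  tot <- 0
  for (b in unique(visits$box_id)) {
    v <- visits[visits$box_id == b, , drop = FALSE]
    cuts <- sort(unique(c(v$t_enter, v$t_exit)))
    if (length(cuts) < 2) next
    for (k in seq_len(length(cuts) - 1)) {
      lo <- cuts[k]; hi <- cuts[k + 1]
      present <- unique(v$tag_id[v$t_enter <= lo & v$t_exit >= hi])
      np <- length(present)
      if (np >= 2) tot <- tot + (hi - lo) * np * (np - 1) / 2
    }
  }
  tot
}

# all set partitions of 1..n as a list of integer label vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

# exhaustive minimum codelength over every partition of the state nodes
brute_force_codelength <- function(sn, tau = 0.01) {
  p <- stationary_flow(sn, tau)
  best <- Inf; best_part <- NULL
  for (part in all_partitions(nrow(sn$nodes))) {
    L <- codelength(sn, part, tau = tau, p = p)$L
    if (L < best - 1e-12) {
      best <- L; best_part <- part
    }
  }
  list(L = best, partition = best_part)
}

# dense eigen-solve oracle for the stationary distribution with uniform
# teleportation (dangling rows teleport fully)
eigen_flow <- function(sn, tau = 0.01) {
  n <- nrow(sn$nodes)
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(sn$edges))) {
    W[sn$edges$from[k], sn$edges$to[k]] <-
      W[sn$edges$from[k], sn$edges$to[k]] + sn$edges$w[k]
  }
  rs <- rowSums(W)
  P <- matrix(1 / n, n, n)
  live <- rs > 0
  P[live, ] <- tau / n + (1 - tau) * W[live, , drop = FALSE] / rs[live]
  v <- Re(eigen(t(P))$vectors[, 1])
  v / sum(v)
}

# Monte-Carlo oracle for multiple paternity: draw a qualifying litter
# uniformly, then two distinct offspring, and count differing fathers
mc_multiple_paternity <- function(pedigree, draws = 1e5) {
  lits <- split(pedigree$father_id, pedigree$litter_id)
  lits <- lits[vapply(lits, function(f) length(f) >= 2 && !anyNA(f), logical(1))]
  hits <- 0L
  for (d in seq_len(draws)) {
    f <- lits[[sample.int(length(lits), 1)]]
    pick <- sample.int(length(f), 2)
    if (f[pick[1]] != f[pick[2]]) hits <- hits + 1L
  }
  hits / draws
}

# quick simulated run -> networks + fit, shared by several tests
sim_fit <- function(seed, duration_days = 10, mixing = 0.05, r = 0.6,
                    n_modules = 2, birth_rate = 0, emigration_rate = 0, ...) {
  run <- simulate_run(sim_config(duration_days = duration_days,
                                 mixing = mixing, n_modules = n_modules,
                                 birth_rate = birth_rate,
                                 emigration_rate = emigration_rate, ...),
                      seed = seed)
  visits <- extract_visits(run$events)
  layers <- build_time_layers(run$events)
  nets <- co_occupancy_networks(visits, layers)
  fit <- fit_demes(nets, r = r, seed = seed)
  list(run = run, visits = visits, layers = layers, nets = nets, fit = fit)
}
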