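#' Normalized mutual information between two partitions
#'
#' Strehl-Ghosh normalisation I(A;B) / sqrt(H(A) H(B)), with entropies of
#' the module-membership frequencies over state nodes. Equal to 1 for
#' identical partitions up to relabelling; defined as 1 when both
#' partitions consist of a single module (no uncertainty to share), and 0
#' when exactly one of them does.
#'
#' @param a,b partitions over the same state-node set: either integer
#'   vectors of equal length or data.frames (tag_id, layer_index,
#'   module_id) over identical node sets.
#' @return value in [0, 1].
#' @export
nmi <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    ka <- paste(a$tag_id, a$layer_index, sep = "\r")
    kb <- paste(b$tag_id, b$layer_index, sep = "\r")
    if (length(ka) != length(kb) || !setequal(ka, kb)) {
      stop("partitions cover different state-node sets")
    }
    b <- b[match(ka, kb), , drop = FALSE]
    a <- a$module_id
    b <- b$module_id
  }
  if (length(a) != length(b)) stop("partitions cover different state-node sets")
  n <- length(a)
  tab <- table(a, b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(plogp(pj))
  hb <- -sum(plogp(pk))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pjk <- tab / n
  mi <- sum(pjk * log2(pjk / outer(pj, pk)), na.rm = TRUE)
  max(0, min(1, mi / sqrt(ha * hb)))
}

#' Choose the consensual relax rate by NMI
#'
#' For each experiment (a collection of layer networks), the multilayer
#' clustering is run at every relax rate of the grid; solutions are
#' compared pairwise by [nmi()], and each rate is scored by its mean NMI
#' against all other rates. The consensual rate maximises the median
#' across experiments of these means; ties resolve to the smaller rate.
#'
#' @param experiments list of layer-network collections (each a list of
#'   \code{layer_network}).
#' @param r_grid relax-rate grid (default 21 values equally spaced on
#'   [0, 1]).
#' @param tau teleportation rate.
#' @param seed integer seed; each (experiment, rate) fit gets a
#'   deterministic sub-seed.
#' @return list of class \code{relax_scan}: \code{r_star}, \code{r_grid},
#'   \code{mean_nmi} (experiments x rates matrix), \code{median_nmi},
#'   \code{partitions} (per experiment, per rate).
#' @export
select_relax_rate <- function(experiments, r_grid = seq(0, 1, length.out = 21),
                              tau = 0.01, seed = 1L) {
  stopifnot(length(experiments) >= 1)
  nr <- length(r_grid)
  mean_nmi <- matrix(NA_real_, length(experiments), nr)
  partitions <- vector("list", length(experiments))
  for (ei in seq_along(experiments)) {
    fits <- vector("list", nr)
    for (ri in seq_len(nr)) {
      fits[[ri]] <- fit_demes(experiments[[ei]], r = r_grid[ri], tau = tau,
                              seed = seed + 1000L * ei + ri)$partition
    }
    partitions[[ei]] <- fits
    nm <- matrix(1, nr, nr)
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        nm[i, j] <- nm[j, i] <- nmi(fits[[i]], fits[[j]])
      }
    }
    mean_nmi[ei, ] <- (rowSums(nm) - 1) / (nr - 1)
  }
  med <- apply(mean_nmi, 2, stats::median)
  r_star <- r_grid[which.max(med)]  # which.max takes the first (smallest r) tie
  structure(list(r_star = r_star, r_grid = r_grid, mean_nmi = mean_nmi,
                 median_nmi = med, partitions = partitions),
            class = "relax_scan")
}

#' @export
print.relax_scan <- function(x, ...) {
  cat("relax-rate scan over", length(x$r_grid), "values;",
      "consensual r* =", x$r_star, "\n")
  invisible(x)
}

#' One visit-reordering bootstrap replicate
#'
#' For every individual independently, the ordered sequence of visit start
#' times is kept fixed while the (box, duration) payloads are randomly
#' permuted among those slots; each visit then runs for its permuted
#' duration from its new start. Every individual therefore spends exactly
#' the same total time in the same nest boxes, but pairwise synchrony is
#' disturbed. Associations carried by many repeated encounters tend to
#' survive; those resting on a single long overlap are typically destroyed.
#'
#' @param visits visits data.frame.
#' @return permuted visits data.frame.
#' @export
bootstrap_replicate <- function(visits) {
  parts <- lapply(split(visits, visits$tag_id), function(v) {
    nv <- nrow(v)
    if (nv <= 1) return(v)
    o <- order(v$t_enter)
    v <- v[o, , drop = FALSE]
    perm <- sample.int(nv)
    dur <- v$t_exit - v$t_enter
    v$box_id <- v$box_id[perm]
    v$t_exit <- v$t_enter + dur[perm]
    v
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$t_enter, out$tag_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap distribution of modularity
#'
#' Runs the full pipeline (layer networks, multilayer clustering,
#' compression-rate modularity) on visit-reordering bootstrap replicates,
#' at each relax rate requested.
#'
#' @param visits observed visits.
#' @param layers layers data.frame (held fixed across replicates).
#' @param r_grid relax rate(s) at which to cluster.
#' @param reps number of bootstrap replicates.
#' @param tau teleportation rate.
#' @param seed integer seed.
#' @param identity if TRUE the permutation is forced to the identity
#'   (replicates equal the observed data; used for checking).
#' @return data.frame (rep, r, M) with attribute \code{"summary"}: per-r
#'   min, max and 2.5/97.5 percent quantiles.
#' @export
bootstrap_modularity <- function(visits, layers, r_grid = 0.6, reps = 100,
                                 tau = 0.01, seed = 1L, identity = FALSE) {
  stopifnot(reps >= 1)
  set.seed(seed)
  rows <- vector("list", reps * length(r_grid))
  k <- 0L
  for (b in seq_len(reps)) {
    vb <- if (identity) visits else bootstrap_replicate(visits)
    nets <- co_occupancy_networks(vb, layers)
    for (r in r_grid) {
      k <- k + 1L
      fit <- fit_demes(nets, r = r, tau = tau,
                       seed = sample.int(.Machine$integer.max, 1))
      rows[[k]] <- data.frame(rep = b, r = r, M = fit$M)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(out$r), function(r) {
    m <- out$M[out$r == r]
    data.frame(r = r, min = min(m), max = max(m),
               q025 = unname(stats::quantile(m, 0.025)),
               q975 = unname(stats::quantile(m, 0.975)))
  }))
  attr(out, "summary") <- summ
  out
}
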