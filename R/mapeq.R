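#' Build the multilayer state network
#'
#' Each individual present in a layer becomes a state node (tag, layer).
#' Intra-layer links carry weight (1 - r) * w_ij. Cross-layer links connect
#' a state node (i, l) to i's neighbours j in every other layer l', with
#' weight r * rho_i(l, l') * what_ij^l' * s_i^l, where what^l' are i's
#' neighbour weights in l' normalised to sum one, s_i^l is i's strength in
#' l, and rho_i(l, l') is the neighbourhood similarity
#' sigma_i(l, l') = sum_j min(what_ij^l, what_ij^l') (overlap coefficient)
#' normalised over all layers l'' != l. Cross-layer flow is therefore
#' strong exactly when a vertex keeps the same neighbours with similar
#' relative weights in both layers, and the relax rate r balances
#' within-layer against cross-layer flow.
#'
#' @param layer_networks list of \code{layer_network} objects.
#' @param r relax rate in [0, 1].
#' @return object of class \code{state_network}: list with \code{nodes}
#'   (data.frame tag_id, layer_index), \code{edges} (data.frame from, to,
#'   w; integer node indices) and \code{r}.
#' @export
build_multilayer <- function(layer_networks, r) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
    stop("relax rate r must lie in [0, 1]")
  }
  layer_networks <- layer_networks[vapply(layer_networks,
                                          function(x) length(x$ids) > 0, logical(1))]
  if (length(layer_networks) < 1) stop("need at least one non-empty layer")
  nodes <- do.call(rbind, lapply(layer_networks, function(nt) {
    data.frame(tag_id = nt$ids, layer_index = nt$layer_index,
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- NULL
  key <- paste(nodes$tag_id, nodes$layer_index, sep = "\r")
  idx <- seq_len(nrow(nodes))
  names(idx) <- key
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  # intra-layer links
  for (nt in layer_networks) {
    A <- nt$A
    nz <- which(A > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      from <- idx[paste(nt$ids[nz[, 1]], nt$layer_index, sep = "\r")]
      to <- idx[paste(nt$ids[nz[, 2]], nt$layer_index, sep = "\r")]
      ef <- c(ef, from); et <- c(et, to); ew <- c(ew, (1 - r) * A[nz])
    }
  }
  # cross-layer links
  if (r > 0 && length(layer_networks) > 1) {
    lidx <- vapply(layer_networks, function(nt) nt$layer_index, numeric(1))
    all_ids <- unique(nodes$tag_id)
    for (id in all_ids) {
      pres <- which(vapply(layer_networks, function(nt) id %in% nt$ids, logical(1)))
      if (length(pres) < 2) next
      # normalised neighbour-weight vectors and strengths per layer
      nb <- list(); s <- numeric(length(pres))
      for (a in seq_along(pres)) {
        nt <- layer_networks[[pres[a]]]
        wv <- nt$A[id, ]
        s[a] <- sum(wv)
        nb[[a]] <- if (s[a] > 0) wv[wv > 0] / s[a] else numeric(0)
      }
      for (a in seq_along(pres)) {
        if (s[a] == 0) next  # no outflow to relax
        sig <- vapply(seq_along(pres), function(b) {
          if (b == a || length(nb[[b]]) == 0) return(0)
          common <- intersect(names(nb[[a]]), names(nb[[b]]))
          if (!length(common)) return(0)
          sum(pmin(nb[[a]][common], nb[[b]][common]))
        }, numeric(1))
        tot <- sum(sig)
        if (tot == 0) next
        for (b in seq_along(pres)) {
          if (sig[b] == 0) next
          rho <- sig[b] / tot
          lb <- lidx[pres[b]]
          targ <- idx[paste(names(nb[[b]]), lb, sep = "\r")]
          ef <- c(ef, rep(idx[paste(id, lidx[pres[a]], sep = "\r")], length(targ)))
          et <- c(et, targ)
          ew <- c(ew, r * rho * nb[[b]] * s[a])
        }
      }
    }
  }
  edges <- data.frame(from = as.integer(ef), to = as.integer(et), w = ew)
  structure(list(nodes = nodes, edges = edges, r = r),
            class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat("state_network:", nrow(x$nodes), "state nodes,", nrow(x$edges),
      "directed links, r =", x$r, "\n")
  invisible(x)
}

#' Stationary visit rates of the random walk
#'
#' Power iteration on the row-normalised transition process with a uniform
#' teleportation probability tau that guarantees ergodicity; nodes without
#' out-links teleport with probability one. With tau = 0 on a single-layer
#' undirected network the visit rates are proportional to node strength.
#'
#' @param sn a \code{state_network}.
#' @param tau teleportation rate (default 0.01).
#' @param tol convergence tolerance on the L1 change (default 1e-14).
#' @return numeric vector p of visit rates summing to one.
#' @export
stationary_flow <- function(sn, tau = 0.01, tol = 1e-14) {
  n <- nrow(sn$nodes)
  e <- sn$edges
  if (nrow(e) == 0 || all(e$w == 0)) stop("network has no links")
  sout <- numeric(n)
  agg <- rowsum(e$w, e$from)
  sout[as.integer(rownames(agg))] <- agg[, 1]
  dangling <- sout == 0
  nw <- e$w / sout[e$from]
  p <- rep(1 / n, n)
  for (it in seq_len(20000)) {
    tele <- sum(p[dangling]) + tau * sum(p[!dangling])
    contrib <- (1 - tau) * p[e$from] * nw
    pn <- numeric(n)
    agg <- rowsum(contrib, e$to)
    pn[as.integer(rownames(agg))] <- agg[, 1]
    pn <- pn + tele / n
    pn <- (p + pn) / 2  # lazy walk: same stationary point, never periodic
    if (sum(abs(pn - p)) < tol) {
      p <- pn
      break
    }
    p <- pn
  }
  p / sum(p)
}

plogp <- function(x) {
  y <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  y[pos] <- x[pos] * log2(x[pos])
  y
}

#' Internal flow decomposition of a state network
#'
#' Splits the stationary flow of every node into a teleporting part
#' (t = p * tau, or all of p for dangling nodes) and per-link flows
#' f_ab = p_a * (1 - tau_a) * w_ab / s_a. These quantities are all the
#' map equation needs.
#' @keywords internal
flow_decomposition <- function(sn, tau = 0.01, p = NULL) {
  n <- nrow(sn$nodes)
  if (is.null(p)) p <- stationary_flow(sn, tau)
  e <- sn$edges
  sout <- numeric(n)
  agg <- rowsum(e$w, e$from)
  sout[as.integer(rownames(agg))] <- agg[, 1]
  dangling <- sout == 0
  taueff <- ifelse(dangling, 1, tau)
  f <- p[e$from] * (1 - taueff[e$from]) * e$w / sout[e$from]
  list(n = n, p = p, t = p * taueff,
       tag = match(sn$nodes$tag_id, unique(sn$nodes$tag_id)),
       ef = e$from, et = e$to, f = f)
}

#' Map-equation codelength of a partition
#'
#' Two-level map equation
#' L = q * H(Q) + sum_m p_m * H(P_m),
#' where q is the total module-exit flow, H(Q) the entropy of relative
#' module-exit flows, and each module codebook P_m holds the module's exit
#' flow plus the visit rates of its members. Members are PHYSICAL
#' individuals: the state nodes of one individual across layers share a
#' codeword within a module, their visit rates summing, so a module that
#' persists across many layers pays for its members once, not once per
#' layer. Exit flows combine link flow crossing the module boundary with
#' the teleporting flow landing outside the module. For the one-module
#' partition L equals the entropy of the individuals' total visit rates
#' exactly.
#'
#' @param sn a \code{state_network}.
#' @param partition integer vector of module ids, one per state node, or a
#'   data.frame with tag_id, layer_index, module_id covering all nodes.
#' @param tau teleportation rate.
#' @param p optional precomputed visit rates.
#' @return list of class \code{codelength_result}: \code{L} (bits/step),
#'   \code{index_term}, \code{module_terms}, \code{p}, \code{q_exit}.
#' @export
codelength <- function(sn, partition, tau = 0.01, p = NULL) {
  if (is.data.frame(partition)) partition <- partition_vector(sn, partition)
  n <- nrow(sn$nodes)
  if (length(partition) != n || anyNA(partition)) {
    stop("partition must assign every state node to a module")
  }
  fd <- flow_decomposition(sn, tau, p)
  mod <- match(partition, unique(partition))
  nm <- max(mod)
  P <- as.vector(rowsum(fd$p, mod))              # module visit rates
  Tm <- as.vector(rowsum(fd$t, mod))             # teleporting mass
  Nm <- as.vector(rowsum(rep(1, n), mod))        # node counts
  cross <- mod[fd$ef] != mod[fd$et]
  Q_link <- numeric(nm)
  if (any(cross)) {
    agg <- rowsum(fd$f[cross], mod[fd$ef][cross])
    Q_link[as.integer(rownames(agg))] <- agg[, 1]
  }
  q <- Tm * (n - Nm) / n + Q_link
  sumq <- sum(q)
  # member codewords per (module, physical individual)
  member_p <- rowsum(fd$p, paste(mod, fd$tag))
  L <- plogp(sumq) - 2 * sum(plogp(q)) + sum(plogp(q + P)) -
    sum(plogp(member_p))
  index_term <- if (sumq > 0) sumq * (-sum(plogp(q / sumq))) else 0
  member_mod <- as.integer(sub(" .*", "", rownames(member_p)))
  module_terms <- vapply(seq_len(nm), function(m) {
    pm <- q[m] + P[m]
    if (pm <= 0) return(0)
    ent <- -sum(plogp(c(q[m], member_p[member_mod == m]) / pm))
    pm * ent
  }, numeric(1))
  structure(list(L = L, index_term = index_term, module_terms = module_terms,
                 p = fd$p, q_exit = q),
            class = "codelength_result")
}

#' One-module codelength (entropy of the individuals' visit rates)
#' @inheritParams codelength
#' @return bits per step.
#' @export
codelength_one_module <- function(sn, tau = 0.01, p = NULL) {
  if (is.null(p)) p <- stationary_flow(sn, tau)
  -sum(plogp(rowsum(p, sn$nodes$tag_id)))
}

#' Convert a partition data.frame to a module vector over state nodes
#' @param sn state network.
#' @param partition data.frame (tag_id, layer_index, module_id).
#' @return integer vector aligned with \code{sn$nodes}.
#' @export
partition_vector <- function(sn, partition) {
  key <- paste(sn$nodes$tag_id, sn$nodes$layer_index, sep = "\r")
  pkey <- paste(partition$tag_id, partition$layer_index, sep = "\r")
  m <- partition$module_id[match(key, pkey)]
  if (anyNA(m)) {
    stop("partition is missing ", sum(is.na(m)), " state node(s)")
  }
  m
}

#' Minimise the map-equation codelength by the Louvain method
#'
#' Local moves (each node greedily joins the neighbouring module that most
#' reduces L, in an order shuffled by the random seed) alternate with
#' aggregation of modules into super-nodes, until no move reduces L by more
#' than \code{tol} bits. The search is unconstrained: modules can be of any
#' size and composition. If the best partition found does not compress
#' below the one-module codelength, the one-module partition is returned
#' (so the compression-rate modularity is never below one).
#'
#' @param sn a \code{state_network}.
#' @param tau teleportation rate.
#' @param seed integer seed controlling the sweep order (NULL = leave the
#'   RNG state alone).
#' @param tol convergence tolerance in bits (default 1e-10).
#' @param max_passes maximum outer (aggregation) passes.
#' @return list with \code{partition} (integer vector over state nodes,
#'   labels in order of first appearance), \code{L_before}, \code{L_after},
#'   \code{M} (= L_before / L_after) and \code{p}.
#' @export
louvain_minimize <- function(sn, tau = 0.01, seed = NULL, tol = 1e-10,
                             max_passes = 100) {
  if (!is.null(seed)) set.seed(seed)
  fd <- flow_decomposition(sn, tau)
  n_orig <- fd$n
  # working copies at the current aggregation level; each node carries its
  # composition of (physical individual, visit rate) pairs
  p <- fd$p; tl <- fd$t; sz <- rep(1L, fd$n)
  ef <- fd$ef; et <- fd$et; f <- fd$f
  comp_tag <- as.list(fd$tag)
  comp_p <- as.list(fd$p)
  assign_orig <- seq_len(fd$n)  # original node -> current-level node
  L_one <- -sum(plogp(rowsum(fd$p, fd$tag)))
  part <- assign_orig
  L_prev <- Inf
  for (pass in seq_len(max_passes)) {
    res <- .local_moves(p, tl, sz, ef, et, f, comp_tag, comp_p, n_orig)
    cand_part <- res$mod[assign_orig]
    L_true <- .partition_codelength(fd, cand_part)
    if (!(L_true < L_prev - tol)) break
    L_prev <- L_true
    part <- cand_part
    # aggregate modules into super-nodes and repeat on the coarse graph
    remap <- match(res$mod, sort(unique(res$mod)))
    p <- as.vector(rowsum(p, remap))
    tl <- as.vector(rowsum(tl, remap))
    sz <- as.vector(rowsum(as.numeric(sz), remap))
    newcomp_tag <- vector("list", max(remap))
    newcomp_p <- vector("list", max(remap))
    for (m in seq_len(max(remap))) {
      members <- which(remap == m)
      tg <- unlist(comp_tag[members])
      pp <- rowsum(unlist(comp_p[members]), tg)
      newcomp_tag[[m]] <- as.integer(rownames(pp))
      newcomp_p[[m]] <- pp[, 1]
    }
    comp_tag <- newcomp_tag; comp_p <- newcomp_p
    if (length(ef)) {
      gf <- remap[ef]; gt <- remap[et]
      key <- paste(gf, gt)
      aggw <- rowsum(f, key)
      ks <- strsplit(rownames(aggw), " ", fixed = TRUE)
      ef <- vapply(ks, function(z) as.integer(z[1]), integer(1))
      et <- vapply(ks, function(z) as.integer(z[2]), integer(1))
      f <- aggw[, 1]
    }
    assign_orig <- remap[assign_orig]
    if (length(p) == 1L) break
  }
  L_after <- .partition_codelength(fd, part)
  if (L_after >= L_one - 1e-12) {
    part <- rep(1L, n_orig)
    L_after <- L_one
  }
  part <- relabel_first_appearance(part, sn$nodes)
  list(partition = part, L_before = L_one, L_after = L_after,
       M = L_one / L_after, p = fd$p)
}

# codelength from a flow decomposition and a module vector (no re-solve)
.partition_codelength <- function(fd, mod) {
  mod <- match(mod, unique(mod))
  n <- fd$n
  P <- as.vector(rowsum(fd$p, mod))
  Tm <- as.vector(rowsum(fd$t, mod))
  Nm <- as.vector(rowsum(rep(1, n), mod))
  nm <- max(mod)
  Q_link <- numeric(nm)
  cross <- mod[fd$ef] != mod[fd$et]
  if (any(cross)) {
    agg <- rowsum(fd$f[cross], mod[fd$ef][cross])
    Q_link[as.integer(rownames(agg))] <- agg[, 1]
  }
  q <- Tm * (n - Nm) / n + Q_link
  member_p <- rowsum(fd$p, paste(mod, fd$tag))
  plogp(sum(q)) - 2 * sum(plogp(q)) + sum(plogp(q + P)) -
    sum(plogp(member_p))
}

# one level of Louvain local moves; nodes carry aggregate p, teleport mass,
# size (original node count) and a composition of physical individuals;
# n_orig is the original state-node count used by the teleportation exit
# term, and member codewords are shared per (module, individual).
.local_moves <- function(p, tl, sz, ef, et, f, comp_tag, comp_p, n_orig) {
  n <- length(p)
  mod <- seq_len(n)
  # per-module member rates, keyed by physical individual
  Mt <- vector("list", n)
  for (i in seq_len(n)) {
    Mt[[i]] <- stats::setNames(comp_p[[i]], as.character(comp_tag[[i]]))
  }
  plogp1 <- function(x) if (x > 0) x * log2(x) else 0
  # change in the member term (-sum plogp) when moving node i out of module
  # a and into module b
  member_delta <- function(i, a, b) {
    d <- 0
    tga <- as.character(comp_tag[[i]]); cp <- comp_p[[i]]
    va <- Mt[[a]]
    for (k in seq_along(tga)) {
      T0 <- va[[tga[k]]]
      d <- d + plogp1(T0) - plogp1(T0 - cp[k])
    }
    vb <- if (b >= 1 && b <= length(Mt) && !is.null(Mt[[b]])) Mt[[b]]
          else numeric(0)
    for (k in seq_along(tga)) {
      T0 <- if (tga[k] %in% names(vb)) vb[[tga[k]]] else 0
      d <- d + plogp1(T0) - plogp1(T0 + cp[k])
    }
    d
  }
  apply_member_move <- function(i, a, b) {
    tga <- as.character(comp_tag[[i]]); cp <- comp_p[[i]]
    va <- Mt[[a]]
    va[tga] <- va[tga] - cp
    Mt[[a]] <<- va[va > 1e-300]
    vb <- if (b >= 1 && b <= length(Mt) && !is.null(Mt[[b]])) Mt[[b]]
          else numeric(0)
    for (k in seq_along(tga)) {
      if (tga[k] %in% names(vb)) {
        vb[[tga[k]]] <- vb[[tga[k]]] + cp[k]
      } else {
        vb[[tga[k]]] <- cp[k]
      }
    }
    if (b > length(Mt)) Mt[[b]] <<- vb else Mt[[b]] <<- vb
  }
  # drop self-loops from cross-flow bookkeeping (they never exit)
  keep <- ef != et
  ef2 <- ef[keep]; et2 <- et[keep]; f2 <- f[keep]
  out_adj <- split(seq_along(ef2), ef2)
  in_adj <- split(seq_along(et2), et2)
  Pm <- p; Tm <- tl; Nm <- as.numeric(sz)
  # initial exit flows: every node its own module
  qm <- Tm * (n_orig - Nm) / n_orig
  if (length(ef2)) {
    agg <- rowsum(f2, ef2)
    qm[as.integer(rownames(agg))] <- qm[as.integer(rownames(agg))] + agg[, 1]
  }
  sumq <- sum(qm)
  improved_any <- TRUE
  sweeps <- 0L
  while (improved_any && sweeps < 50L) {
    improved_any <- FALSE
    sweeps <- sweeps + 1L
    ord <- sample.int(n)
    for (alpha in ord) {
      a <- mod[alpha]
      oa <- out_adj[[as.character(alpha)]]
      ia <- in_adj[[as.character(alpha)]]
      out_to <- if (length(oa)) mod[et2[oa]] else integer(0)
      in_from <- if (length(ia)) mod[ef2[ia]] else integer(0)
      out_tot <- if (length(oa)) sum(f2[oa]) else 0
      in_tot <- if (length(ia)) sum(f2[ia]) else 0
      out_by_mod <- if (length(oa)) rowsum(f2[oa], out_to) else NULL
      in_by_mod <- if (length(ia)) rowsum(f2[ia], in_from) else NULL
      getom <- function(m) {
        if (is.null(out_by_mod)) return(0)
        j <- match(as.character(m), rownames(out_by_mod))
        if (is.na(j)) 0 else out_by_mod[j, 1]
      }
      getim <- function(m) {
        if (is.null(in_by_mod)) return(0)
        j <- match(as.character(m), rownames(in_by_mod))
        if (is.na(j)) 0 else in_by_mod[j, 1]
      }
      cand <- unique(c(out_to, in_from))
      cand <- cand[cand != a]
      if (Nm[a] > sz[alpha]) cand <- c(cand, 0L)  # 0 = fresh module
      if (!length(cand)) next
      # state of module a with alpha removed
      q_a_new <- (Tm[a] - tl[alpha]) * (n_orig - (Nm[a] - sz[alpha])) / n_orig +
        (qm[a] - Tm[a] * (n_orig - Nm[a]) / n_orig) -
        (out_tot - getom(a)) + getim(a)
      P_a_new <- Pm[a] - p[alpha]
      old_terms_a <- -2 * plogp(qm[a]) + plogp(qm[a] + Pm[a])
      best_dL <- -1e-14; best_b <- NA_integer_; best_qb <- NA_real_
      for (b in cand) {
        if (b == 0L) {
          q_b_old <- 0; P_b_old <- 0; T_b_old <- 0; N_b_old <- 0
        } else {
          q_b_old <- qm[b]; P_b_old <- Pm[b]; T_b_old <- Tm[b]; N_b_old <- Nm[b]
        }
        q_b_link_old <- q_b_old - T_b_old * (n_orig - N_b_old) / n_orig
        q_b_new <- (T_b_old + tl[alpha]) *
          (n_orig - (N_b_old + sz[alpha])) / n_orig +
          q_b_link_old + (out_tot - getom(b)) - getim(b)
        sq_new <- sumq - qm[a] - q_b_old + q_a_new + q_b_new
        dL <- (plogp(sq_new) - plogp(sumq)) -
          2 * (plogp(q_a_new) + plogp(q_b_new) - plogp(qm[a]) - plogp(q_b_old)) +
          (plogp(q_a_new + P_a_new) + plogp(q_b_new + P_b_old + p[alpha]) -
             plogp(qm[a] + Pm[a]) - plogp(q_b_old + P_b_old)) +
          member_delta(alpha, a, b)
        if (dL < best_dL) {
          best_dL <- dL; best_b <- b; best_qb <- q_b_new
        }
      }
      if (!is.na(best_b)) {
        b <- best_b
        if (b == 0L) {
          b <- length(qm) + 1L
          qm <- c(qm, 0); Pm <- c(Pm, 0); Tm <- c(Tm, 0); Nm <- c(Nm, 0)
        }
        apply_member_move(alpha, a, b)
        q_b_new <- best_qb
        sumq <- sumq - qm[a] - qm[b] + q_a_new + q_b_new
        qm[a] <- q_a_new; qm[b] <- q_b_new
        Pm[a] <- Pm[a] - p[alpha]; Pm[b] <- Pm[b] + p[alpha]
        Tm[a] <- Tm[a] - tl[alpha]; Tm[b] <- Tm[b] + tl[alpha]
        Nm[a] <- Nm[a] - sz[alpha]; Nm[b] <- Nm[b] + sz[alpha]
        mod[alpha] <- b
        improved_any <- TRUE
      }
    }
  }
  list(mod = match(mod, unique(mod)))
}

#' Relabel modules in order of first appearance
#'
#' Module labels are assigned 1, 2, ... by the earliest layer (then tag
#' order) in which any member state node appears, keeping labels stable for
#' module-persistence displays.
#'
#' @param part integer module vector.
#' @param nodes state-node table (tag_id, layer_index).
#' @return relabelled integer vector.
#' @export
relabel_first_appearance <- function(part, nodes) {
  ord <- order(nodes$layer_index, nodes$tag_id)
  first <- part[ord][!duplicated(part[ord])]
  match(part, first)
}

#' Compression-rate modularity under a fixed partition, on filtered edges
#'
#' Rebuilds the multilayer state network keeping only interactions of a
#' given sex class (female-female, male-male or female-male) among adults,
#' then evaluates the one-module and the fixed-partition codelength on the
#' filtered flow and returns their ratio. With \code{filter = "all"} the
#' layer networks are used as-is, so the result equals the full-data M
#' under the same fixed partition.
#'
#' @param layer_networks list of \code{layer_network}.
#' @param partition data.frame (tag_id, layer_index, module_id) from a fit;
#'   kept fixed.
#' @param filter one of "all", "FF", "MM", "FM".
#' @param individuals metadata with tag_id, sex, birth_time (required
#'   unless filter = "all").
#' @param layers layers data.frame (for layer mid-times; required unless
#'   filter = "all").
#' @param r relax rate used to rebuild the state network.
#' @param tau teleportation rate.
#' @param adult_age_days adulthood threshold applied at the layer mid-time.
#' @return list with \code{M}, \code{L_before}, \code{L_after}.
#' @export
modularity_for_subgraph <- function(layer_networks, partition,
                                    filter = c("all", "FF", "MM", "FM"),
                                    individuals = NULL, layers = NULL,
                                    r = 0.6, tau = 0.01,
                                    adult_age_days = 50) {
  filter <- match.arg(filter)
  nets <- layer_networks
  if (filter != "all") {
    if (is.null(individuals) || is.null(layers)) {
      stop("individuals and layers are required for sex-specific filters")
    }
    sex <- stats::setNames(individuals$sex, individuals$tag_id)
    birth <- stats::setNames(individuals$birth_time, individuals$tag_id)
    nets <- lapply(layer_networks, function(nt) {
      if (!length(nt$ids)) return(nt)
      mid <- layers$mid_time_days[match(nt$layer_index, layers$index)] * DAY
      adult <- nt$ids[!is.na(birth[nt$ids]) &
                        (mid - birth[nt$ids]) / DAY >= adult_age_days]
      A <- nt$A[adult, adult, drop = FALSE]
      if (length(adult) >= 2) {
        sx <- sex[adult]
        pairsex <- outer(sx, sx, function(a, b) paste0(pmin(a, b), pmax(a, b)))
        want <- switch(filter, FF = "FF", MM = "MM", FM = "FM")
        A[pairsex != want] <- 0
      }
      structure(list(layer_index = nt$layer_index, ids = adult, A = A),
                class = "layer_network")
    })
  }
  nets <- nets[vapply(nets, function(x) length(x$ids) > 0, logical(1))]
  if (!length(nets) || all(vapply(nets, function(x) sum(x$A), numeric(1)) == 0)) {
    stop("no interactions of requested class")
  }
  sn <- build_multilayer(nets, r)
  p <- stationary_flow(sn, tau)
  pv <- partition_vector(sn, partition)
  L_before <- codelength_one_module(sn, tau, p)
  L_after <- codelength(sn, pv, tau, p)$L
  list(M = L_before / L_after, L_before = L_before, L_after = L_after)
}
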