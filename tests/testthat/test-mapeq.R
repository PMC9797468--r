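triangle <- function(layer = 1L, ids = c("a", "b", "c"), w = 1) {
  A <- sym(3, ids)
  A[upper.tri(A)] <- w
  A <- A + t(A)
  lnet(A, layer)
}

test_that("stationary flow matches symmetry and strength closed forms", {
  sn <- build_multilayer(list(triangle()), 0)
  expect_equal(stationary_flow(sn, tau = 0.01), rep(1 / 3, 3), tolerance = 1e-10)

  # path a-b-c: visit rates proportional to strength as tau -> 0
  A <- sym(3, c("a", "b", "c"))
  A["a", "b"] <- A["b", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  sn2 <- build_multilayer(list(lnet(A)), 0)
  expect_equal(stationary_flow(sn2, tau = 1e-10), c(0.25, 0.5, 0.25),
               tolerance = 1e-6)

  expect_error(stationary_flow(build_multilayer(list(lnet(sym(2))), 0)),
               "no links")
})

test_that("stationary flow matches a dense eigen solve on random graphs", {
  set.seed(5)
  for (rep in 1:3) {
    A <- matrix(runif(25), 5, 5)
    A <- A + t(A); diag(A) <- 0
    dimnames(A) <- list(paste0("n", 1:5), paste0("n", 1:5))
    sn <- build_multilayer(list(lnet(A)), 0)
    expect_equal(stationary_flow(sn, tau = 0.01), eigen_flow(sn, tau = 0.01),
                 tolerance = 1e-9)
  }
})

test_that("codelength reduces to the visit-rate entropy for one module", {
  set.seed(6)
  A <- matrix(runif(36), 6, 6); A <- A + t(A); diag(A) <- 0
  dimnames(A) <- list(letters[1:6], letters[1:6])
  sn <- build_multilayer(list(lnet(A)), 0)
  p <- stationary_flow(sn, tau = 0.01)
  cl <- codelength(sn, rep(1L, 6), tau = 0.01, p = p)
  expect_equal(cl$L, -sum(ifelse(p > 0, p * log2(p), 0)), tolerance = 1e-12)
  expect_equal(cl$L, codelength_one_module(sn, tau = 0.01, p = p))
})

test_that("two disconnected triangles give the hand-derived codelengths", {
  sn <- build_multilayer(make_fixture("two_triangles"), 0)
  p <- stationary_flow(sn, tau = 0)
  expect_equal(p, rep(1 / 6, 6), tolerance = 1e-12)
  # by components: q = 0, L = 2 * (1/2) * log2(3)
  two <- codelength(sn, c(1, 1, 1, 2, 2, 2), tau = 0, p = p)
  expect_equal(two$L, log2(3), tolerance = 1e-9)
  expect_equal(two$index_term + sum(two$module_terms), two$L, tolerance = 1e-12)
  # one module: H(p) = log2 6
  expect_equal(codelength_one_module(sn, tau = 0, p = p), log2(6),
               tolerance = 1e-12)
  # singletons are strictly worse than components
  single <- codelength(sn, 1:6, tau = 0, p = p)
  expect_gt(single$L, two$L)
  expect_error(codelength(sn, c(1, 1, 1)), "every state node")
})

test_that("multilayer coupling follows the similarity-weighted formulas", {
  expect_error(build_multilayer(list(triangle()), 1.5), "relax rate")

  # r = 0: no cross-layer links, block-diagonal by layer
  sn0 <- build_multilayer(list(triangle(1L), triangle(2L)), 0)
  lay <- sn0$nodes$layer_index
  expect_true(all(lay[sn0$edges$from] == lay[sn0$edges$to]))

  # two identical layers, r = 0.5: sigma = 1, so cross-layer out-weight
  # equals intra-layer out-weight for every state node
  snh <- build_multilayer(list(triangle(1L), triangle(2L)), 0.5)
  lay <- snh$nodes$layer_index
  for (v in seq_len(nrow(snh$nodes))) {
    eo <- snh$edges[snh$edges$from == v, ]
    intra <- sum(eo$w[lay[eo$to] == lay[v]])
    cross <- sum(eo$w[lay[eo$to] != lay[v]])
    expect_equal(intra, cross, tolerance = 1e-12)
  }

  # disjoint neighbourhoods: sigma = 0, no cross-layer flow for that node
  A1 <- sym(3, c("i", "j", "k")); A1["i", "j"] <- A1["j", "i"] <- 1
  A2 <- sym(3, c("i", "k", "l")); A2["i", "k"] <- A2["k", "i"] <- 1
  snd <- build_multilayer(list(lnet(A1, 1L), lnet(A2, 2L)), 0.5)
  lay <- snd$nodes$layer_index
  crossw <- snd$edges$w[lay[snd$edges$from] != lay[snd$edges$to]]
  expect_equal(sum(crossw), 0)
})

test_that("the optimiser recovers components and matches brute force", {
  sn <- build_multilayer(make_fixture("two_triangles"), 0)
  res <- louvain_minimize(sn, tau = 0.01, seed = 3)
  expect_equal(res$partition, c(1, 1, 1, 2, 2, 2))
  bf <- brute_force_codelength(sn, tau = 0.01)
  expect_equal(res$L_after, bf$L, tolerance = 1e-9)
  expect_equal(res$M, res$L_before / res$L_after)

  # complete graph with equal weights: nothing to compress, M = 1
  A <- sym(5); A[] <- 1; diag(A) <- 0
  snc <- build_multilayer(list(lnet(A)), 0)
  resc <- louvain_minimize(snc, seed = 1)
  expect_equal(resc$M, 1)
  expect_equal(length(unique(resc$partition)), 1)
})

test_that("the optimiser attains the global optimum on small multilayer nets", {
  # 4 state nodes over 2 layers, r = 0.6
  A1 <- sym(2, c("a", "b")); A1["a", "b"] <- A1["b", "a"] <- 3
  A2 <- sym(2, c("a", "b")); A2["a", "b"] <- A2["b", "a"] <- 1
  sn <- build_multilayer(list(lnet(A1, 1L), lnet(A2, 2L)), 0.6)
  res <- louvain_minimize(sn, seed = 7)
  bf <- brute_force_codelength(sn, tau = 0.01)
  expect_equal(res$L_after, bf$L, tolerance = 1e-9)

  # random weighted 7-node single layer
  set.seed(9)
  A <- matrix(rbinom(49, 1, 0.5) * runif(49), 7, 7)
  A <- A + t(A); diag(A) <- 0
  A[1:3, 4:7] <- A[1:3, 4:7] / 10; A[4:7, 1:3] <- t(A[1:3, 4:7])
  dimnames(A) <- list(paste0("n", 1:7), paste0("n", 1:7))
  snr <- build_multilayer(list(lnet(A)), 0)
  resr <- louvain_minimize(snr, seed = 11)
  bfr <- brute_force_codelength(snr, tau = 0.01)
  expect_equal(resr$L_after, bfr$L, tolerance = 1e-9)
})

test_that("fits are deterministic under a fixed seed and never report M < 1", {
  set.seed(30)
  for (rep in 1:4) {
    n <- sample(4:7, 1)
    A <- matrix(rbinom(n * n, 1, 0.6) * runif(n * n), n, n)
    A <- A + t(A); diag(A) <- 0
    if (sum(A) == 0) next
    dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
    sn <- build_multilayer(list(lnet(A)), 0)
    r1 <- louvain_minimize(sn, seed = 99)
    r2 <- louvain_minimize(sn, seed = 99)
    expect_identical(r1$partition, r2$partition)
    expect_gte(r1$M, 1)
  }
})

test_that("r = 0 clustering equals independent layer-by-layer clustering", {
  # each layer holds two disconnected triangles: real within-layer structure
  A <- sym(6, letters[1:6])
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  nets <- list(lnet(A, 1L), lnet(A, 2L))
  # without teleportation the disjoint union's codelength is the mean of
  # the per-layer codelengths, and the within-layer clusterings agree
  fit0 <- fit_demes(nets, r = 0, tau = 0, seed = 2)
  per <- lapply(nets, function(nt) fit_demes(list(nt), r = 0, tau = 0, seed = 2))
  expect_equal(fit0$L_after, mean(vapply(per, function(f) f$L_after, numeric(1))),
               tolerance = 1e-9)
  for (k in 1:2) {
    sub <- fit0$partition[fit0$partition$layer_index == nets[[k]]$layer_index, ]
    expect_equal(nmi(sub$module_id[match(per[[k]]$partition$tag_id, sub$tag_id)],
                     per[[k]]$partition$module_id), 1)
  }
})

test_that("found partitions compress at least as well as the planted truth", {
  sf <- sim_fit(seed = 55, duration_days = 6, mixing = 0.05)
  sn <- sf$fit$state_network
  p <- stationary_flow(sn, 0.01)
  planted <- partition_vector(sn, planted_partition(sf$run, sf$fit$partition))
  L_planted <- codelength(sn, planted, 0.01, p)$L
  expect_lte(sf$fit$L_after, L_planted + 1e-9)
})

test_that("module labels are assigned in order of first appearance", {
  sf <- sim_fit(seed = 77, duration_days = 6, mixing = 0.02)
  pt <- sf$fit$partition
  first_layer <- tapply(pt$layer_index, pt$module_id, min)
  expect_true(all(diff(first_layer[order(as.integer(names(first_layer)))]) >= 0))
})

test_that("sex-filtered modularity keeps the identity under the full filter", {
  sf <- sim_fit(seed = 31, duration_days = 6, mixing = 0.05)
  full <- modularity_for_subgraph(sf$nets, sf$fit$partition, filter = "all",
                                  r = 0.6)
  expect_equal(full$M, sf$fit$L_before / sf$fit$L_after, tolerance = 1e-9)

  # single-sex network, opposite-sex filter: error
  inds <- sf$run$individuals
  males <- inds$tag_id[inds$sex == "M"]
  nets_m <- lapply(sf$nets, function(nt) {
    keep <- intersect(nt$ids, males)
    lnet(nt$A[keep, keep, drop = FALSE], nt$layer_index)
  })
  expect_error(
    modularity_for_subgraph(nets_m, sf$fit$partition, filter = "FF",
                            individuals = inds, layers = sf$layers, r = 0.6),
    "no interactions")
})
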