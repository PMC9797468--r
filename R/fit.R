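#' Fit persistent social modules to time-layered co-occupancy networks
#'
#' The central estimator of the package. A multilayer state network is
#' built from the per-layer co-occupancy networks (cross-layer coupling by
#' neighbourhood similarity, balanced by the relax rate \code{r}), the
#' map-equation codelength of a random walk on it is minimised by the
#' Louvain method, and the result is summarised by the compression-rate
#' modularity M = L_before / L_after, the ratio of the one-module
#' codelength to the partitioned codelength. M is 1 when no partition
#' compresses the walk and grows with the tightness and exclusiveness of
#' the module structure.
#'
#' @param networks a list of \code{layer_network} objects
#'   (see [co_occupancy_networks()]), or a single \code{layer_network}.
#' @param r relax rate in [0, 1]; 0 clusters layers independently.
#' @param tau teleportation rate of the random walk (default 0.01).
#' @param seed integer seed for the optimiser's sweep order.
#' @param tol convergence tolerance of the optimiser, in bits.
#' @return an object of class \code{"demefit"}: list with
#'   \describe{
#'     \item{partition}{data.frame (tag_id, layer_index, module_id); module
#'       ids are stable across layers, numbered by first appearance.}
#'     \item{L_before, L_after}{one-module and partitioned codelength, bits
#'       per walk step.}
#'     \item{M}{compression-rate modularity, L_before / L_after.}
#'     \item{r, tau, seed}{the parameters used.}
#'     \item{flow}{stationary visit rates of the state nodes.}
#'   }
#' @examples
#' nets <- make_fixture("two_triangles")
#' fit <- fit_demes(nets, r = 0, seed = 1)
#' fit$M
#' @export
fit_demes <- function(networks, r = 0.6, tau = 0.01, seed = NULL,
                      tol = 1e-10) {
  if (inherits(networks, "layer_network")) networks <- list(networks)
  sn <- build_multilayer(networks, r)
  res <- louvain_minimize(sn, tau = tau, seed = seed, tol = tol)
  partition <- data.frame(tag_id = sn$nodes$tag_id,
                          layer_index = sn$nodes$layer_index,
                          module_id = res$partition,
                          stringsAsFactors = FALSE)
  structure(list(partition = partition,
                 L_before = res$L_before, L_after = res$L_after,
                 M = res$M, r = r, tau = tau, seed = seed,
                 flow = res$p, state_network = sn,
                 call = match.call()),
            class = "demefit")
}

#' @export
print.demefit <- function(x, ...) {
  cat("Multilayer map-equation module fit\n")
  cat(sprintf("  state nodes: %d  layers: %d  modules: %d\n",
              nrow(x$partition), length(unique(x$partition$layer_index)),
              length(unique(x$partition$module_id))))
  cat(sprintf("  relax rate r = %.2f, teleportation tau = %.3g\n", x$r, x$tau))
  cat(sprintf("  codelength: %.4f -> %.4f bits/step  (modularity M = %.3f)\n",
              x$L_before, x$L_after, x$M))
  invisible(x)
}

#' @export
summary.demefit <- function(object, ...) {
  pt <- object$partition
  mods <- sort(unique(pt$module_id))
  tab <- do.call(rbind, lapply(mods, function(m) {
    sub <- pt[pt$module_id == m, ]
    data.frame(module_id = m,
               n_individuals = length(unique(sub$tag_id)),
               n_state_nodes = nrow(sub),
               first_layer = min(sub$layer_index),
               last_layer = max(sub$layer_index))
  }))
  out <- list(modules = tab, M = object$M, L_before = object$L_before,
              L_after = object$L_after, r = object$r)
  class(out) <- "summary.demefit"
  out
}

#' @export
print.summary.demefit <- function(x, ...) {
  cat(sprintf("Modularity M = %.3f (L %.4f -> %.4f bits/step, r = %.2f)\n",
              x$M, x$L_before, x$L_after, x$r))
  cat("Modules (labelled by first appearance):\n")
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Module-membership raster plot
#'
#' Rows are individuals, columns are time layers, colours are modules;
#' blank cells mark layers in which an individual entered no box.
#'
#' @param x a \code{demefit}.
#' @param layers optional layers data.frame; when given, the x axis is in
#'   days (layer mid-times) instead of layer index.
#' @param ... passed to [graphics::image()].
#' @export
plot.demefit <- function(x, layers = NULL, ...) {
  pt <- x$partition
  ids <- unique(pt$tag_id[order(pt$layer_index)])
  lidx <- sort(unique(pt$layer_index))
  z <- matrix(NA_real_, length(lidx), length(ids))
  z[cbind(match(pt$layer_index, lidx), match(pt$tag_id, ids))] <- pt$module_id
  xat <- if (!is.null(layers)) layers$mid_time_days[match(lidx, layers$index)] else lidx
  nmod <- max(pt$module_id)
  graphics::image(x = xat, y = seq_along(ids), z = z,
                  col = grDevices::hcl.colors(nmod, "Dark 3"),
                  xlab = if (is.null(layers)) "time layer" else "days since start",
                  ylab = "individual", yaxt = "n", ...)
  invisible(x)
}

#' Report a fit as a codelength JSON file
#'
#' @param fit a \code{demefit}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_codelength_report <- function(fit, path) {
  jsonlite::write_json(
    list(L_before = fit$L_before, L_after = fit$L_after, M = fit$M,
         r = fit$r, tau = fit$tau,
         seed = if (is.null(fit$seed)) NA else fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
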