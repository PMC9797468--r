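#' Module distinctiveness of one time layer
#'
#' For every individual with positive total interaction time in the layer,
#' the proportion of that time spent with members of its own module; the
#' index is the unweighted mean of these proportions. 1.00 means all
#' individuals met in the boxes only with members of their modules (a
#' single-module layer is 1.00 by construction). Individuals with no
#' interactions are excluded; if nobody interacted the value is NA.
#'
#' @param layer_network a \code{layer_network}.
#' @param partition data.frame (tag_id, layer_index, module_id) or a named
#'   vector of module ids for the layer's individuals.
#' @param pooled also return the time-pooled variant (total intramodular
#'   over total interaction time) as attribute \code{"pooled"}.
#' @return mean proportion in [0, 1], or NA.
#' @export
distinctiveness <- function(layer_network, partition, pooled = TRUE) {
  ids <- layer_network$ids
  mod <- .layer_modules(partition, layer_network)
  A <- layer_network$A
  tot <- rowSums(A)
  same <- outer(mod, mod, "==")
  intra <- rowSums(A * same)
  keep <- tot > 0
  val <- if (any(keep)) mean(intra[keep] / tot[keep]) else NA_real_
  if (pooled) {
    attr(val, "pooled") <- if (any(keep)) sum(intra[keep]) / sum(tot[keep]) else NA_real_
  }
  val
}

.layer_modules <- function(partition, layer_network) {
  ids <- layer_network$ids
  if (is.data.frame(partition)) {
    sub <- partition[partition$layer_index == layer_network$layer_index, ]
    mod <- sub$module_id[match(ids, sub$tag_id)]
  } else {
    mod <- unname(partition[ids])
  }
  if (anyNA(mod)) stop("partition does not cover all individuals of the layer")
  mod
}

#' Spatial separation of modules in one time layer
#'
#' Per box, the times spent by members of each module are divided by the
#' total usage of the box, giving box possession values; their maximum is
#' the box usage exclusivity. The layer index is the weighted mean of
#' exclusivities with weights proportional to total box usage. Unoccupied
#' boxes are excluded. Solitary box time counts towards usage.
#'
#' @param layer_visits visits of one layer (clipped to it), with a
#'   \code{layer_index} column or all from the same layer.
#' @param partition module assignment (data.frame or named vector), as in
#'   [distinctiveness()].
#' @param layer_index the layer's index (needed when \code{partition} is a
#'   data.frame and \code{layer_visits} lacks the column).
#' @return list of class \code{separation_index}: \code{index},
#'   \code{possession} (modules x boxes matrix), \code{exclusivity},
#'   \code{usage} (seconds per box). \code{index} is NA when no box was
#'   used.
#' @export
spatial_separation <- function(layer_visits, partition, layer_index = NULL) {
  if (is.null(layer_index)) {
    layer_index <- if ("layer_index" %in% names(layer_visits) &&
                       nrow(layer_visits)) layer_visits$layer_index[1] else NA
  }
  if (nrow(layer_visits) == 0) {
    return(structure(list(index = NA_real_, possession = NULL,
                          exclusivity = NULL, usage = NULL,
                          layer_index = layer_index),
                     class = "separation_index"))
  }
  if (is.data.frame(partition)) {
    sub <- partition[partition$layer_index == layer_index, ]
    mod <- sub$module_id[match(layer_visits$tag_id, sub$tag_id)]
  } else {
    mod <- unname(partition[layer_visits$tag_id])
  }
  if (anyNA(mod)) stop("partition does not cover all individuals with visits")
  dur <- layer_visits$t_exit - layer_visits$t_enter
  poss <- tapply(dur, list(module = mod, box = layer_visits$box_id), sum,
                 default = 0)
  usage <- colSums(poss)
  occupied <- usage > 0
  poss <- poss[, occupied, drop = FALSE]
  usage <- usage[occupied]
  possession <- sweep(poss, 2, usage, "/")
  exclusivity <- apply(possession, 2, max)
  structure(list(index = sum(usage * exclusivity) / sum(usage),
                 possession = possession, exclusivity = exclusivity,
                 usage = usage, layer_index = layer_index),
            class = "separation_index")
}

#' @export
print.separation_index <- function(x, ...) {
  cat("spatial separation index:", format(x$index, digits = 4),
      if (!is.na(x$layer_index)) paste0("(layer ", x$layer_index, ")"), "\n")
  invisible(x)
}

#' Box occupancy by module
#'
#' Per-box proportions of occupancy time attributable to each module
#' (the pie charts of module settlement); boxes without any usage are
#' flagged empty.
#'
#' @inheritParams spatial_separation
#' @param boxes optional character vector of all boxes (so unused ones are
#'   reported as empty).
#' @return data.frame (box_id, module_id, proportion, empty).
#' @export
box_occupancy <- function(layer_visits, partition, layer_index = NULL,
                          boxes = NULL) {
  sep <- spatial_separation(layer_visits, partition, layer_index)
  used <- if (is.null(sep$possession)) character(0) else colnames(sep$possession)
  if (is.null(boxes)) boxes <- used
  rows <- list()
  for (b in boxes) {
    if (b %in% used) {
      pv <- sep$possession[, b]
      rows[[b]] <- data.frame(box_id = b,
                              module_id = as.integer(rownames(sep$possession)),
                              proportion = as.numeric(pv),
                              empty = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[b]] <- data.frame(box_id = b, module_id = NA_integer_,
                              proportion = NA_real_, empty = TRUE,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Period-summary network over a window of layers
#'
#' Mean interaction strength over a window of time layers (layers where a
#' pair is absent contribute zero), restricted to a given set of
#' individuals (typically founders and proven reproducers). Vertices carry
#' the prevailing module (modal assignment over the window, ties to the
#' earliest module label) and sex.
#'
#' @param layer_networks list of \code{layer_network}.
#' @param window integer vector of layer indices (usually 10).
#' @param include_ids individuals to include.
#' @param partition multilayer partition data.frame.
#' @param individuals optional metadata (for the sex attribute).
#' @return list of class \code{summary_network}: \code{ids}, matrix
#'   \code{A} (mean strengths), \code{module} (prevailing), \code{sex}.
#' @export
summary_network <- function(layer_networks, window, include_ids, partition,
                            individuals = NULL) {
  lidx <- vapply(layer_networks, function(x) x$layer_index, numeric(1))
  if (!all(window %in% lidx)) {
    stop("window extends beyond the available layers")
  }
  ids <- sort(include_ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in window) {
    nt <- layer_networks[[match(k, lidx)]]
    common <- intersect(ids, nt$ids)
    if (length(common) >= 2) {
      A[common, common] <- A[common, common] + nt$A[common, common]
    }
  }
  A <- A / length(window)
  sub <- partition[partition$layer_index %in% window &
                     partition$tag_id %in% ids, ]
  module <- vapply(ids, function(id) {
    m <- sub$module_id[sub$tag_id == id]
    if (!length(m)) return(NA_integer_)
    cnt <- table(m)
    winners <- as.integer(names(cnt)[cnt == max(cnt)])
    min(winners)  # tie -> earliest module label
  }, integer(1))
  sex <- if (!is.null(individuals)) {
    individuals$sex[match(ids, individuals$tag_id)]
  } else rep(NA_character_, n)
  structure(list(ids = ids, A = A, module = module, sex = sex,
                 window = window),
            class = "summary_network")
}

#' @export
print.summary_network <- function(x, ...) {
  cat("summary network over layers", min(x$window), "-", max(x$window), ":",
      length(x$ids), "individuals,", sum(x$A > 0) / 2, "edges\n")
  invisible(x)
}

#' Export a summary network as GraphML
#' @param sn a \code{summary_network}.
#' @param path output path.
#' @export
write_summary_graphml <- function(sn, path) {
  g <- igraph::graph_from_adjacency_matrix(sn$A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$module <- sn$module
  igraph::V(g)$sex <- ifelse(is.na(sn$sex), "", sn$sex)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Per-layer metrics table
#'
#' Convenience wrapper computing distinctiveness and spatial separation
#' for every layer.
#'
#' @param layer_networks list of \code{layer_network}.
#' @param visits visits data.frame (whole record).
#' @param layers layers data.frame.
#' @param partition multilayer partition data.frame.
#' @return data.frame (layer_index, distinctiveness,
#'   distinctiveness_pooled, spatial_separation).
#' @export
layer_metrics <- function(layer_networks, visits, layers, partition) {
  lv <- assign_visits_to_layers(visits, layers)
  do.call(rbind, lapply(layer_networks, function(nt) {
    if (!length(nt$ids)) {
      return(data.frame(layer_index = nt$layer_index, distinctiveness = NA,
                        distinctiveness_pooled = NA, spatial_separation = NA))
    }
    d <- distinctiveness(nt, partition)
    s <- spatial_separation(lv[lv$layer_index == nt$layer_index, , drop = FALSE],
                            partition, nt$layer_index)
    data.frame(layer_index = nt$layer_index,
               distinctiveness = as.numeric(d),
               distinctiveness_pooled = attr(d, "pooled"),
               spatial_separation = s$index)
  }))
}
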