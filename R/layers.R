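#' Merge a set of intervals into disjoint sorted intervals
#' @param s,e numeric start/end vectors.
#' @return two-column matrix of merged intervals.
#' @keywords internal
merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] <= me) {
        me <- max(me, e[k])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[k]; me <- e[k]
      }
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

#' Total overlap of two sets of disjoint sorted intervals
#' @param a,b matrices from [merge_intervals()].
#' @return total overlap length.
#' @keywords internal
interval_overlap <- function(a, b) {
  i <- 1L; j <- 1L; tot <- 0
  na <- nrow(a); nb <- nrow(b)
  while (i <= na && j <= nb) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  tot
}

#' Pairwise co-occupancy time of two individuals
#'
#' Total time two individuals spent together in any nest box: the summed
#' temporal overlap of their visit intervals, box by box, irrespective of
#' other individuals present.
#'
#' @param visits_i,visits_j visits data.frames of two distinct individuals
#'   (within one time layer).
#' @return seconds of co-occupancy.
#' @export
contact_time <- function(visits_i, visits_j) {
  if (nrow(visits_i) && nrow(visits_j) &&
      visits_i$tag_id[1] == visits_j$tag_id[1]) {
    stop("contact_time requires two distinct individuals")
  }
  boxes <- intersect(unique(visits_i$box_id), unique(visits_j$box_id))
  tot <- 0
  for (b in boxes) {
    vi <- visits_i[visits_i$box_id == b, , drop = FALSE]
    vj <- visits_j[visits_j$box_id == b, , drop = FALSE]
    tot <- tot + interval_overlap(merge_intervals(vi$t_enter, vi$t_exit),
                                  merge_intervals(vj$t_enter, vj$t_exit))
  }
  tot
}

#' Build the weighted social network of one time layer
#'
#' Vertices are the individuals with at least one visit in the layer; the
#' symmetric adjacency matrix A holds pairwise co-occupancy seconds
#' ([contact_time()]), zero on the diagonal. Individuals with visits but no
#' contacts remain as isolated vertices.
#'
#' @param layer_visits visits of a single layer (already clipped to it).
#' @param layer_index the layer's ordinal index.
#' @return object of class \code{layer_network}: list with
#'   \code{layer_index}, \code{ids}, matrix \code{A}.
#' @export
build_layer_network <- function(layer_visits, layer_index = NA_integer_) {
  ids <- sort(unique(layer_visits$tag_id))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    # pre-merge intervals per (individual, box)
    merged <- list()
    for (i in seq_len(n)) {
      vi <- layer_visits[layer_visits$tag_id == ids[i], , drop = FALSE]
      merged[[i]] <- lapply(split(vi, vi$box_id),
                            function(v) merge_intervals(v$t_enter, v$t_exit))
    }
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        boxes <- intersect(names(merged[[i]]), names(merged[[j]]))
        w <- 0
        for (b in boxes) w <- w + interval_overlap(merged[[i]][[b]], merged[[j]][[b]])
        A[i, j] <- A[j, i] <- w
      }
    }
  }
  structure(list(layer_index = layer_index, ids = ids, A = A),
            class = "layer_network")
}

#' Build layer networks for all time layers
#'
#' @param visits visits data.frame (whole record).
#' @param layers layers data.frame from [build_time_layers()].
#' @return list of \code{layer_network}, one per layer, in layer order.
#'   Layers in which no individual visited any box yield networks with zero
#'   vertices.
#' @export
co_occupancy_networks <- function(visits, layers) {
  lv <- assign_visits_to_layers(visits, layers)
  lapply(layers$index, function(k) {
    build_layer_network(lv[lv$layer_index == k, , drop = FALSE], k)
  })
}

#' @export
print.layer_network <- function(x, ...) {
  cat("layer_network: layer", x$layer_index, "-", length(x$ids),
      "individuals,", sum(x$A > 0) / 2, "weighted edges\n")
  invisible(x)
}
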