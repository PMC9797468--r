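#' Mean probability of multiple paternity
#'
#' Per litter with at least two offspring of assigned paternity, the
#' probability that two distinct offspring drawn without replacement have
#' different fathers: 1 - sum_f n_f (n_f - 1) / (n (n - 1)). The index is
#' the unweighted mean over qualifying litters; litters of size one or
#' containing unassigned fathers are excluded entirely.
#'
#' @param pedigree pedigree data.frame (see [read_pedigree()]).
#' @return probability in [0, 1], or NA when no litter qualifies.
#' @export
multiple_paternity <- function(pedigree) {
  vals <- vapply(split(seq_len(nrow(pedigree)), pedigree$litter_id),
                 function(i) {
    f <- pedigree$father_id[i]
    n <- length(f)
    if (n < 2 || anyNA(f)) return(NA_real_)
    nf <- table(f)
    1 - sum(nf * (nf - 1)) / (n * (n - 1))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Litter table with conception times and layers
#'
#' One row per litter: mother, delivery time, conception time (delivery
#' minus the assumed gestation) and the conception layer (the layer whose
#' span contains the conception time, else the nearest layer).
#'
#' @param pedigree pedigree data.frame.
#' @param layers layers data.frame.
#' @param gestation_days assumed gestation (default 20).
#' @return data.frame (litter_id, mother_id, delivery_time,
#'   conception_time, conception_layer, n_offspring).
#' @export
litter_table <- function(pedigree, layers, gestation_days = 20) {
  if (nrow(pedigree) == 0) {
    return(data.frame(litter_id = character(0), mother_id = character(0),
                      delivery_time = numeric(0), n_offspring = integer(0),
                      conception_time = numeric(0),
                      conception_layer = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(as.data.frame(pedigree),
                                     pedigree$litter_id), function(lt) {
    data.frame(litter_id = lt$litter_id[1], mother_id = lt$mother_id[1],
               delivery_time = lt$delivery_time[1],
               n_offspring = nrow(lt), stringsAsFactors = FALSE)
  }))
  out$conception_time <- out$delivery_time - gestation_days * DAY
  out$conception_layer <- vapply(out$conception_time, function(tc) {
    inside <- which(layers$t_start <= tc & tc < layers$t_end)
    if (length(inside)) return(layers$index[inside[1]])
    d <- pmin(abs(layers$t_start - tc), abs(layers$t_end - tc))
    layers$index[which.min(d)]
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Persistence of family bonds within modules
#'
#' Parentage arrows run from each parent to each offspring. For a given
#' time layer, the proportion of arrows whose two members are assigned to
#' the same module, among arrows with both members assigned in the layer.
#' Sex-specific variants restrict to mother-daughter or father-son arrows
#' (offspring of unknown sex are excluded from those variants only).
#'
#' @param pedigree pedigree data.frame.
#' @param partition multilayer partition data.frame.
#' @param layer_index the layer to evaluate.
#' @param filter one of "all", "mother-daughter", "father-son".
#' @param individuals metadata with tag_id and sex (needed for the
#'   sex-specific filters).
#' @return proportion in [0, 1], or NA when no arrow has both ends
#'   assigned.
#' @export
bond_persistence <- function(pedigree, partition, layer_index,
                             filter = c("all", "mother-daughter", "father-son"),
                             individuals = NULL) {
  filter <- match.arg(filter)
  arrows <- rbind(
    data.frame(parent = pedigree$mother_id, offspring = pedigree$offspring_id,
               ptype = "mother", stringsAsFactors = FALSE),
    data.frame(parent = pedigree$father_id, offspring = pedigree$offspring_id,
               ptype = "father", stringsAsFactors = FALSE))
  arrows <- arrows[!is.na(arrows$parent), , drop = FALSE]
  if (filter != "all") {
    if (is.null(individuals)) stop("individuals metadata required for sex filters")
    osex <- individuals$sex[match(arrows$offspring, individuals$tag_id)]
    arrows <- if (filter == "mother-daughter") {
      arrows[arrows$ptype == "mother" & !is.na(osex) & osex == "F", , drop = FALSE]
    } else {
      arrows[arrows$ptype == "father" & !is.na(osex) & osex == "M", , drop = FALSE]
    }
  }
  sub <- partition[partition$layer_index == layer_index, ]
  mp <- sub$module_id[match(arrows$parent, sub$tag_id)]
  mo <- sub$module_id[match(arrows$offspring, sub$tag_id)]
  ok <- !is.na(mp) & !is.na(mo)
  if (!any(ok)) return(NA_real_)
  mean(mp[ok] == mo[ok])
}

#' Deme support: effective parental pairs per module
#'
#' A module is a candidate deme for a litter when the mother belonged to it
#' at the estimated time of conception. The litter's support is the
#' proportion of gestation-window layers (layers whose mid-time falls
#' between conception and delivery) in which BOTH parents are assigned to
#' that module; window layers where a parent has no assignment count
#' against the support (the denominator is the full window). Supports are
#' summed per module into the effective number of parental pairs; a module
#' with positive support is considered a deme.
#'
#' @param pedigree pedigree data.frame.
#' @param partition multilayer partition data.frame.
#' @param layers layers data.frame.
#' @param gestation_days assumed gestation (default 20).
#' @return list of class \code{deme_support}: \code{litters} (per-litter
#'   support, candidate module, plus the observed-layers-only variant
#'   \code{support_observed}) and \code{modules} (module_id,
#'   effective_pairs, is_deme).
#' @export
deme_support <- function(pedigree, partition, layers, gestation_days = 20) {
  lt <- litter_table(pedigree, layers, gestation_days)
  fathers <- tapply(pedigree$father_id, pedigree$litter_id,
                    function(f) unique(f[!is.na(f)]))
  rows <- list()
  for (k in seq_len(nrow(lt))) {
    lid <- lt$litter_id[k]
    fa <- fathers[[as.character(lid)]]
    if (length(fa) == 0) {
      warning("litter ", lid, " skipped: father unassigned")
      next
    }
    window <- layers$index[layers$mid_time_days * DAY >= lt$conception_time[k] &
                             layers$mid_time_days * DAY <= lt$delivery_time[k]]
    if (length(window) == 0) {
      warning("litter ", lid, " skipped: empty gestation window")
      next
    }
    csub <- partition[partition$layer_index == lt$conception_layer[k], ]
    cand <- csub$module_id[match(lt$mother_id[k], csub$tag_id)]
    if (is.na(cand)) {
      warning("litter ", lid, " skipped: mother unassigned at conception")
      next
    }
    for (f in fa) {  # multi-sired litters support via each father
      joint <- vapply(window, function(li) {
        sub <- partition[partition$layer_index == li, ]
        mm <- sub$module_id[match(lt$mother_id[k], sub$tag_id)]
        mf <- sub$module_id[match(f, sub$tag_id)]
        c(both_in = isTRUE(mm == cand) && isTRUE(mf == cand),
          observed = !is.na(mm) && !is.na(mf))
      }, logical(2))
      nobs <- sum(joint["observed", ])
      rows[[length(rows) + 1L]] <- data.frame(
        litter_id = lid, mother_id = lt$mother_id[k], father_id = f,
        candidate_module = cand,
        n_window_layers = length(window),
        support = sum(joint["both_in", ]) / length(window),
        support_observed = if (nobs > 0) sum(joint["both_in", ]) / nobs else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  litters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(litter_id = character(0), mother_id = character(0),
               father_id = character(0), candidate_module = integer(0),
               n_window_layers = integer(0), support = numeric(0),
               support_observed = numeric(0))
  mods <- sort(unique(partition$module_id))
  eff <- vapply(mods, function(m) {
    sum(litters$support[litters$candidate_module == m])
  }, numeric(1))
  modules <- data.frame(module_id = mods, effective_pairs = eff,
                        is_deme = eff > 0)
  structure(list(litters = litters, modules = modules),
            class = "deme_support")
}

#' @export
print.deme_support <- function(x, ...) {
  cat("Deme support (effective parental pairs per module):\n")
  print(x$modules, row.names = FALSE)
  invisible(x)
}
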