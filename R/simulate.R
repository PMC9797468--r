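#' Simulation configuration
#'
#' Parameters of the synthetic enclosure. Defaults emulate the study
#' setting: a six-box enclosure seeded with twelve adult founders (six of
#' each sex, about 90 days old at start), module-structured co-nesting
#' with a tunable mixing rate, 20-day gestation, litters of 3-7 pups,
#' transponders at 14 days, adulthood at 50 days, paternity skewed towards
#' the module's dominant male, occasional emigration, and minor/major
#' check schedules (every 3 days for 1 h; every 35 days for 6 h).
#'
#' @param n_boxes number of nest boxes.
#' @param n_founders founders, split evenly between the sexes.
#' @param duration_days length of the run.
#' @param n_modules planted modules; boxes are partitioned among them as
#'   evenly as possible.
#' @param mixing probability that a visit targets a box outside the
#'   module's home set.
#' @param mean_visit_min,mean_gap_min exponential means of the module-level
#'   communal rest bouts and of the active time between them, minutes.
#' @param join_prob probability that a member joins a given rest bout of
#'   its module.
#' @param birth_rate conceptions per eligible female per day.
#' @param litter_sizes vector sampled uniformly for litter size.
#' @param paternity_skew probability a conception is sired by the module's
#'   dominant male.
#' @param gestation_days,maturity_days,transponder_days life-history ages.
#' @param emigration_rate permanent-disappearance rate per individual per
#'   day.
#' @param spurious_rate expected number of stray (equivocal) reads per
#'   visit, for exercising the signal-cleaning path.
#' @param enclosure_id label stamped on the events.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_boxes = 6, n_founders = 12, duration_days = 60,
                       n_modules = 2, mixing = 0.05,
                       mean_visit_min = 40, mean_gap_min = 30,
                       join_prob = 0.9,
                       birth_rate = 0.04, litter_sizes = 3:7,
                       paternity_skew = 0.9, gestation_days = 20,
                       maturity_days = 50, transponder_days = 14,
                       emigration_rate = 0.002, spurious_rate = 0,
                       enclosure_id = "E1") {
  stopifnot(n_boxes >= n_modules, n_modules >= 1, n_founders >= 2,
            duration_days > 0, mixing >= 0, mixing <= 1,
            paternity_skew >= 0, paternity_skew <= 1, join_prob > 0,
            join_prob <= 1, mean_visit_min > 0, mean_gap_min > 0,
            birth_rate >= 0, emigration_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an enclosure run
#'
#' Continuous-time simulation with planted social modules. Each individual
#' alternates time outside boxes with nest-box visits; a visit targets a
#' home box of its module with probability 1 - mixing, otherwise a uniform
#' other box. Each visit emits the four antenna reads of a credible entry
#' and exit (outer-inner ... inner-outer) with 1-3 s lags. Adult females
#' conceive at the configured rate; the father is the module's dominant
#' male with probability \code{paternity_skew}, otherwise a uniform adult
#' male of the module. Offspring inherit the mother's module, become
#' detectable at 14 days and adult at 50. The planted truth records every
#' individual's module per day.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed reproduces the run exactly.
#' @return list of class \code{sim_run}: \code{events},
#'   \code{individuals}, \code{checks}, \code{pedigree}, \code{truth}
#'   (tag_id, day, module_id), \code{modules} (tag_id, module_id),
#'   \code{home_boxes}.
#' @export
simulate_run <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cf <- config
  end <- cf$duration_days * DAY
  nf2 <- cf$n_founders %/% 2
  box_of_module <- split(seq_len(cf$n_boxes),
                         sort(rep_len(seq_len(cf$n_modules), cf$n_boxes)))
  ind <- data.frame(
    tag_id = c(sprintf("F%03d", seq_len(nf2)), sprintf("M%03d", seq_len(nf2))),
    sex = rep(c("F", "M"), each = nf2),
    birth_time = -90 * DAY,
    founder = TRUE,
    module = c(rep_len(seq_len(cf$n_modules), nf2),
               rep_len(seq_len(cf$n_modules), nf2)),
    stringsAsFactors = FALSE)
  if (cf$birth_rate > 0) {
    if (cf$n_modules > nf2) {
      stop("infeasible config: more planted modules than founder pairs, ",
           "so some module would lack resident males")
    }
    has_f <- tapply(ind$sex == "F", ind$module, any)
    has_m <- tapply(ind$sex == "M", ind$module, any)
    if (any(has_f & !has_m)) {
      stop("infeasible config: a module has breeding females but no males")
    }
  }
  dominant <- vapply(seq_len(cf$n_modules), function(m) {
    ind$tag_id[ind$sex == "M" & ind$module == m][1]
  }, character(1))
  # emigration (permanent disappearance)
  draw_removal <- function(from) {
    if (cf$emigration_rate <= 0) return(NA_real_)
    t <- from + stats::rexp(1, cf$emigration_rate) * DAY
    if (t >= end) NA_real_ else t
  }
  ind$removal <- vapply(pmax(ind$birth_time, 0), draw_removal, numeric(1))
  # demography: process females in maturity order, population may grow
  ped <- list(); next_pup <- 1L; next_litter <- 1L
  qi <- 1L
  while (qi <= nrow(ind)) {
    row <- ind[qi, ]
    qi <- qi + 1L
    if (row$sex != "F" || cf$birth_rate == 0) next
    t <- max(row$birth_time + cf$maturity_days * DAY, 0)
    repeat {
      t <- t + stats::rexp(1, cf$birth_rate) * DAY
      deliver <- t + cf$gestation_days * DAY
      alive_until <- if (is.na(row$removal)) end else row$removal
      if (t >= alive_until || deliver >= end) break
      m <- row$module
      males <- ind$tag_id[ind$sex == "M" & ind$module == m &
                            ind$birth_time + cf$maturity_days * DAY <= t &
                            (is.na(ind$removal) | ind$removal > t)]
      if (!length(males)) next
      dom <- dominant[m]
      father <- if (dom %in% males && stats::runif(1) < cf$paternity_skew) {
        dom
      } else {
        males[sample.int(length(males), 1)]
      }
      nl <- sample(cf$litter_sizes, 1)
      lid <- sprintf("L%03d", next_litter); next_litter <- next_litter + 1L
      for (j in seq_len(nl)) {
        pid <- sprintf("P%04d", next_pup); next_pup <- next_pup + 1L
        psex <- sample(c("F", "M"), 1)
        ind <- rbind(ind, data.frame(
          tag_id = pid, sex = psex, birth_time = deliver, founder = FALSE,
          module = m, removal = draw_removal(deliver),
          stringsAsFactors = FALSE))
        ped[[pid]] <- data.frame(offspring_id = pid,
                                 mother_id = row$tag_id, father_id = father,
                                 delivery_time = deliver, litter_id = lid,
                                 stringsAsFactors = FALSE)
      }
      t <- deliver  # next conception only after delivery
    }
  }
  pedigree <- if (length(ped)) as_pedigree(do.call(rbind, ped)) else
    structure(data.frame(offspring_id = character(0), mother_id = character(0),
                         father_id = character(0), delivery_time = numeric(0),
                         litter_id = character(0)),
              class = c("pedigree", "data.frame"))
  # movement: module-level communal rest bouts that members join with some
  # probability and small entry/exit jitter; a joining member targets the
  # bout's box unless mixing sends it to a uniform other box. This plants
  # both spatial preference and temporal synchrony, the two ingredients of
  # co-nesting associations.
  mv <- cf$mean_visit_min * 60; mg <- cf$mean_gap_min * 60
  bouts <- lapply(seq_len(cf$n_modules), function(m) {
    home <- box_of_module[[m]]
    t <- 0; ws <- numeric(0); we <- numeric(0); wb <- integer(0)
    repeat {
      t <- t + 300 + stats::rexp(1, 1 / mg)  # >= 5 min between bouts
      if (t >= end) break
      dur <- 60 + stats::rexp(1, 1 / mv)
      ws <- c(ws, t); we <- c(we, min(t + dur, end))
      wb <- c(wb, home[sample.int(length(home), 1)])
      t <- t + dur
    }
    list(start = ws, end = we, box = wb)
  })
  evs <- vector("list", nrow(ind))
  for (k in seq_len(nrow(ind))) {
    a0 <- max(0, ind$birth_time[k] + cf$transponder_days * DAY)
    a1 <- min(end, if (is.na(ind$removal[k])) end else ind$removal[k])
    if (a0 >= a1) next
    m <- ind$module[k]
    sched <- bouts[[m]]
    away <- setdiff(seq_len(cf$n_boxes), box_of_module[[m]])
    use <- which(sched$end > a0 & sched$start < a1)
    if (!length(use)) next
    nmax <- length(use)
    tt <- numeric(4 * nmax); bx <- integer(4 * nmax); ps <- character(4 * nmax)
    ne <- 0L
    for (w in use) {
      if (stats::runif(1) > cf$join_prob) next
      entry <- max(sched$start[w] + stats::runif(1, 0, 120), a0)
      exit <- min(sched$end[w] - stats::runif(1, 0, 120), a1)
      if (exit - entry <= 5) next
      box <- if (length(away) && stats::runif(1) < cf$mixing) {
        away[sample.int(length(away), 1)]
      } else {
        sched$box[w]
      }
      l1 <- stats::runif(1, 1, 3); l2 <- stats::runif(1, 1, 3)
      tt[ne + 1:4] <- c(entry - l1, entry, exit, exit + l2)
      bx[ne + 1:4] <- box
      ps[ne + 1:4] <- c("outer", "inner", "inner", "outer")
      ne <- ne + 4L
    }
    if (ne == 0L) next
    keep <- seq_len(ne)
    df <- data.frame(timestamp = tt[keep], tag_id = ind$tag_id[k],
                     box_id = paste0("box", bx[keep]), position = ps[keep],
                     enclosure_id = cf$enclosure_id, stringsAsFactors = FALSE)
    if (cf$spurious_rate > 0) {
      nsp <- stats::rpois(1, cf$spurious_rate * ne / 4)
      if (nsp > 0) {
        df <- rbind(df, data.frame(
          timestamp = stats::runif(nsp, a0, a1), tag_id = ind$tag_id[k],
          box_id = paste0("box", sample.int(cf$n_boxes, nsp, replace = TRUE)),
          position = sample(c("inner", "outer"), nsp, replace = TRUE),
          enclosure_id = cf$enclosure_id, stringsAsFactors = FALSE))
      }
    }
    evs[[k]] <- df
  }
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  events <- events[order(events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  # check schedule: minor every 3 d; a major every 36 d replaces the minor
  minor_days <- if (cf$duration_days > 4) seq(3, cf$duration_days - 1, by = 3)
                else numeric(0)
  major_days <- if (cf$duration_days > 37) seq(36, cf$duration_days - 1, by = 36)
                else numeric(0)
  minor_days <- setdiff(minor_days, major_days)
  checks <- rbind(
    if (length(minor_days)) data.frame(start = minor_days * DAY + 9 * 3600,
                                       end = minor_days * DAY + 10 * 3600,
                                       kind = "minor"),
    if (length(major_days)) data.frame(start = major_days * DAY + 9 * 3600,
                                       end = major_days * DAY + 15 * 3600,
                                       kind = "major"))
  if (is.null(checks)) checks <- data.frame(start = numeric(0), end = numeric(0),
                                            kind = character(0))
  # planted truth, per day of detectability
  truth <- do.call(rbind, lapply(seq_len(nrow(ind)), function(k) {
    a0 <- max(0, ind$birth_time[k] + cf$transponder_days * DAY)
    a1 <- min(end, if (is.na(ind$removal[k])) end else ind$removal[k])
    if (a0 >= a1) return(NULL)
    days <- seq(floor(a0 / DAY), ceiling(a1 / DAY) - 1)
    data.frame(tag_id = ind$tag_id[k], day = days, module_id = ind$module[k],
               stringsAsFactors = FALSE)
  }))
  individuals <- data.frame(tag_id = ind$tag_id, sex = ind$sex,
                            birth_time = ind$birth_time, founder = ind$founder,
                            death_or_removal_time = ind$removal,
                            stringsAsFactors = FALSE)
  structure(list(events = events, individuals = individuals, checks = checks,
                 pedigree = pedigree, truth = truth,
                 modules = data.frame(tag_id = ind$tag_id,
                                      module_id = ind$module,
                                      stringsAsFactors = FALSE),
                 home_boxes = box_of_module, config = cf, seed = seed),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run:", nrow(x$individuals), "individuals,", nrow(x$events),
      "reads over", x$config$duration_days, "days;",
      x$config$n_modules, "planted modules\n")
  invisible(x)
}

#' Write a simulated run in the pipeline's input formats
#'
#' Emits events.csv, individuals.csv, checks.csv and pedigree.csv.
#'
#' @param run a \code{sim_run}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(run$events, file.path(dir, "events.csv"))
  utils::write.csv(run$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$checks, file.path(dir, "checks.csv"),
                   row.names = FALSE, quote = FALSE)
  write_pedigree(run$pedigree, file.path(dir, "pedigree.csv"))
  invisible(dir)
}

#' Planted partition aligned with a fitted one
#'
#' Expands a run's planted truth to the state nodes of a fitted partition
#' (each individual keeps its planted module in every layer it occupies),
#' for NMI comparison against the fit.
#'
#' @param run a \code{sim_run}.
#' @param partition fitted partition data.frame.
#' @return data.frame (tag_id, layer_index, module_id).
#' @export
planted_partition <- function(run, partition) {
  mod <- run$modules$module_id[match(partition$tag_id, run$modules$tag_id)]
  if (anyNA(mod)) stop("fitted partition contains unknown individuals")
  data.frame(tag_id = partition$tag_id, layer_index = partition$layer_index,
             module_id = mod, stringsAsFactors = FALSE)
}

#' Hand-constructed fixtures for worked examples
#'
#' \describe{
#'   \item{toy_visits}{two individuals, one box, a single 20 s overlap.}
#'   \item{two_triangles}{one layer holding two disconnected equal-weight
#'     triangles; the optimal two-module codelength is known in closed
#'     form.}
#'   \item{nora_miro}{a one-litter pedigree with a 20-layer record:
#'     conception falls in layer 6, delivery in layer 15, so the gestation
#'     window covers exactly layers 6-15 (10 layers). Ships two partitions:
#'     \code{partition_full} keeps both parents in the candidate module in
#'     all ten window layers (support 1.0) and \code{partition_partial} in
#'     only two of them (support 0.2).}
#'   \item{occupancy_toy}{one layer of visits over three boxes with known
#'     possession shares for the spatial-separation arithmetic.}
#' }
#'
#' @param name fixture name.
#' @return the fixture (structure depends on the name).
#' @export
make_fixture <- function(name = c("toy_visits", "two_triangles", "nora_miro",
                                  "occupancy_toy")) {
  name <- match.arg(name)
  switch(name,
    toy_visits = data.frame(
      tag_id = c("a", "b"), box_id = "box1",
      t_enter = c(0, 80), t_exit = c(100, 180), stringsAsFactors = FALSE),
    two_triangles = {
      ids <- letters[1:6]
      A <- matrix(0, 6, 6, dimnames = list(ids, ids))
      for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
        A[e[1], e[2]] <- A[e[2], e[1]] <- 1
      }
      list(structure(list(layer_index = 1L, ids = ids, A = A),
                     class = "layer_network"))
    },
    nora_miro = {
      # layers (days): 1-5 of 2 d; layer 6 = [10,11]; 7-14 spanning [11,30);
      # layer 15 = [30,31]; 16-20 of 2 d. Conception 10.5 d, delivery 30.5 d:
      # window mids are exactly layers 6..15.
      s7 <- 11 + (0:7) * (19 / 8)
      t_start <- c((0:4) * 2, 10, s7, 30, 31 + (0:4) * 2)
      t_end <- c((1:5) * 2, 11, s7 + 19 / 8, 31, 33 + (0:4) * 2)
      layers <- data.frame(index = 1:20, t_start = t_start * DAY,
                           t_end = t_end * DAY,
                           mid_time_days = (t_start + t_end) / 2)
      ped <- as_pedigree(data.frame(
        offspring_id = c("pup1", "pup2", "pup3"), mother_id = "nora",
        father_id = "miro", delivery_time = 30.5 * DAY, litter_id = "L001",
        stringsAsFactors = FALSE))
      base <- expand.grid(tag_id = c("nora", "miro"), layer_index = 1:20,
                          stringsAsFactors = FALSE)
      full <- base; full$module_id <- 1L
      partial <- base
      # joint membership in the candidate module only in window layers 6, 7
      partial$module_id <- ifelse(partial$tag_id == "nora", 1L,
                                  ifelse(partial$layer_index %in% c(6, 7), 1L, 2L))
      list(pedigree = ped, layers = layers, partition_full = full,
           partition_partial = partial,
           individuals = data.frame(tag_id = c("nora", "miro"),
                                    sex = c("F", "M"),
                                    birth_time = -90 * DAY, founder = TRUE,
                                    stringsAsFactors = FALSE))
    },
    occupancy_toy = {
      visits <- data.frame(
        tag_id = c("x1", "x2", "y1", "y2", "z1"),
        box_id = c("box1", "box2", "box2", "box3", "box3"),
        t_enter = 0, t_exit = c(300, 100, 100, 150, 50),
        layer_index = 1L, stringsAsFactors = FALSE)
      partition <- data.frame(
        tag_id = c("x1", "x2", "y1", "y2", "z1"), layer_index = 1L,
        module_id = c(1L, 1L, 2L, 2L, 3L), stringsAsFactors = FALSE)
      list(visits = visits, partition = partition)
    })
}
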