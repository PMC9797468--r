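#' Parse timestamps to numeric seconds
#'
#' Accepts numeric seconds (returned unchanged) or ISO-8601 date-times,
#' which are converted to seconds since the Unix epoch in UTC. Sub-second
#' precision, when present, is preserved.
#'
#' @param x numeric or character vector.
#' @return numeric vector of seconds.
#' @keywords internal
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num[!is.na(x)])) return(num)
  t <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(t[!is.na(x)])) {
    bad <- which(is.na(t) & !is.na(x))[1]
    stop("unparseable timestamp at row ", bad, ": '", x[bad], "'")
  }
  as.numeric(t)
}

.position_levels <- c("inner", "outer", "single")

#' Read RFID reader events
#'
#' Reads a delimited text file of antenna detections with columns
#' \code{timestamp}, \code{tag_id}, \code{box_id}, \code{position} and
#' \code{enclosure_id}. Events are returned sorted by timestamp with a
#' stable sort, so records sharing a timestamp keep their file order.
#'
#' @param path path to a CSV file with a header row.
#' @return a data.frame of events ordered by time, with numeric
#'   \code{timestamp} in seconds.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("timestamp", "tag_id", "box_id", "position", "enclosure_id")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(ev[need]) |
                 ev$timestamp == "" | ev$tag_id == "")
  if (length(bad)) stop("malformed event row at line ", bad[1] + 1L)
  unknown <- which(!ev$position %in% .position_levels)
  if (length(unknown)) {
    stop("unknown position token '", ev$position[unknown[1]],
         "' at line ", unknown[1] + 1L)
  }
  ev$timestamp <- parse_time(ev$timestamp)
  ev <- ev[order(ev$timestamp), , drop = FALSE]  # order() is stable
  rownames(ev) <- NULL
  ev[need]
}

#' Write RFID reader events
#' @param events data.frame as returned by [read_events()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read individual metadata
#'
#' Columns: \code{tag_id}, \code{sex} (\code{F}/\code{M}), \code{birth_time},
#' \code{founder} (logical), and optional \code{death_or_removal_time}.
#'
#' @param path path to CSV.
#' @return data.frame with numeric times (seconds).
#' @export
read_individuals <- function(path) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "sex", "birth_time", "founder")
  miss <- setdiff(need, names(ind))
  if (length(miss)) stop("individuals file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ind$tag_id)) stop("duplicate tag_id in individuals file")
  if (!all(ind$sex %in% c("F", "M", NA))) stop("sex must be 'F' or 'M'")
  ind$birth_time <- parse_time(ind$birth_time)
  ind$founder <- as.logical(ind$founder)
  if (!"death_or_removal_time" %in% names(ind)) {
    ind$death_or_removal_time <- NA_real_
  } else {
    ind$death_or_removal_time <- parse_time(ind$death_or_removal_time)
  }
  both <- !is.na(ind$death_or_removal_time)
  if (any(both & ind$birth_time >= ind$death_or_removal_time)) {
    stop("birth_time must precede death_or_removal_time")
  }
  ind
}

#' Read the enclosure-check schedule
#'
#' One check interval per row: \code{start}, \code{end}, \code{kind}
#' (\code{minor} or \code{major}).
#'
#' @param path path to CSV.
#' @return data.frame with numeric \code{start}, \code{end} in seconds.
#' @export
read_checks <- function(path) {
  ck <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("start", "end", "kind"), names(ck))
  if (length(miss)) stop("checks file lacks column(s): ", paste(miss, collapse = ", "))
  ck$start <- parse_time(ck$start)
  ck$end <- parse_time(ck$end)
  if (any(ck$end <= ck$start)) stop("check end must follow start")
  ck
}

#' Read a pedigree table
#'
#' Columns: \code{offspring_id}, \code{mother_id}, \code{father_id} (may be
#' empty/NA when parentage is unassigned), \code{delivery_time},
#' \code{litter_id}. Offspring grouped into litters by \code{litter_id}.
#'
#' @param path path to CSV.
#' @return data.frame of class \code{"pedigree"}; each row one offspring.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("offspring_id", "mother_id", "father_id", "delivery_time", "litter_id")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "))
  ped$father_id[ped$father_id %in% c("", "NA")] <- NA_character_
  as_pedigree(ped)
}

#' Validate and class a pedigree data.frame
#' @param ped data.frame with pedigree columns.
#' @return the validated data.frame, classed \code{"pedigree"}.
#' @export
as_pedigree <- function(ped) {
  if (anyDuplicated(ped$offspring_id)) {
    stop("duplicate offspring_id: ",
         ped$offspring_id[anyDuplicated(ped$offspring_id)])
  }
  selfpar <- ped$offspring_id == ped$mother_id |
    (!is.na(ped$father_id) & ped$offspring_id == ped$father_id)
  if (any(selfpar)) {
    stop("offspring listed as its own parent: ", ped$offspring_id[which(selfpar)[1]])
  }
  ped$delivery_time <- parse_time(ped$delivery_time)
  one_mother <- tapply(ped$mother_id, ped$litter_id, function(m) length(unique(m)))
  if (any(one_mother > 1L)) stop("a litter_id spans more than one mother")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write a pedigree table
#' @param ped pedigree data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a multilayer partition
#'
#' Partitions are stored as CSV with columns \code{tag_id},
#' \code{layer_index}, \code{module_id}: one row per state node
#' (individual-in-layer).
#'
#' @param path file path.
#' @return data.frame partition.
#' @export
read_partition <- function(path) {
  pt <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tag_id", "layer_index", "module_id"), names(pt))
  if (length(miss)) stop("partition file lacks column(s): ", paste(miss, collapse = ", "))
  pt$layer_index <- as.integer(pt$layer_index)
  pt$module_id <- as.integer(pt$module_id)
  pt
}

#' @rdname read_partition
#' @param partition data.frame with tag_id, layer_index, module_id.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(partition[c("tag_id", "layer_index", "module_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a layer network as GraphML
#'
#' @param net a \code{layer_network} (see [build_layer_network()]).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_layer_graphml <- function(net, path) {
  stopifnot(inherits(net, "layer_network"))
  g <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a layer network adjacency matrix as CSV
#' @inheritParams write_layer_graphml
#' @export
write_layer_matrix <- function(net, path) {
  stopifnot(inherits(net, "layer_network"))
  utils::write.csv(as.data.frame(net$A), path, row.names = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable constants of the pipeline. Durations are hours or
#' days as named; internal times are seconds (1 day = 86400 s).
#'
#' @param layer_max_hours maximum layer length before splitting (48 h).
#' @param gap_max_hours enclosure-wide silent gap that splits the record (1 h).
#' @param layer_min_hours_for_merge layers whose first-to-last-event span is
#'   shorter than this are merged into a neighbour (24 h).
#' @param gestation_days assumed gestation; conception = delivery - this (20 d).
#' @param adult_age_days age at adulthood for sex-specific analyses (50 d).
#' @param relax_rates grid of relax rates for the multilayer clustering.
#' @param bootstrap_reps visit-reordering bootstrap replicates.
#' @param tau teleportation rate of the random walk.
#' @param rng_seed integer seed.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(layer_max_hours = 48, gap_max_hours = 1,
                       layer_min_hours_for_merge = 24, gestation_days = 20,
                       adult_age_days = 50,
                       relax_rates = seq(0, 1, length.out = 21),
                       bootstrap_reps = 100, tau = 0.01, rng_seed = 1L) {
  stopifnot(layer_max_hours > 0, gap_max_hours > 0,
            layer_min_hours_for_merge > 0, gestation_days > 0,
            adult_age_days > 0, bootstrap_reps >= 1,
            all(relax_rates >= 0 & relax_rates <= 1))
  structure(list(layer_max_hours = layer_max_hours,
                 gap_max_hours = gap_max_hours,
                 layer_min_hours_for_merge = layer_min_hours_for_merge,
                 gestation_days = gestation_days,
                 adult_age_days = adult_age_days,
                 relax_rates = relax_rates,
                 bootstrap_reps = bootstrap_reps,
                 tau = tau,
                 rng_seed = rng_seed),
            class = "run_config")
}

DAY <- 86400

#' Read / write visits tables
#'
#' Visits are stored as CSV with columns \code{tag_id}, \code{box_id},
#' \code{t_enter}, \code{t_exit} (seconds).
#'
#' @param path file path.
#' @return data.frame of visits.
#' @export
read_visits <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tag_id", "box_id", "t_enter", "t_exit"), names(v))
  if (length(miss)) stop("visits file lacks column(s): ", paste(miss, collapse = ", "))
  v$t_enter <- parse_time(v$t_enter)
  v$t_exit <- parse_time(v$t_exit)
  v
}

#' @rdname read_visits
#' @param visits visits data.frame.
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits[c("tag_id", "box_id", "t_enter", "t_exit")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the layer table as JSON
#' @param path file path.
#' @return layers data.frame.
#' @export
read_layers_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_layers_json
#' @param layers layers data.frame from [build_time_layers()].
#' @export
write_layers_json <- function(layers, path) {
  jsonlite::write_json(layers, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Write detected migrations as CSV
#' @param migrations data.frame from [detect_migrations()].
#' @param path file path.
#' @export
write_migrations <- function(migrations, path) {
  utils::write.csv(migrations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
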