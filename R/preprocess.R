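#' Reconstruct nest-box visits from paired antenna signals
#'
#' Each box entrance carries two antennas. A credible entry is an outer read
#' followed by an inner read (entry time = the inner read); a credible exit
#' is an inner read followed by an outer read (exit time = the outer read).
#' An entry is paired with the next exit from the same box by the same
#' individual. A new credible entry before a matching exit closes the open
#' visit at the new entry's inner-read time (the animal must have left
#' unseen). All other signal patterns are equivocal: they are dropped and
#' counted, never raised as errors.
#'
#' @param events data.frame of reader events sorted by time
#'   (see [read_events()]). Reads with \code{position == "single"}
#'   (tube and exit readers) do not form visits and are ignored here.
#' @return data.frame of visits (\code{tag_id}, \code{box_id},
#'   \code{t_enter}, \code{t_exit}), with attribute \code{"equivocal"}
#'   giving the number of dropped signals.
#' @export
extract_visits <- function(events) {
  ev <- events[events$position %in% c("inner", "outer"), , drop = FALSE]
  per_tag <- vector("list", length(unique(ev$tag_id)))
  names(per_tag) <- unique(ev$tag_id)
  equivocal <- 0L
  for (tag in unique(ev$tag_id)) {
    e <- ev[ev$tag_id == tag, , drop = FALSE]
    # previous unconsumed read per box
    prev_box <- character(0); prev_pos <- character(0); prev_t <- numeric(0)
    open_box <- NA_character_; open_t <- NA_real_
    nmax <- nrow(e)
    v_box <- character(nmax); v_en <- numeric(nmax); v_ex <- numeric(nmax)
    nv <- 0L
    emit <- function(box, t_en, t_ex) {
      nv <<- nv + 1L
      v_box[nv] <<- box; v_en[nv] <<- t_en; v_ex[nv] <<- t_ex
    }
    for (k in seq_len(nrow(e))) {
      box <- e$box_id[k]; pos <- e$position[k]; t <- e$timestamp[k]
      j <- match(box, prev_box)
      if (is.na(j)) {
        prev_box <- c(prev_box, box); prev_pos <- c(prev_pos, pos); prev_t <- c(prev_t, t)
        next
      }
      if (prev_pos[j] == "outer" && pos == "inner") {
        # credible entry at the inner-read time
        if (!is.na(open_box)) {
          if (t > open_t) emit(open_box, open_t, t) else equivocal <- equivocal + 2L
        }
        open_box <- box; open_t <- t
        prev_box <- prev_box[-j]; prev_pos <- prev_pos[-j]; prev_t <- prev_t[-j]
      } else if (prev_pos[j] == "inner" && pos == "outer") {
        # credible exit at the outer-read time
        if (!is.na(open_box) && open_box == box && t > open_t) {
          emit(open_box, open_t, t)
          open_box <- NA_character_; open_t <- NA_real_
        } else {
          equivocal <- equivocal + 2L
        }
        prev_box <- prev_box[-j]; prev_pos <- prev_pos[-j]; prev_t <- prev_t[-j]
      } else {
        # same-antenna repeat: the older read is equivocal
        equivocal <- equivocal + 1L
        prev_pos[j] <- pos; prev_t[j] <- t
      }
    }
    equivocal <- equivocal + length(prev_box) + (!is.na(open_box))
    if (nv > 0L) {
      per_tag[[tag]] <- data.frame(tag_id = tag, box_id = v_box[seq_len(nv)],
                                   t_enter = v_en[seq_len(nv)],
                                   t_exit = v_ex[seq_len(nv)],
                                   stringsAsFactors = FALSE)
    }
  }
  per_tag <- per_tag[!vapply(per_tag, is.null, logical(1))]
  visits <- if (length(per_tag)) do.call(rbind, per_tag) else
    data.frame(tag_id = character(0), box_id = character(0),
               t_enter = numeric(0), t_exit = numeric(0),
               stringsAsFactors = FALSE)
  visits <- visits[order(visits$t_enter, visits$tag_id), , drop = FALSE]
  rownames(visits) <- NULL
  attr(visits, "equivocal") <- equivocal
  visits
}

#' Censored windows implied by enclosure checks
#'
#' Records made during a check and after it until midnight of the concerned
#' day are untrustworthy: each check interval maps to the window
#' [check start, first midnight after check end).
#'
#' @param checks data.frame with \code{start}, \code{end} (seconds).
#' @return data.frame with \code{start}, \code{end} of censored windows.
#' @keywords internal
censor_windows <- function(checks) {
  if (is.null(checks) || nrow(checks) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = checks$start,
             end = (floor(checks$end / DAY) + 1) * DAY)
}

#' Remove events recorded during and after enclosure checks
#'
#' Every event whose timestamp falls in [check start, next midnight after
#' check end) is dropped.
#'
#' @param events data.frame of reader events.
#' @param checks data.frame of check intervals (\code{start}, \code{end}).
#' @return the censored events data.frame.
#' @export
censor_checks <- function(events, checks) {
  win <- censor_windows(checks)
  if (nrow(win) == 0 || nrow(events) == 0) return(events)
  span <- range(events$timestamp)
  outside <- win$end <= span[1] | win$start >= span[2]
  if (any(outside)) warning(sum(outside), " check interval(s) outside the recorded span")
  keep <- rep(TRUE, nrow(events))
  for (k in seq_len(nrow(win))) {
    keep <- keep & !(events$timestamp >= win$start[k] & events$timestamp < win$end[k])
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clip visits to lie outside censored windows
#'
#' A visit overlapping a censored window is cut at the window boundary; the
#' parts falling inside any window are removed. Called by the pipeline after
#' [extract_visits()] so that no retained visit time overlaps a check window.
#'
#' @param visits visits data.frame.
#' @param checks check intervals.
#' @return clipped visits data.frame.
#' @export
clip_visits_to_checks <- function(visits, checks) {
  win <- censor_windows(checks)
  if (nrow(win) == 0 || nrow(visits) == 0) return(visits)
  pieces <- visits
  for (k in seq_len(nrow(win))) {
    s <- win$start[k]; e <- win$end[k]
    hit <- pieces$t_enter < e & pieces$t_exit > s
    if (!any(hit)) next
    keep <- pieces[!hit, , drop = FALSE]
    cut <- pieces[hit, , drop = FALSE]
    left <- cut[cut$t_enter < s, , drop = FALSE]
    if (nrow(left)) left$t_exit <- pmin(left$t_exit, s)
    right <- cut[cut$t_exit > e, , drop = FALSE]
    if (nrow(right)) right$t_enter <- pmax(right$t_enter, e)
    pieces <- rbind(keep, left, right)
  }
  pieces <- pieces[pieces$t_exit > pieces$t_enter, , drop = FALSE]
  pieces <- pieces[order(pieces$t_enter, pieces$tag_id), , drop = FALSE]
  rownames(pieces) <- NULL
  pieces
}

#' Discretise the record into time layers
#'
#' The censored record is split at every enclosure-wide silent gap longer
#' than \code{gap_max_hours}; fragments longer than \code{layer_max_hours}
#' are cut into consecutive pieces of at most that length (measured from the
#' fragment start); finally any layer whose first-to-last-event span is
#' shorter than \code{min_hours} is merged with its nearest neighbour (the
#' one across the smaller inter-layer gap; ties go to the earlier
#' neighbour), iteratively, until none remains or a single layer is left.
#'
#' @param events censored, time-sorted reader events.
#' @param gap_max_hours silent gap that splits the record (default 1).
#' @param layer_max_hours maximum fragment length (default 48).
#' @param min_hours merge threshold on the event span (default 24).
#' @return data.frame of layers: \code{index}, \code{t_start}, \code{t_end}
#'   (first and last event time), \code{mid_time_days}.
#' @export
build_time_layers <- function(events, gap_max_hours = 1, layer_max_hours = 48,
                              min_hours = 24) {
  ts <- sort(events$timestamp)
  if (length(ts) == 0) stop("no events after censoring")
  gap <- gap_max_hours * 3600
  cap <- layer_max_hours * 3600
  # fragment at silent gaps
  brk <- which(diff(ts) > gap)
  frag_start <- c(1L, brk + 1L)
  frag_end <- c(brk, length(ts))
  starts <- numeric(0); ends <- numeric(0)
  for (f in seq_along(frag_start)) {
    tt <- ts[frag_start[f]:frag_end[f]]
    t0 <- tt[1]
    repeat {
      inpiece <- tt >= t0 & tt <= t0 + cap
      # events exactly at the cut belong to the earlier piece
      piece <- tt[inpiece]
      starts <- c(starts, piece[1]); ends <- c(ends, piece[length(piece)])
      tt <- tt[tt > t0 + cap]
      if (length(tt) == 0) break
      t0 <- t0 + cap
    }
  }
  # iterative merge of short layers
  minspan <- min_hours * 3600
  repeat {
    if (length(starts) <= 1L) break
    span <- ends - starts
    short <- which(span < minspan)
    if (length(short) == 0) break
    i <- short[which.min(span[short])]  # shortest first: deterministic
    n <- length(starts)
    if (i == 1L) {
      j <- 2L
    } else if (i == n) {
      j <- n - 1L
    } else {
      gap_prev <- starts[i] - ends[i - 1L]
      gap_next <- starts[i + 1L] - ends[i]
      j <- if (gap_prev <= gap_next) i - 1L else i + 1L
    }
    a <- min(i, j); b <- max(i, j)
    starts[a] <- starts[a]; ends[a] <- ends[b]
    starts <- starts[-b]; ends <- ends[-b]
  }
  data.frame(index = seq_along(starts), t_start = starts, t_end = ends,
             mid_time_days = (starts + ends) / 2 / DAY)
}

#' Assign visits to time layers
#'
#' A visit spanning a layer boundary is split and its time apportioned to
#' each layer it intersects; time falling in inter-layer gaps is dropped.
#'
#' @param visits visits data.frame.
#' @param layers layers data.frame from [build_time_layers()].
#' @return visits data.frame with an added \code{layer_index} column,
#'   clipped to layer extents.
#' @export
assign_visits_to_layers <- function(visits, layers) {
  res <- vector("list", nrow(layers))
  for (k in seq_len(nrow(layers))) {
    s <- layers$t_start[k]; e <- layers$t_end[k]
    hit <- visits$t_enter < e & visits$t_exit > s
    v <- visits[hit, , drop = FALSE]
    if (nrow(v)) {
      v$t_enter <- pmax(v$t_enter, s)
      v$t_exit <- pmin(v$t_exit, e)
      v$layer_index <- layers$index[k]
    } else {
      v$layer_index <- integer(0)
    }
    res[[k]] <- v
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect migrations between enclosures
#'
#' A proven migration is a pair of consecutive reads of the same individual
#' from different enclosures (any reader proves presence, box entrance not
#' required). Tube-reader hits that are not followed by a read from the
#' opposite enclosure count as unrealised attempts.
#'
#' @param events reader events carrying \code{enclosure_id}.
#' @param tube_boxes box_id values of the connecting-tube readers.
#' @return list with \code{migrations} (data.frame: \code{tag_id},
#'   \code{time}, \code{from_enclosure}, \code{to_enclosure}) and
#'   \code{attempts} (count of unrealised attempts).
#' @export
detect_migrations <- function(events,
                              tube_boxes = c("connector-left", "connector-right")) {
  mig <- list(); attempts <- 0L
  for (tag in unique(events$tag_id)) {
    e <- events[events$tag_id == tag, , drop = FALSE]
    enc <- e$enclosure_id
    if (nrow(e) >= 2) {
      sw <- which(enc[-1] != enc[-nrow(e)])
      if (length(sw)) {
        mig[[tag]] <- data.frame(tag_id = tag, time = e$timestamp[sw + 1L],
                                 from_enclosure = enc[sw],
                                 to_enclosure = enc[sw + 1L],
                                 stringsAsFactors = FALSE)
      }
    }
    tube <- which(e$box_id %in% tube_boxes)
    for (k in tube) {
      nxt <- if (k < nrow(e)) enc[k + 1L] else NA_character_
      if (is.na(nxt) || nxt == enc[k]) attempts <- attempts + 1L
    }
  }
  migrations <- if (length(mig)) do.call(rbind, mig) else
    data.frame(tag_id = character(0), time = numeric(0),
               from_enclosure = character(0), to_enclosure = character(0))
  rownames(migrations) <- NULL
  list(migrations = migrations, attempts = attempts)
}
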