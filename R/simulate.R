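# Simulation of the three-period selective-feeder experiment and the two
# unmanipulated contexts (ephemeral patches, nest-boxes).
#
# Mechanics: gathering events arise per location per day as a homogeneous
# Poisson count with uniformly placed daylight centres; flock composition
# is built by sequential recruitment from the location's eligible pool,
# each candidate weighted multiplicatively by (1 + strength * P[cand, r])
# over already-recruited members r. During the manipulation each original
# site is replaced by an odd- and an even-restricted feeder sharing the
# site's event rate; birds of the wrong parity still approach their home
# site's mismatched feeder with relative propensity `denied_visit_rate`
# and are logged with access_granted = FALSE.

# Internal accumulator for detection records.
new_record_sink <- function() {
  e <- new.env(parent = emptyenv())
  e$chunks <- list()
  e$i <- 0L
  e
}

sink_add <- function(sink, tag_id, timestamp, location_id, context,
                     access_granted, true_event_id) {
  sink$i <- sink$i + 1L
  sink$chunks[[sink$i]] <- list(
    tag_id = tag_id, timestamp = timestamp, location_id = location_id,
    context = context, access_granted = access_granted,
    true_event_id = true_event_id
  )
  invisible(NULL)
}

sink_collect <- function(sink) {
  ch <- sink$chunks[seq_len(sink$i)]
  if (length(ch) == 0) {
    return(data.frame(
      tag_id = character(), timestamp = integer(),
      location_id = character(), context = character(),
      access_granted = logical(), true_event_id = integer(),
      stringsAsFactors = FALSE
    ))
  }
  df <- data.frame(
    tag_id = unlist(lapply(ch, `[[`, "tag_id")),
    timestamp = unlist(lapply(ch, `[[`, "timestamp")),
    location_id = unlist(lapply(ch, `[[`, "location_id")),
    context = unlist(lapply(ch, `[[`, "context")),
    access_granted = unlist(lapply(ch, `[[`, "access_granted")),
    true_event_id = unlist(lapply(ch, `[[`, "true_event_id")),
    stringsAsFactors = FALSE
  )
  df[order(df$timestamp, df$tag_id), , drop = FALSE]
}

# Sequential preference-weighted flock recruitment. `cands` are integer
# indices into P's roster, `base_w` their baseline weights.
compose_flock <- function(cands, base_w, P, size, strength) {
  size <- min(size, length(cands))
  if (size <= 0) return(integer())
  first <- cands[sample.int(length(cands), 1, prob = base_w)]
  chosen <- first
  avail <- cands[cands != first]
  w <- base_w[cands != first]
  while (length(chosen) < size && length(avail) > 0) {
    if (strength > 0) {
      pref <- exp(rowSums(log1p(strength * P[avail, chosen, drop = FALSE])))
      wj <- w * pref
    } else {
      wj <- w
    }
    k <- sample.int(length(avail), 1, prob = wj)
    chosen <- c(chosen, avail[k])
    avail <- avail[-k]
    w <- w[-k]
  }
  chosen
}

# Preference-bound party, used at the unmanipulated contexts. Birds reach
# an ephemeral patch, or land on one nest-box entrance, in small parties
# of current associates (co-travel), so recruitment is proportional to
# pairwise preference towards the members already present, with a small
# baseline propensity for unaffiliated joiners.
compose_party <- function(cands, P, size, baseline = 0.06) {
  size <- min(size, length(cands))
  if (size <= 0) return(integer())
  chosen <- cands[sample.int(length(cands), 1)]
  avail <- cands[cands != chosen]
  while (length(chosen) < size && length(avail) > 0) {
    w <- baseline + rowSums(P[avail, chosen, drop = FALSE])
    k <- sample.int(length(avail), 1, prob = w)
    chosen <- c(chosen, avail[k])
    avail <- avail[-k]
  }
  chosen
}

# One burst event: emit member reads jittered within the event span.
emit_event <- function(sink, tags, granted, centre, duration, location_id,
                       context, event_id, reads_mean) {
  t0 <- max(0, centre - duration / 2)
  t1 <- centre + duration / 2
  for (i in seq_along(tags)) {
    nr <- 1L + rpois(1, max(reads_mean - 1, 0))
    ts <- as.integer(round(runif(nr, t0, t1)))
    sink_add(sink, rep(tags[i], nr), ts, rep(location_id, nr),
             rep(context, nr), rep(granted[i], nr), rep(event_id, nr))
  }
  invisible(NULL)
}

#' Simulate one period of feeder activity
#'
#' Generates the detection stream at the selective feeder sites for one
#' experimental period. In `pre` and `post` all individuals are granted
#' access everywhere; in `during` each site is replaced by an odd- and an
#' even-restricted feeder and access is granted only on parity match. The
#' preference matrix is updated at the end of each simulated day from that
#' day's granted co-memberships.
#'
#' @param population a `flock_population`.
#' @param config a [scenario_config()].
#' @param period one of `"pre"`, `"during"`, `"post"`.
#' @param P symmetric preference matrix with zero diagonal (tag dimnames).
#' @param snapshot_days integer days (0-based, absolute) at whose *start*
#'   a copy of the social state (`P` and home sites) should be returned
#'   (used to hand consistent states to context simulators).
#' @param event_id_offset integer added to within-period event counters so
#'   event ids are globally unique.
#' @param home optional list of current home-site vectors (one per
#'   individual), when continuing from an earlier period; defaults to the
#'   population's initial home sites.
#' @return list with `detections` (data frame), `events` (ground-truth
#'   data frame with list-columns `members`, `members_granted`), `P`
#'   (final matrix), `home` (final home sites) and `snapshots` (named list
#'   by day of `list(P, home)`).
#' @export
simulate_period <- function(population, config, period, P,
                            snapshot_days = integer(),
                            event_id_offset = 0L,
                            home = NULL) {
  if (!period %in% c("pre", "during", "post")) {
    stop("unknown period label: ", period)
  }
  stopifnot(is.matrix(P), nrow(P) == nrow(population))
  if (!isTRUE(all.equal(P, t(P), check.attributes = FALSE))) {
    stop("P must be symmetric")
  }
  bounds <- period_bounds(config)[[period]]
  days <- seq.int(bounds[1], bounds[2] - 1L)
  parity <- as.character(population$parity)
  if (is.null(home)) home <- population$home_sites

  with_seed(child_seed(config$rng_seed, period), {
    sink <- new_record_sink()
    ev_rows <- list()
    snaps <- list()
    ev_n <- 0L
    for (d in days) {
      site_members <- site_membership(home, config$n_sites)
      day_events <- list()
      for (s in seq_len(config$n_sites)) {
        members_s <- site_members[[s]]
        if (length(members_s) == 0) next
        if (period == "during") {
          feeders <- list(
            list(loc = sprintf("F%dO", s), allow = "odd"),
            list(loc = sprintf("F%dE", s), allow = "even")
          )
          rate <- config$event_rate_per_site_day / 2
        } else {
          feeders <- list(list(loc = sprintf("F%d", s), allow = NULL))
          rate <- config$event_rate_per_site_day
        }
        for (f in feeders) {
          k <- rpois(1, rate)
          if (k == 0) next
          centres <- runif(k, (d + 0.25) * DAY_S, (d + 0.75) * DAY_S)
          for (ci in seq_len(k)) {
            if (is.null(f$allow)) {
              cands <- members_s
              base_w <- rep(1, length(cands))
            } else {
              match_p <- parity[members_s] == f$allow
              base_w <- ifelse(match_p, 1, config$denied_visit_rate)
              keep <- base_w > 0
              cands <- members_s[keep]
              base_w <- base_w[keep]
            }
            if (length(cands) == 0) next
            size <- 1L + rpois(1, max(config$mean_flock_size - 1, 0))
            idx <- compose_flock(cands, base_w, P, size,
                                 config$preference_strength)
            if (length(idx) == 0) next
            tags <- population$tag_id[idx]
            granted <- if (is.null(f$allow)) {
              rep(TRUE, length(idx))
            } else {
              parity[idx] == f$allow
            }
            dur <- rgamma(1, shape = 4, rate = 4 / config$event_duration_s)
            ev_n <- ev_n + 1L
            eid <- event_id_offset + ev_n
            emit_event(sink, tags, granted, centres[ci], dur,
                       f$loc, "selective_feeder", eid,
                       config$reads_per_visit_mean)
            ev_rows[[ev_n]] <- list(
              event_id = eid, context = "selective_feeder", period = period,
              location_id = f$loc, site = s, day = d,
              t_centre = centres[ci], duration_s = dur,
              members = tags, members_granted = tags[granted]
            )
            g <- tags[granted]
            if (length(g) >= 2) day_events[[length(day_events) + 1L]] <- g
          }
        }
      }
      P <- update_preferences(P, day_events, config$preference_update_rate)
      # snapshot reflects the day's own co-foraging: contexts sampled on
      # day d (patch visits, box prospecting) draw on the associations
      # expressed at the feeders that same day
      if (d %in% snapshot_days) {
        snaps[[as.character(d)]] <- list(P = P, home = home)
      }
      home <- drift_home(home, config$n_sites, config$site_drift_rate)
    }
    list(
      detections = sink_collect(sink),
      events = collect_truth_events(ev_rows, ev_n),
      P = P,
      home = home,
      snapshots = snaps
    )
  })
}

collect_truth_events <- function(ev_rows, n) {
  ev_rows <- ev_rows[seq_len(n)]
  if (n == 0) {
    df <- data.frame(
      event_id = integer(), context = character(), period = character(),
      location_id = character(), site = integer(), day = integer(),
      t_centre = numeric(), duration_s = numeric(), stringsAsFactors = FALSE
    )
    df$members <- list()
    df$members_granted <- list()
    return(df)
  }
  df <- data.frame(
    event_id = vapply(ev_rows, `[[`, numeric(1), "event_id"),
    context = vapply(ev_rows, `[[`, character(1), "context"),
    period = vapply(ev_rows, `[[`, character(1), "period"),
    location_id = vapply(ev_rows, `[[`, character(1), "location_id"),
    site = vapply(ev_rows, `[[`, numeric(1), "site"),
    day = vapply(ev_rows, `[[`, numeric(1), "day"),
    t_centre = vapply(ev_rows, `[[`, numeric(1), "t_centre"),
    duration_s = vapply(ev_rows, `[[`, numeric(1), "duration_s"),
    stringsAsFactors = FALSE
  )
  df$members <- lapply(ev_rows, `[[`, "members")
  df$members_granted <- lapply(ev_rows, `[[`, "members_granted")
  df
}

# site -> integer indices of individuals with that home site
site_membership <- function(home, n_sites) {
  lapply(seq_len(n_sites), function(s) {
    which(vapply(home, function(h) s %in% h, logical(1)))
  })
}

# Slow winter range drift: each day each individual shifts one of its home
# sites to a ring neighbour with probability `rate`.
drift_home <- function(home, n_sites, rate) {
  if (rate <= 0 || n_sites < 2) return(home)
  move <- runif(length(home)) < rate
  for (i in which(move)) {
    h <- home[[i]]
    j <- h[sample.int(length(h), 1)]
    step <- if (runif(1) < 0.5) -1L else 1L
    new_site <- (j + step - 1L) %% n_sites + 1L
    home[[i]] <- sort(unique(c(setdiff(h, j), new_site)))
  }
  home
}

#' Simulate an unmanipulated social context
#'
#' Generates detection streams at contexts without access rules. Ephemeral
#' food patches receive burst gathering events exactly like feeders
#' (preference-weighted recruitment, no restriction); nest-boxes receive,
#' per box and calendar day, a Poisson number of distinct prospecting
#' visitors recruited with preference weighting, each producing one or
#' more entrance-hole landing records.
#'
#' @param population a `flock_population`.
#' @param P social state driving recruitment: either a bare preference
#'   matrix (home sites taken from the population), a snapshot
#'   `list(P, home)` from [simulate_period()], or -- for nest-boxes -- a
#'   named list of daily snapshots keyed by day.
#' @param context `"ephemeral_patch"` or `"nest_box"`.
#' @param config a [scenario_config()].
#' @param days integer vector of 0-based days the context is active.
#' @param deployment_id integer identifying a patch deployment (affects the
#'   random stream and location ids; ignored for nest-boxes).
#' @param event_id_offset integer offset for globally unique event ids.
#' @return list with `detections` and ground-truth `events` as in
#'   [simulate_period()].
#' @export
simulate_context <- function(population, P, context, config, days,
                             deployment_id = 1L, event_id_offset = 0L) {
  if (!context %in% c("ephemeral_patch", "nest_box")) {
    stop("unknown context: ", context)
  }
  seed <- child_seed(config$rng_seed, context) + 131L * as.integer(deployment_id)
  with_seed(seed, {
    if (context == "ephemeral_patch") {
      simulate_patches(population, P, config, days, deployment_id,
                       event_id_offset)
    } else {
      simulate_nestboxes(population, P, config, days, event_id_offset)
    }
  })
}

# accept a bare matrix or a list(P, home) snapshot
as_state <- function(P, population) {
  if (is.matrix(P)) return(list(P = P, home = population$home_sites))
  stopifnot(is.list(P), is.matrix(P$P))
  if (is.null(P$home)) P$home <- population$home_sites
  P
}

simulate_patches <- function(population, P, config, days, deployment_id,
                             event_id_offset) {
  state <- as_state(P, population)
  P <- state$P
  site_members <- site_membership(state$home, config$n_sites)
  sink <- new_record_sink()
  ev_rows <- list()
  ev_n <- 0L
  rate <- config$event_rate_per_site_day / 2
  # each patch sits between two neighbouring sites and draws both pools
  patch_site <- sample.int(config$n_sites, config$n_patches, replace = TRUE)
  for (p in seq_len(config$n_patches)) {
    s <- patch_site[p]
    s2 <- s %% config$n_sites + 1L
    cands <- sort(unique(c(site_members[[s]], site_members[[s2]])))
    if (length(cands) == 0) next
    loc <- sprintf("P%d_%d", deployment_id, p)
    for (d in days) {
      k <- rpois(1, rate)
      if (k == 0) next
      centres <- runif(k, (d + 0.25) * DAY_S, (d + 0.75) * DAY_S)
      for (ci in seq_len(k)) {
        size <- 1L + rpois(1, max(config$mean_flock_size - 1, 0))
        idx <- compose_party(cands, P, size)
        if (length(idx) == 0) next
        tags <- population$tag_id[idx]
        dur <- rgamma(1, shape = 4, rate = 4 / config$event_duration_s)
        ev_n <- ev_n + 1L
        eid <- event_id_offset + ev_n
        emit_event(sink, tags, rep(TRUE, length(tags)), centres[ci], dur,
                   loc, "ephemeral_patch", eid, config$reads_per_visit_mean)
        ev_rows[[ev_n]] <- list(
          event_id = eid, context = "ephemeral_patch", period = NA_character_,
          location_id = loc, site = s, day = d, t_centre = centres[ci],
          duration_s = dur, members = tags, members_granted = tags
        )
      }
    }
  }
  list(detections = sink_collect(sink),
       events = collect_truth_events(ev_rows, ev_n))
}

simulate_nestboxes <- function(population, P, config, days,
                               event_id_offset) {
  # P may be one matrix, one snapshot, or daily snapshots keyed by day
  daily <- is.list(P) && is.null(P$P)
  get_state <- function(d) {
    if (!daily) return(as_state(P, population))
    key <- as.character(d)
    s <- if (!is.null(P[[key]])) P[[key]] else P[[length(P)]]
    as_state(s, population)
  }
  sink <- new_record_sink()
  ev_rows <- list()
  ev_n <- 0L
  box_site <- sample.int(config$n_sites, config$n_nestboxes, replace = TRUE)
  for (d in days) {
    state <- get_state(d)
    site_members <- site_membership(state$home, config$n_sites)
    for (b in seq_len(config$n_nestboxes)) {
      cands <- site_members[[box_site[b]]]
      if (length(cands) == 0) next
      size <- rpois(1, config$nestbox_mean_visitors)
      if (size == 0) next
      idx <- compose_party(cands, state$P, size)
      if (length(idx) == 0) next
      tags <- population$tag_id[idx]
      loc <- sprintf("B%d", b)
      ev_n <- ev_n + 1L
      eid <- event_id_offset + ev_n
      for (i in seq_along(tags)) {
        nr <- 1L + rpois(1, 2)
        ts <- as.integer(round(runif(nr, (d + 0.2) * DAY_S, (d + 0.8) * DAY_S)))
        sink_add(sink, rep(tags[i], nr), ts, rep(loc, nr),
                 rep("nest_box", nr), rep(TRUE, nr), rep(eid, nr))
      }
      ev_rows[[ev_n]] <- list(
        event_id = eid, context = "nest_box", period = NA_character_,
        location_id = loc, site = box_site[b], day = d,
        t_centre = (d + 0.5) * DAY_S, duration_s = 0.6 * DAY_S,
        members = tags, members_granted = tags
      )
    }
  }
  list(detections = sink_collect(sink),
       events = collect_truth_events(ev_rows, ev_n))
}
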