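#' Link structure records between consecutive timepoints
#'
#' Greedy nearest-centroid matching: candidate pairs within `gate_um` are
#' accepted in ascending distance order (ties broken by smaller structure id
#' at t, then at t+1), each record used at most once. Unmatched records at t
#' are deaths, unmatched records at t+1 births. Structures embedded in gel
#' are nearly stationary, so greedy matching is adequate and fully
#' deterministic; crowded, fast-moving fields would need optimal assignment.
#'
#' @param records_t,records_next record tables (need `structure_id`,
#'   `cx_um`, `cy_um`) from the same field at consecutive timepoints.
#' @param gate_um maximum centroid displacement for a link (um).
#' @return list with `matches` (data.frame `id_t`, `id_next`, `dist_um`),
#'   `deaths` (ids at t), `births` (ids at t+1).
#' @export
link_timepoints <- function(records_t, records_next, gate_um = 50) {
  if (gate_um <= 0) stop("gate_um must be positive")
  n1 <- nrow(records_t); n2 <- nrow(records_next)
  matches <- data.frame(id_t = integer(0), id_next = integer(0),
                        dist_um = numeric(0))
  if (n1 > 0 && n2 > 0) {
    d <- sqrt(outer(records_t$cx_um, records_next$cx_um, "-")^2 +
              outer(records_t$cy_um, records_next$cy_um, "-")^2)
    cand <- which(d <= gate_um, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], records_t$structure_id[cand[, 1]],
                   records_next$structure_id[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      used1 <- logical(n1); used2 <- logical(n2)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used1[i] || used2[j]) next
        used1[i] <- TRUE; used2[j] <- TRUE
        matches <- rbind(matches, data.frame(
          id_t = records_t$structure_id[i],
          id_next = records_next$structure_id[j],
          dist_um = d[i, j]))
      }
    }
  }
  list(matches = matches,
       deaths = setdiff(records_t$structure_id, matches$id_t),
       births = setdiff(records_next$structure_id, matches$id_next))
}

#' Build identity-preserving tracks across all timepoints
#'
#' Chains pairwise links into tracks (transitive closure). A track broken at
#' exactly one timepoint (e.g. a transient focus exclusion) may bridge the
#' single gap when the displacement over the doubled interval is within
#' `1.5 * gate_um`. A track is `complete` when observed at one or more
#' pre-induction timepoints (`timepoint_h <= induction_time_h`) and one or
#' more post-induction timepoints.
#'
#' @param records long record table across timepoints of one field (needs
#'   `structure_id`, `timepoint_h`, `cx_um`, `cy_um`).
#' @param arm treatment arm label attached to every track.
#' @param induction_time_h induction time (h).
#' @param gate_um per-interval matching gate (um).
#' @param bridge_gaps allow single-timepoint gap bridging.
#' @return list with `records` (input plus `track_id`) and `tracks` summary
#'   data.frame (`track_id`, `arm`, `n_records`, `first_h`, `last_h`,
#'   `complete`).
#' @export
build_tracks <- function(records, arm = "control", induction_time_h = 0,
                         gate_um = 50, bridge_gaps = TRUE) {
  tps <- sort(unique(records$timepoint_h))
  if (length(tps) < 2) stop("need records from at least 2 timepoints")
  records$track_id <- NA_integer_
  key <- function(t, id) paste(t, id)
  tid_of <- new.env(parent = emptyenv())
  next_tid <- 0L
  assign_tid <- function(t, id) {
    next_tid <<- next_tid + 1L
    assign(key(t, id), next_tid, envir = tid_of)
    next_tid
  }
  at <- function(t) records[records$timepoint_h == t, , drop = FALSE]
  for (id in at(tps[1])$structure_id) assign_tid(tps[1], id)
  open_ends <- list()   # tracks that died at t-1, eligible for one-gap bridge
  for (k in seq_len(length(tps) - 1)) {
    t0 <- tps[k]; t1 <- tps[k + 1]
    r0 <- at(t0); r1 <- at(t1)
    lk <- link_timepoints(r0, r1, gate_um)
    matched_next <- integer(0)
    for (m in seq_len(nrow(lk$matches))) {
      tid <- get(key(t0, lk$matches$id_t[m]), envir = tid_of)
      assign(key(t1, lk$matches$id_next[m]), tid, envir = tid_of)
      matched_next <- c(matched_next, lk$matches$id_next[m])
    }
    births <- setdiff(r1$structure_id, matched_next)
    if (bridge_gaps && length(open_ends) && length(births)) {
      b <- r1[r1$structure_id %in% births, , drop = FALSE]
      for (oe in open_ends) {
        if (!nrow(b)) break
        dd <- sqrt((b$cx_um - oe$cx)^2 + (b$cy_um - oe$cy)^2)
        j <- which(dd <= 1.5 * gate_um)
        if (length(j)) {
          j <- j[order(dd[j], b$structure_id[j])][1]
          assign(key(t1, b$structure_id[j]), oe$tid, envir = tid_of)
          births <- setdiff(births, b$structure_id[j])
          b <- b[-j, , drop = FALSE]
        }
      }
    }
    for (id in births) assign_tid(t1, id)
    # deaths at this transition become bridge candidates for the next one
    open_ends <- lapply(lk$deaths, function(id) {
      row <- r0[r0$structure_id == id, ]
      list(tid = get(key(t0, id), envir = tid_of),
           cx = row$cx_um, cy = row$cy_um)
    })
  }
  for (i in seq_len(nrow(records)))
    records$track_id[i] <- get(key(records$timepoint_h[i],
                                   records$structure_id[i]), envir = tid_of)
  agg <- split(records, records$track_id)
  tracks <- do.call(rbind, lapply(agg, function(g) data.frame(
    track_id = g$track_id[1], arm = arm, n_records = nrow(g),
    first_h = min(g$timepoint_h), last_h = max(g$timepoint_h),
    complete = any(g$timepoint_h <= induction_time_h) &&
      any(g$timepoint_h > induction_time_h))))
  rownames(tracks) <- NULL
  records$arm <- arm
  list(records = records, tracks = tracks)
}
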