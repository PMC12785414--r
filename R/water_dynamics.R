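# Water residency times (persistence-threshold detector), exit-region
# classification and residency aggregation.

#' Water residency criteria
#'
#' A water has left the protein at the earliest time from which its
#' oxygen-to-reference distance stays above `cutoff` for at least
#' `persistence` continuously. Defaults follow the 2 nm / 0.1 ns rule
#' measured from the chromophore beta-methylene bridge atom (atom name
#' `CB2` in the chromophore residue by default; the atom role, not the
#' name, is what matters, so the selection is overridable).
#'
#' @param cutoff distance cutoff, nm
#' @param persistence minimum continuous time above cutoff, ns
#' @param reference_atom selection resolving to the single reference atom
#' @return object of class `residency_criteria`
#' @export
residency_criteria <- function(cutoff = 2.0, persistence = 0.1,
                               reference_atom = atom_select(name = "CB2",
                                                            resname = "CRO")) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (persistence < 0) stop("persistence must be >= 0")
  structure(list(cutoff = cutoff, persistence = persistence,
                 reference_atom = reference_atom),
            class = "residency_criteria")
}

.water_oxygen <- function(traj, water_resid,
                          water_resnames = c("HOH", "SOL", "WAT", "TIP3")) {
  top <- traj$topology
  idx <- which(top$resid == water_resid & top$resname %in% water_resnames &
                 top$element == "O")
  if (length(idx) == 0L)
    stop("water residue ", water_resid, " has no oxygen atom")
  idx[1]
}

#' Distance trace of a water oxygen from the reference atom
#'
#' @param traj a `chromo_traj`
#' @param water_resid residue id of the water molecule
#' @param criteria a [residency_criteria()] (provides the reference atom)
#' @return a `chromo_series` of per-frame distances, nm
#' @export
distance_trace <- function(traj, water_resid, criteria = residency_criteria()) {
  wi <- .water_oxygen(traj, water_resid)
  ri <- .resolve_nonempty(traj, criteria$reference_atom, "reference atom")
  if (length(ri) != 1L)
    stop("reference atom selection resolves to ", length(ri), " atoms")
  d <- sqrt(colSums((traj$coords[wi, , ] - traj$coords[ri, , ])^2))
  series_stat(traj$times, d, label = paste0("water", water_resid))
}

#' Residency time by the persistence-threshold rule
#'
#' The residency time is the earliest `t*` such that the trace exceeds
#' the cutoff at every sampled frame in `[t*, t* + persistence]`
#' (window inclusive of its start frame). If no such `t*` exists the
#' record is censored at the trajectory duration.
#'
#' @param trace a `chromo_series` distance trace with uniform frame
#'   spacing
#' @param criteria a [residency_criteria()]
#' @param water_id optional identifier carried into the record
#' @return object of class `residency_record`: list with `water_id`,
#'   `residency_ns`, `censored`, `exit_region` (NA until classified) and
#'   `exit_frame` (index of `t*`, NA if censored)
#' @export
residency_time <- function(trace, criteria = residency_criteria(),
                           water_id = NA_character_) {
  tt <- trace$times
  if (length(tt) < 2L) stop("trace needs >= 2 frames")
  dt <- diff(tt)
  if (diff(range(dt)) > 1e-6 * max(dt))
    stop("non-uniform frame spacing beyond tolerance")
  dt <- dt[1]
  # frames spanning [t*, t* + persistence], inclusive of both ends
  k <- floor(criteria$persistence / dt + 1e-9) + 1L
  above <- trace$values > criteria$cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) {
    rec <- list(water_id = water_id, residency_ns = tt[length(tt)] - tt[1],
                censored = TRUE, exit_region = NA_character_,
                exit_frame = NA_integer_)
  } else {
    i0 <- starts[hit[1]]
    rec <- list(water_id = water_id, residency_ns = tt[i0] - tt[1],
                censored = FALSE, exit_region = NA_character_,
                exit_frame = i0)
  }
  structure(rec, class = "residency_record")
}

#' @export
print.residency_record <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<residency_record> %s: > %.4g ns (censored)\n",
                x$water_id, x$residency_ns))
  } else {
    cat(sprintf("<residency_record> %s: %.4g ns, exit %s\n", x$water_id,
                x$residency_ns,
                if (is.na(x$exit_region)) "(unclassified)" else x$exit_region))
  }
  invisible(x)
}

#' Classify the exit region of a departed water
#'
#' At the first frame of the persistent excursion the water oxygen is
#' assigned to the interstrand gate whose centroid (mean Calpha position
#' of the region's two residue segments at that frame) is nearest.
#' Ties resolve to the earlier region in the region set; the margin
#' between the best and second-best gate distance is recorded for audit.
#'
#' @param traj the `chromo_traj` the trace came from
#' @param water_resid residue id of the water
#' @param record a non-censored `residency_record`
#' @param regions a `region_set` (see [load_regions()])
#' @return the record with `exit_region`, `decision_distance_nm` and
#'   `decision_margin_nm` filled in
#' @export
classify_exit <- function(traj, water_resid, record, regions) {
  stopifnot(inherits(record, "residency_record"))
  if (record$censored)
    stop("cannot classify exit region of a censored record")
  if (length(regions) == 0L) stop("empty region set")
  wi <- .water_oxygen(traj, water_resid)
  w <- traj$coords[wi, , record$exit_frame]
  d <- vapply(names(regions), function(lab) {
    cen <- .region_centroid(traj, regions[[lab]], record$exit_frame)
    sqrt(sum((w - cen)^2))
  }, numeric(1))
  best <- which.min(d)  # first minimum wins on ties -> earlier label
  record$exit_region <- names(regions)[best]
  record$decision_distance_nm <- unname(d[best])
  record$decision_margin_nm <- if (length(d) > 1L)
    unname(sort(d)[2] - d[best]) else Inf
  record
}

#' Run the full residency analysis for a set of waters
#'
#' Convenience wrapper: distance trace, residency time and (for
#' non-censored records) exit classification for each water residue.
#'
#' @param traj a `chromo_traj`
#' @param water_resids residue ids of the waters of interest
#' @param regions a `region_set`
#' @param criteria a [residency_criteria()]
#' @param water_ids optional labels (default: `"W<resid>"`)
#' @return data.frame: water_id, residency_ns, censored, exit_region,
#'   decision_margin_nm
#' @export
residency_table <- function(traj, water_resids, regions,
                            criteria = residency_criteria(),
                            water_ids = paste0("W", water_resids)) {
  rows <- lapply(seq_along(water_resids), function(i) {
    tr <- distance_trace(traj, water_resids[i], criteria)
    rec <- residency_time(tr, criteria, water_id = water_ids[i])
    if (!rec$censored)
      rec <- classify_exit(traj, water_resids[i], rec, regions)
    data.frame(water_id = rec$water_id, residency_ns = rec$residency_ns,
               censored = rec$censored,
               exit_region = if (is.na(rec$exit_region)) NA_character_ else rec$exit_region,
               decision_margin_nm = if (rec$censored) NA_real_ else rec$decision_margin_nm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate per-run residency records per water
#'
#' Arithmetic mean and sample (n-1) standard deviation of the
#' non-censored residencies of each water across independent runs;
#' censored records are excluded from the statistics and counted
#' separately. A water with a single usable record reports its value
#' with an absent (NA) sd; a water with only censored records is
#' flagged unavailable (NA mean).
#'
#' @param records data.frame with columns `water_id`, `residency_ns`,
#'   `censored` (e.g. several [residency_table()] outputs row-bound)
#' @return data.frame: water_id, n, mean_ns, sd_ns, n_censored
#' @export
aggregate_residency <- function(records) {
  stopifnot(all(c("water_id", "residency_ns", "censored") %in% names(records)))
  rows <- lapply(unique(records$water_id), function(w) {
    r <- records[records$water_id == w, , drop = FALSE]
    use <- r[!r$censored, , drop = FALSE]
    n <- nrow(use)
    data.frame(water_id = w, n = n,
               mean_ns = if (n >= 1L) mean(use$residency_ns) else NA_real_,
               sd_ns = if (n >= 2L) stats::sd(use$residency_ns) else NA_real_,
               n_censored = sum(r$censored), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
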