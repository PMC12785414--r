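# Geometric hydrogen-bond detection and partitioned per-frame counting.

#' Geometric hydrogen-bond criteria
#'
#' A donor-hydrogen...acceptor triple is an H-bond when the
#' donor-acceptor distance is at most `max_da_distance` and the
#' hydrogen-donor-acceptor angle is at most `max_hda_angle`. The
#' defaults (0.35 nm, 30 degrees) are the widely used geometric cutoffs
#' of MD analysis tools.
#'
#' @param max_da_distance donor-acceptor distance cutoff, nm
#' @param max_hda_angle hydrogen-donor-acceptor angle cutoff, degrees
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  if (max_da_distance <= 0 || max_hda_angle <= 0)
    stop("hbond criteria must be positive")
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criteria")
}

# Default donor/acceptor typing: N and O heavy atoms; donors must carry
# a declared hydrogen. A small rule table, overridable by passing
# explicit selections to the detection functions.
.default_polar <- function(traj) {
  which(traj$topology$element %in% c("N", "O"))
}

.donor_hydrogens <- function(traj, donor_idx) {
  if (is.null(traj$hydrogens))
    stop("topology declares no donor hydrogens; H-bond detection needs ",
         "a trajectory with a hydrogens table (heavy-atom-only input is ",
         "unsupported)")
  serials <- traj$topology$serial[donor_idx]
  h <- traj$hydrogens[traj$hydrogens$donor %in% serials, , drop = FALSE]
  nohyd <- setdiff(serials, h$donor)
  if (length(nohyd) > 0L)
    stop("donor atom(s) without declared hydrogen: serial ",
         paste(nohyd, collapse = ", "))
  data.frame(donor = match(h$donor, traj$topology$serial),
             hydrogen = match(h$hydrogen, traj$topology$serial))
}

#' Detect hydrogen bonds in one frame
#'
#' Emits one event per (donor, hydrogen, acceptor) triple satisfying the
#' geometric criteria; self-pairs (donor == acceptor) are excluded.
#'
#' @param traj a `chromo_traj` whose `hydrogens` table declares bonded
#'   hydrogens for every donor
#' @param frame frame index
#' @param donors selection of donor heavy atoms (default: N/O atoms that
#'   carry a declared hydrogen)
#' @param acceptors selection of acceptor heavy atoms (default: all N/O)
#' @param criteria an [hbond_criteria()]
#' @return data.frame with atom indices `donor`, `hydrogen`, `acceptor`
#'   plus `distance` (nm) and `angle` (degrees)
#' @export
find_hbonds <- function(traj, frame = 1L, donors = NULL, acceptors = NULL,
                        criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  di <- if (is.null(donors)) {
    cand <- .default_polar(traj)
    if (is.null(traj$hydrogens))
      stop("topology declares no donor hydrogens; H-bond detection needs ",
           "a trajectory with a hydrogens table (heavy-atom-only input is ",
           "unsupported)")
    cand[traj$topology$serial[cand] %in% traj$hydrogens$donor]
  } else .resolve_nonempty(traj, donors, "donor selection")
  ai <- if (is.null(acceptors)) .default_polar(traj) else
    .resolve_nonempty(traj, acceptors, "acceptor selection")
  dh <- .donor_hydrogens(traj, di)
  xyz <- frame_coords(traj, frame)

  out <- list()
  for (r in seq_len(nrow(dh))) {
    d <- dh$donor[r]; h <- dh$hydrogen[r]
    acc <- setdiff(ai, d)
    if (length(acc) == 0L) next
    dv <- sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])
    dist <- sqrt(rowSums(dv^2))
    keep <- dist <= criteria$max_da_distance
    if (!any(keep)) next
    acc <- acc[keep]; dist <- dist[keep]
    hd <- xyz[h, ] - xyz[d, ]
    da <- sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])
    cosang <- (da %*% hd) / (dist * sqrt(sum(hd^2)))
    ang <- acos(pmin(1, pmax(-1, as.numeric(cosang)))) * 180 / pi
    keep2 <- ang <= criteria$max_hda_angle
    if (!any(keep2)) next
    out[[length(out) + 1L]] <-
      data.frame(donor = d, hydrogen = h, acceptor = acc[keep2],
                 distance = dist[keep2], angle = ang[keep2])
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Partitioned per-frame hydrogen-bond counts
#'
#' Counts, per frame, H-bond events with one end in `group` and the
#' other in each partner class (direction-agnostic: the group atom may
#' be the donor or the acceptor). Partner classes must be disjoint.
#'
#' @param traj a `chromo_traj`
#' @param group selection of the group of interest (e.g. chromophore
#'   heavy atoms)
#' @param partners named list of selections, e.g.
#'   `list(protein = ..., water = ...)`
#' @param criteria an [hbond_criteria()]
#' @return object of class `hbond_counts`: list with `counts`
#'   (data.frame: time_ns, one column per class, `total`), `summary`
#'   (per-class mean/sd, median of totals) and `frequency` (count value
#'   vs number of frames, per class and total)
#' @export
count_partitioned <- function(traj, group, partners,
                              criteria = hbond_criteria()) {
  gi <- .resolve_nonempty(traj, group, "group selection")
  pidx <- lapply(names(partners), function(nm)
    .resolve_nonempty(traj, partners[[nm]], paste0("partner '", nm, "'")))
  names(pidx) <- names(partners)
  if (length(pidx) >= 2L) {
    for (i in seq_along(pidx)) for (j in seq_len(i - 1L))
      if (length(intersect(pidx[[i]], pidx[[j]])) > 0L)
        stop("partner classes '", names(pidx)[j], "' and '",
             names(pidx)[i], "' overlap")
  }
  # restrict donors/acceptors to atoms that can participate at all
  relevant <- sort(unique(c(gi, unlist(pidx))))
  don_cand <- relevant[traj$topology$element[relevant] %in% c("N", "O")]
  don <- don_cand[traj$topology$serial[don_cand] %in%
                    (if (is.null(traj$hydrogens)) integer() else traj$hydrogens$donor)]
  acc <- relevant[traj$topology$element[relevant] %in% c("N", "O")]
  if (length(don) == 0L)
    stop("no donor atoms with declared hydrogens among group/partners")

  nf <- n_frames(traj)
  counts <- matrix(0L, nrow = nf, ncol = length(pidx),
                   dimnames = list(NULL, names(pidx)))
  for (k in seq_len(nf)) {
    ev <- find_hbonds(traj, k, donors = don, acceptors = acc,
                      criteria = criteria)
    if (nrow(ev) == 0L) next
    for (nm in names(pidx)) {
      cross <- (ev$donor %in% gi & ev$acceptor %in% pidx[[nm]]) |
               (ev$donor %in% pidx[[nm]] & ev$acceptor %in% gi)
      counts[k, nm] <- sum(cross)
    }
  }
  total <- as.integer(rowSums(counts))
  df <- data.frame(time_ns = traj$times, counts, total = total,
                   check.names = FALSE)
  freq_of <- function(x) {
    tb <- table(factor(x, levels = 0:max(x)))
    data.frame(count = as.integer(names(tb)), frames = as.integer(tb))
  }
  summary <- list(
    mean = colMeans(counts), sd = apply(counts, 2, stats::sd),
    mean_total = mean(total), sd_total = stats::sd(total),
    median_total = stats::median(total))
  freq <- c(lapply(as.data.frame(counts), freq_of), list(total = freq_of(total)))
  structure(list(counts = df, summary = summary, frequency = freq),
            class = "hbond_counts")
}

#' @export
print.hbond_counts <- function(x, ...) {
  cat("<hbond_counts>", nrow(x$counts), "frames\n")
  for (nm in setdiff(names(x$counts), c("time_ns", "total")))
    cat(sprintf("  %-10s %.2f +/- %.2f per frame\n", nm,
                x$summary$mean[[nm]], x$summary$sd[[nm]]))
  cat(sprintf("  total      %.2f +/- %.2f (median %g)\n",
              x$summary$mean_total, x$summary$sd_total,
              x$summary$median_total))
  invisible(x)
}
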