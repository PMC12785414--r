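# Two-state segmentation of chromophore RMSD series and acylimine
# carbonyl flip-angle analysis.

#' Two-state segmentation of an RMSD series
#'
#' Deterministic 1-D two-means clustering: centres are initialised at
#' the series minimum and maximum, points are assigned to the nearer
#' centre, centres are recomputed, and the loop runs to a fixed point.
#' States are labelled `low`/`high` by level. A (numerically) constant
#' series yields a single occupied state with zero switches. This is an
#' operational definition of the by-eye state assignment common in
#' trajectory analysis: deterministic and reproducible.
#'
#' @param series a `chromo_series` with >= 10 frames
#' @param n_states number of states; only 2 is supported
#' @return object of class `state_segmentation`: list with `states`
#'   (factor, per frame), `occupancy` (named fractions summing to 1),
#'   `switches` (number of label changes), `levels` (per-state mean)
#' @export
segment_states <- function(series, n_states = 2L) {
  if (n_states != 2L) stop("only n_states = 2 is supported")
  v <- series$values
  if (length(v) < 10L) stop("segmentation needs >= 10 frames")
  rng <- diff(range(v))
  if (rng < 1e-12 * max(abs(v), 1)) {
    states <- factor(rep("low", length(v)), levels = c("low", "high"))
    return(structure(list(states = states,
                          occupancy = c(low = 1, high = 0),
                          switches = 0L,
                          levels = c(low = mean(v), high = NA_real_)),
                     class = "state_segmentation"))
  }
  centers <- range(v)
  for (it in 1:100) {
    thr <- mean(centers)
    hi <- v > thr
    new_centers <- c(mean(v[!hi]), mean(v[hi]))
    if (isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  states <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  occ <- c(low = mean(!hi), high = mean(hi))
  structure(list(states = states, occupancy = occ,
                 switches = sum(states[-1] != states[-length(states)]),
                 levels = c(low = centers[1], high = centers[2])),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("<state_segmentation> occupancy low %.3f / high %.3f, %d switch(es)\n",
              x$occupancy["low"], x$occupancy["high"], x$switches))
  cat(sprintf("  levels: low %.4g, high %.4g\n", x$levels["low"], x$levels["high"]))
  invisible(x)
}

# Signed dihedral (degrees, in (-180, 180]) of points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("collinear geometry: dihedral undefined")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrapped angular difference in [-180, 180).
.angdiff <- function(a, b) ((a - b + 180) %% 360) - 180

#' Default dihedral quadruple for the acylimine carbonyl flip
#'
#' The flip of the carbonyl oxygen contributed by the residue preceding
#' the chromophore is monitored as the dihedral of the imidazolinone
#' nitrogen, the acylimine Calpha, the carbonyl carbon and the carbonyl
#' oxygen (atom names `N2`, `CA1`, `C1`, `O1` in the chromophore
#' residue). A ~180 degree change of this dihedral takes the carbonyl
#' out of the plane of the conjugated network.
#'
#' @return list of four single-atom `atom_selection`s
#' @export
flip_dihedral_default <- function() {
  list(atom_select(name = "N2", resname = "CRO"),
       atom_select(name = "CA1", resname = "CRO"),
       atom_select(name = "C1", resname = "CRO"),
       atom_select(name = "O1", resname = "CRO"))
}

#' Carbonyl flip-angle series and flip events
#'
#' Computes the signed dihedral of a 4-atom quadruple per frame and
#' detects flip events: frames where the angle departs from the
#' first-frame reference by at least `flip_threshold` (wrapped) and the
#' departed (or returned) state persists for at least `persistence`.
#' Both the transition into and out of the flipped state count as
#' events.
#'
#' @param traj a `chromo_traj`
#' @param dihedral_atoms list of four selections, each resolving to one
#'   atom (default: [flip_dihedral_default()])
#' @param flip_threshold departure threshold, degrees
#' @param persistence minimum duration of a state, ns (default 0.05 ns:
#'   below the residency persistence scale, above the frame interval)
#' @return object of class `flip_series`: list with `times`, `angles`
#'   (degrees), `flipped` (logical per frame, persistence-filtered),
#'   `events` (data.frame: frame, time_ns, direction)
#' @export
flip_angle <- function(traj, dihedral_atoms = flip_dihedral_default(),
                       flip_threshold = 120, persistence = 0.05) {
  if (length(dihedral_atoms) != 4L) stop("need exactly four dihedral atoms")
  idx <- vapply(seq_along(dihedral_atoms), function(i) {
    ii <- .resolve_nonempty(traj, dihedral_atoms[[i]],
                            paste0("dihedral atom ", i))
    if (length(ii) != 1L)
      stop("dihedral atom ", i, " resolves to ", length(ii), " atoms")
    ii
  }, integer(1))
  nf <- n_frames(traj)
  ang <- vapply(seq_len(nf), function(k) {
    xyz <- frame_coords(traj, k)
    tryCatch(.dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ]),
             error = function(e) stop("frame ", k, ": ", conditionMessage(e)))
  }, numeric(1))
  ref <- ang[1]
  flipped <- abs(.angdiff(ang, ref)) >= flip_threshold
  # persistence filter: absorb runs shorter than p frames into the
  # preceding state
  dt <- if (nf > 1L) traj$times[2] - traj$times[1] else persistence
  pmin_frames <- max(1L, floor(persistence / dt + 1e-9) + 1L)
  r <- rle(flipped)
  if (length(r$lengths) > 1L) {
    for (i in seq_along(r$lengths)[-1]) {
      if (r$lengths[i] < pmin_frames) r$values[i] <- r$values[i - 1L]
    }
    flipped <- inverse.rle(r)
    r2 <- rle(flipped)
    flipped <- inverse.rle(r2)
  }
  chg <- which(flipped[-1] != flipped[-nf]) + 1L
  events <- data.frame(frame = chg, time_ns = traj$times[chg],
                       direction = ifelse(flipped[chg], "flip", "return"),
                       stringsAsFactors = FALSE)
  structure(list(times = traj$times, angles = ang, flipped = flipped,
                 events = events, reference_deg = ref),
            class = "flip_series")
}

#' @export
print.flip_series <- function(x, ...) {
  cat(sprintf("<flip_series> %d frames, reference %.1f deg, %d event(s)\n",
              length(x$angles), x$reference_deg, nrow(x$events)))
  invisible(x)
}
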