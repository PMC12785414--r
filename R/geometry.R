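# Superposition, RMSD/RMSF statistics, pairwise distances and distance
# histograms.

#' Kabsch least-squares rigid superposition
#'
#' Closed-form optimal rotation/translation (SVD of the covariance with
#' determinant correction) superposing `mobile` onto `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3,
#'   matched row-for-row.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3,
#'   nm; the transform is `x %*% rotation + translation`), and `rmsd`
#'   (nm) over the input points after superposition.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference have different atom counts")
  if (nrow(mobile) < 3L) stop("superposition needs >= 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m <- sweep(mobile, 2, cm); r <- sweep(reference, 2, cr)
  if (max(abs(m)) < 1e-12 || max(abs(r)) < 1e-12)
    stop("degenerate point set: all points coincident")
  # collinearity: centered coords must have rank >= 2
  if (min(svd(m, nu = 0, nv = 0)$d[2], svd(r, nu = 0, nv = 0)$d[2]) < 1e-9)
    stop("degenerate point set: points are collinear")
  s <- svd(crossprod(m, r))           # t(m) %*% r = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- m %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
       rmsd = rmsd)
}

# Apply a kabsch fit computed on fit atoms to a full coordinate matrix.
.apply_fit <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2, fit$translation, "+")

#' Match atoms of two topologies by chain, residue id and atom name
#'
#' @param traj_a,traj_b `chromo_traj` objects
#' @param name atom name(s) to match (default `"CA"`)
#' @return two-column integer matrix of matched atom indices (a, b)
#' @export
match_atoms <- function(traj_a, traj_b, name = "CA") {
  ta <- traj_a$topology; tb <- traj_b$topology
  ka <- which(ta$name %in% name); kb <- which(tb$name %in% name)
  ida <- paste(ta$chain[ka], ta$resid[ka], ta$name[ka])
  idb <- paste(tb$chain[kb], tb$resid[kb], tb$name[kb])
  common <- intersect(ida, idb)
  if (length(common) == 0L) stop("no matched atoms between topologies")
  cbind(a = ka[match(common, ida)], b = kb[match(common, idb)])
}

#' Crystal-structure RMSD after Kabsch superposition
#'
#' Superposes matched atoms (by chain/residue/name) of two single-frame
#' structures and reports the RMSD, in Angstrom by convention for
#' crystal-to-crystal comparisons.
#'
#' @param traj_a,traj_b single-frame `chromo_traj` structures
#' @param name atom name(s) to match, default Calpha
#' @param units `"angstrom"` (default) or `"nm"`
#' @return list: `rmsd`, `n_atoms`, `units`
#' @export
structural_rmsd <- function(traj_a, traj_b, name = "CA", units = c("angstrom", "nm")) {
  units <- match.arg(units)
  mm <- match_atoms(traj_a, traj_b, name = name)
  fit <- kabsch(frame_coords(traj_a, 1)[mm[, 1], , drop = FALSE],
                frame_coords(traj_b, 1)[mm[, 2], , drop = FALSE])
  r <- if (units == "angstrom") fit$rmsd * 10 else fit$rmsd
  list(rmsd = r, n_atoms = nrow(mm), units = units)
}

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference on the fit selection
#' (typically protein Calpha) and the RMSD is reported over the measure
#' selection (typically chromophore heavy atoms).
#'
#' @param traj a `chromo_traj`
#' @param reference reference coordinates: a frame index into `traj`, or
#'   an n_atoms x 3 matrix (nm) over the full topology
#' @param fit_sel,measure_sel `atom_selection`s (or index vectors)
#' @return a `chromo_series` of RMSD values, nm
#' @export
rmsd_series <- function(traj, reference = 1L, fit_sel, measure_sel) {
  fi <- .resolve_nonempty(traj, fit_sel, "fit selection")
  mi <- .resolve_nonempty(traj, measure_sel, "measure selection")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    fit <- kabsch(xyz[fi, , drop = FALSE], ref[fi, , drop = FALSE])
    moved <- .apply_fit(xyz[mi, , drop = FALSE], fit)
    sqrt(mean(rowSums((moved - ref[mi, , drop = FALSE])^2)))
  }, numeric(1))
  series_stat(traj$times, vals, label = "rmsd")
}

#' Root-mean-square fluctuation profile
#'
#' Two-pass procedure: all frames are superposed (on the fit selection)
#' onto frame 1, the time-averaged structure is formed, frames are
#' re-superposed onto that average, and
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` is computed over the
#' measure selection. No mass weighting.
#'
#' @param traj a `chromo_traj` with >= 2 frames
#' @param measure_sel atoms to report (default: all atoms)
#' @param fit_sel atoms used for superposition (default: all Calpha)
#' @param by `"atom"` keys results as `"resid:name"`; `"residue"`
#'   reduces to per-residue Calpha keyed by residue id
#' @return data.frame of class `fluct_profile` with columns `key`, `rmsf`
#'   (nm)
#' @export
rmsf <- function(traj, measure_sel = NULL, fit_sel = atom_select(name = "CA"),
                 by = c("atom", "residue")) {
  by <- match.arg(by)
  if (n_frames(traj) < 2L) stop("RMSF needs at least two frames")
  if (by == "residue") measure_sel <- atom_select(name = "CA")
  mi <- if (is.null(measure_sel)) seq_len(n_atoms(traj)) else
    .resolve_nonempty(traj, measure_sel, "measure selection")
  fi <- .resolve_nonempty(traj, fit_sel, "fit selection")
  nf <- n_frames(traj)

  align_to <- function(ref) {
    arr <- array(0, c(n_atoms(traj), 3, nf))
    for (k in seq_len(nf)) {
      xyz <- frame_coords(traj, k)
      fit <- kabsch(xyz[fi, , drop = FALSE], ref[fi, , drop = FALSE])
      arr[, , k] <- .apply_fit(xyz, fit)
    }
    arr
  }
  aligned <- align_to(frame_coords(traj, 1))
  avg <- apply(aligned, c(1, 2), mean)
  aligned <- align_to(avg)
  avg <- apply(aligned, c(1, 2), mean)

  dev2 <- matrix(0, nrow = length(mi), ncol = nf)
  for (k in seq_len(nf))
    dev2[, k] <- rowSums((matrix(aligned[mi, , k], ncol = 3) -
                            avg[mi, , drop = FALSE])^2)
  vals <- sqrt(rowMeans(dev2))
  top <- traj$topology
  key <- if (by == "residue") as.character(top$resid[mi]) else
    paste0(top$resid[mi], ":", top$name[mi])
  structure(data.frame(key = key, rmsf = vals, stringsAsFactors = FALSE),
            class = c("fluct_profile", "data.frame"))
}

#' Difference of two fluctuation profiles
#'
#' Elementwise `a - b` over identical key sets; positive values mean the
#' first profile is more mobile.
#'
#' @param a,b `fluct_profile` objects with identical key sets
#' @return a `fluct_profile` of differences (may be negative)
#' @export
delta_rmsf <- function(a, b) {
  missing_in_b <- setdiff(a$key, b$key)
  missing_in_a <- setdiff(b$key, a$key)
  if (length(missing_in_b) || length(missing_in_a))
    stop("profile key mismatch; missing in b: ",
         paste(missing_in_b, collapse = ","), "; missing in a: ",
         paste(missing_in_a, collapse = ","))
  d <- a$rmsf - b$rmsf[match(a$key, b$key)]
  structure(data.frame(key = a$key, rmsf = d, stringsAsFactors = FALSE),
            class = c("fluct_profile", "data.frame"))
}

#' Per-frame distance between two atoms
#'
#' @param traj a `chromo_traj`
#' @param a,b selections each resolving to exactly one atom
#' @return a `chromo_series` of Euclidean distances, nm
#' @export
pair_distance_series <- function(traj, a, b) {
  ia <- .resolve_nonempty(traj, a, "selection 'a'")
  ib <- .resolve_nonempty(traj, b, "selection 'b'")
  if (length(ia) != 1L || length(ib) != 1L)
    stop("pair_distance_series needs single-atom selections (got ",
         length(ia), " and ", length(ib), ")")
  d <- sqrt(colSums((matrix(traj$coords[ia, , ], nrow = 3) -
                       matrix(traj$coords[ib, , ], nrow = 3))^2))
  top <- traj$topology
  series_stat(traj$times, d,
              label = paste0(top$resid[ia], ":", top$name[ia], "-",
                             top$resid[ib], ":", top$name[ib]))
}

#' Histogram of a series with fixed-width bins anchored at zero
#'
#' Bins are left-closed right-open `[k*w, (k+1)*w)`. The mode is the
#' centre of the most populated bin; ties resolve to the lower bin.
#'
#' @param series a `chromo_series`
#' @param bin_width bin width, nm (> 0)
#' @return list: `breaks`, `centers`, `counts`, `mode` (bin centre)
#' @export
distance_histogram <- function(series, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  v <- series$values
  if (length(v) == 0L) stop("empty series")
  if (any(v < 0)) stop("negative values in distance series")
  bin <- floor(v / bin_width)            # left-closed, right-open
  k <- 0:max(bin)
  counts <- tabulate(bin + 1L, nbins = length(k))
  centers <- (k + 0.5) * bin_width
  mode_bin <- which.max(counts)          # which.max takes the first tie
  list(breaks = c(k, max(bin) + 1L) * bin_width, centers = centers,
       counts = counts, mode = centers[mode_bin])
}
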