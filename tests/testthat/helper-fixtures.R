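# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (loops, grids, window scans) and share
# no code with the implementation they check.

# tiny trajectory from a list of per-frame coordinate matrices
make_traj <- function(frames, names, resnames = "X", resids = 1L,
                      chains = "A", elements = NULL, dt = 0.01,
                      hydrogens = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(elements)) elements <- substr(names, 1, 1)
  top <- data.frame(serial = seq_len(n), name = names,
                    element = rep_len(elements, n),
                    resname = rep_len(resnames, n),
                    resid = rep_len(resids, n),
                    chain = rep_len(chains, n), stringsAsFactors = FALSE)
  arr <- array(0, c(n, 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  trajectory(top, arr, times = (seq_along(frames) - 1) * dt,
             hydrogens = hydrogens)
}

# random rigid transform (rotation from QR, det +1)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, trans = rnorm(3))
}

rot_euler <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# brute-force minimum RMSD over rotation space: coarse Euler-angle grid
# followed by Nelder-Mead polish of the best grid point. Independent of
# the SVD route.
rmsd_rotation_search <- function(mobile, reference, grid_step = pi / 12) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) {
    rot <- rot_euler(p[1], p[2], p[3])
    sqrt(mean(rowSums((m %*% t(rot) - r)^2)))
  }
  best <- NULL; bestv <- Inf
  for (a in seq(0, 2 * pi, by = grid_step))
    for (b in seq(0, pi, by = grid_step))
      for (cc in seq(0, 2 * pi, by = grid_step)) {
        v <- obj(c(a, b, cc))
        if (v < bestv) { bestv <- v; best <- c(a, b, cc) }
      }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# brute-force all-pairs H-bond scan: triple loop, no vectorisation
brute_hbonds <- function(traj, frame, donor_idx, acceptor_idx, criteria) {
  xyz <- frame_coords(traj, frame)
  top <- traj$topology
  hyd <- traj$hydrogens
  out <- list()
  for (d in donor_idx) {
    hs <- hyd$hydrogen[hyd$donor == top$serial[d]]
    for (hserial in hs) {
      h <- which(top$serial == hserial)
      for (a in acceptor_idx) {
        if (a == d) next
        da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
        if (da > criteria$max_da_distance) next
        v1 <- xyz[h, ] - xyz[d, ]
        v2 <- xyz[a, ] - xyz[d, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang <= criteria$max_hda_angle)
          out[[length(out) + 1L]] <- c(d, h, a)
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(), ncol = 3))
  do.call(rbind, out)
}

# brute-force residency: scan every window start
residency_scan <- function(trace, cutoff, persistence) {
  tt <- trace$times; v <- trace$values
  dt <- tt[2] - tt[1]
  k <- floor(persistence / dt + 1e-9) + 1
  for (i in seq_len(length(v) - k + 1)) {
    if (all(v[i:(i + k - 1)] > cutoff)) return(tt[i] - tt[1])
  }
  NA_real_  # censored
}

# hand-written 3-atom PDB content with known Angstrom coordinates
tiny_pdb_lines <- function(dup_serial = FALSE) {
  s2 <- if (dup_serial) 1L else 2L
  c(sprintf("ATOM  %5d  CA  ALA A   1      10.000  20.000  30.000  1.00  0.00           C", 1L),
    sprintf("ATOM  %5d  CB  ALA A   1      11.500  20.000  30.000  1.00  0.00           C", s2),
    sprintf("ATOM  %5d  O   HOH W   2       0.000   0.000   5.000  1.00  0.00           O", 3L),
    "END")
}
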