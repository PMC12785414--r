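# Synthetic trajectory and titration generators with planted, recorded
# ground truth. The barrel template is a stylized 11-strand cylinder
# with labelled residues, not a real protein: every downstream analysis
# depends only on labelled geometry, which keeps the test-bed fully
# offline.

# run code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stylized beta-barrel template topology and base coordinates
#'
#' Eleven strand segments on a cylinder (radius 1.2 nm) in the spatial
#' order that places strand 3 next to strand 11, strand 10 next to
#' strand 7 and strand 7 next to strand 8, so the four interstrand exit
#' gates of the shipped region config exist with realistic gaps. Strand
#' 7 is bulge-split: S7A (residues 139-145) occupies the lower half of
#' its slot and S7B (146-153) the upper half. Marker residues A145,
#' K198, T43 and Y214 carry their author numbers. A chromophore residue
#' (resname `CRO`, resid 66) sits at the barrel centre with a
#' beta-methylene bridge atom `CB2` at the origin, an acylimine
#' carbonyl (`CA1`,`C1`,`O1`) contributed by the preceding residue, an
#' imidazolinone nitrogen `N2`, a thiol sulphur `SG` and a phenol ring
#' with a protonated hydroxyl (donor `OH`-`HO`).
#'
#' @return list: `topology`, `coords` (base n_atoms x 3, nm),
#'   `hydrogens`, `bridge_index`, `strands` (residue ranges)
#' @keywords internal
barrel_template <- function() {
  strands <- list(
    S1 = c(10, 17), S2 = c(25, 32), S3 = c(40, 47), S4 = c(90, 97),
    S5 = c(105, 112), S6 = c(118, 125), S7A = c(139, 145),
    S7B = c(146, 153), S8 = c(160, 167), S9 = c(176, 183),
    S10 = c(193, 200), S11 = c(210, 217))
  slot_order <- c("S1", "S2", "S3", "S11", "S10", "S7", "S8", "S9",
                  "S4", "S5", "S6")
  angle <- stats::setNames(2 * pi * (seq_along(slot_order) - 1) / 11,
                           slot_order)
  radius <- 1.2
  marker <- c("145" = "ALA", "198" = "LYS", "43" = "THR", "214" = "TYR")

  rows <- list(); xyz <- list()
  add <- function(name, element, resname, resid, chain, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = name, element = element,
      resname = resname, resid = resid, chain = chain,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  strand_z <- function(sname, n) {
    if (sname == "S7A") seq(-1.4, -0.2, length.out = n)
    else if (sname == "S7B") seq(0.0, 1.4, length.out = n)
    else seq(-1.4, 1.4, length.out = n)
  }
  for (sname in names(strands)) {
    slot <- if (sname %in% c("S7A", "S7B")) "S7" else sname
    th <- angle[[slot]]
    rr <- strands[[sname]][1]:strands[[sname]][2]
    zz <- strand_z(sname, length(rr))
    for (i in seq_along(rr)) {
      rn <- marker[as.character(rr[i])]
      if (is.na(rn)) rn <- "GLY"
      add("CA", "C", rn, rr[i], "A",
          c(radius * cos(th), radius * sin(th), zz[i]))
    }
  }
  # chromophore (resid 66), bridge CB2 at the origin
  cro <- list(
    CB2 = c(0, 0, 0), C2 = c(-0.14, 0.05, 0), N2 = c(-0.25, 0.18, 0),
    O2 = c(-0.10, -0.10, 0.05), CA1 = c(-0.45, 0.20, 0),
    C1 = c(-0.50, 0.06, 0.02), O1 = c(-0.62, 0.00, 0.08),
    SG = c(-0.55, 0.35, 0.10), CG = c(0.14, 0.05, 0),
    CD1 = c(0.26, -0.02, 0), CD2 = c(0.16, 0.19, 0),
    CE1 = c(0.39, 0.04, 0), CE2 = c(0.29, 0.25, 0),
    CZ = c(0.40, 0.18, 0), OH = c(0.52, 0.25, 0), HO = c(0.58, 0.31, 0))
  for (nm in names(cro)) {
    el <- substr(nm, 1, 1)
    if (el == "H") el <- "H"
    if (nm == "SG") el <- "S"
    add(nm, el, "CRO", 66, "A", cro[[nm]])
  }
  top <- do.call(rbind, rows)
  top$serial <- seq_len(nrow(top))
  coords <- do.call(rbind, xyz)
  oh <- top$serial[top$name == "OH" & top$resname == "CRO"]
  ho <- top$serial[top$name == "HO" & top$resname == "CRO"]
  list(topology = top, coords = coords,
       hydrogens = data.frame(donor = oh, hydrogen = ho),
       bridge_index = which(top$name == "CB2" & top$resname == "CRO"),
       strands = strands)
}

.water_atoms <- function(resid, serial0, opos) {
  top <- data.frame(
    serial = serial0 + 0:2, name = c("O", "H1", "H2"),
    element = c("O", "H", "H"), resname = "HOH", resid = resid,
    chain = "W", stringsAsFactors = FALSE)
  coords <- rbind(opos, opos + c(0.095, 0, 0), opos + c(-0.024, 0.092, 0))
  list(topology = top, coords = coords,
       hydrogens = data.frame(donor = serial0, hydrogen = serial0 + 1:2))
}

#' Specification of a synthetic trajectory
#'
#' @param duration trajectory length, ns (default 1000, the production
#'   run length the generator emulates)
#' @param frame_interval frame spacing, ns (default 0.01, so a 1000 ns
#'   run holds 100,001 frames inclusive of both endpoints)
#' @param noise_sd isotropic Gaussian positional noise per coordinate,
#'   nm (default 0.01, a mild thermal jitter)
#' @param waters data.frame of residency plants with columns
#'   `water_id`, `exit_time` (ns; NA = never leaves), `region` (gate
#'   label for the escape path; NA for residents) and optionally `dwell`
#'   (pre-exit distance from the bridge atom, nm; default 0.6)
#' @param flips times (ns) at which the acylimine carbonyl toggles
#'   between its reference and 180-degree-flipped orientation
#' @param hbond_counts scripted per-frame count of chromophore-water
#'   H-bonds: a single integer (constant) or a vector recycled to the
#'   frame count; NULL for none
#' @param breathing optional `list(amplitude, period)` (nm, ns): moves
#'   the A145 Calpha sinusoidally along the A145-K198 axis
#' @param regions `region_set` used to aim escape paths (default the
#'   shipped config, which matches the template numbering)
#' @param seed integer RNG seed; same seed, same trajectory
#' @return object of class `trajectory_spec`
#' @export
trajectory_spec <- function(duration = 1000, frame_interval = 0.01,
                            noise_sd = 0.01, waters = NULL,
                            flips = numeric(0), hbond_counts = NULL,
                            breathing = NULL, regions = load_regions(),
                            seed = 1L) {
  if (duration <= 0 || frame_interval <= 0)
    stop("duration and frame_interval must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(waters)) {
    stopifnot(all(c("water_id", "exit_time", "region") %in% names(waters)))
    if (is.null(waters$dwell)) waters$dwell <- 0.6
    bad <- !is.na(waters$exit_time) & waters$exit_time >= duration
    if (any(bad)) stop("exit times must be < duration")
    planted <- stats::na.omit(unique(waters$region))
    unknown <- setdiff(planted, names(regions))
    if (length(unknown) > 0L)
      stop("planted region(s) absent from region set: ",
           paste(unknown, collapse = ", "))
  }
  if (any(flips < 0 | flips >= duration)) stop("flip times must lie in [0, duration)")
  structure(list(duration = duration, frame_interval = frame_interval,
                 noise_sd = noise_sd, waters = waters,
                 flips = sort(flips), hbond_counts = hbond_counts,
                 breathing = breathing, regions = regions,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

# rotate point p by 180 degrees about the axis through a with direction u
.rot180 <- function(p, a, u) {
  u <- u / sqrt(sum(u^2))
  v <- p - a
  a + 2 * sum(v * u) * u - v
}

#' Generate a synthetic trajectory with planted events
#'
#' Builds the barrel template, scripts water escape paths (dwell below
#' the bridge-atom cutoff, then a step to 0.2 nm beyond 2 nm at the
#' planted exit time followed by a slow outward drift along the planted
#' gate direction), toggles the acylimine carbonyl at the planted flip
#' times, realises scripted chromophore-water H-bond counts
#' geometrically (donor at 0.28 nm / 10 degrees when bonded, 0.6 nm
#' when not, so the detector is exercised, not shortcut), and finally
#' adds isotropic Gaussian jitter to every atom. Margins of all plants
#' are several standard deviations wide at the default noise, so the
#' planted events are recoverable exactly.
#'
#' @param spec a [trajectory_spec()]
#' @return list with `trajectory` (a `chromo_traj`) and `truth` (class
#'   `ground_truth`: the planted schedule)
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  tmpl <- barrel_template()
  nf <- as.integer(round(spec$duration / spec$frame_interval)) + 1L
  times <- (seq_len(nf) - 1L) * spec$frame_interval

  top <- tmpl$topology
  base <- tmpl$coords
  hyd <- tmpl$hydrogens
  bridge <- base[tmpl$bridge_index, ]

  # gate centroids from the unperturbed template
  base_traj <- trajectory(top, array(base, c(nrow(top), 3, 1)), 0)
  centroid <- lapply(spec$regions, function(r)
    .region_centroid(base_traj, r, 1L))

  # residency-plant waters
  wtab <- spec$waters
  n_w <- if (is.null(wtab)) 0L else nrow(wtab)
  wserial <- max(top$serial)
  w_atom_rows <- list()
  if (n_w > 0L) {
    for (i in seq_len(n_w)) {
      dir <- if (is.na(wtab$region[i])) c(0, 0, 1) else {
        d <- centroid[[wtab$region[i]]] - bridge
        d / sqrt(sum(d^2))
      }
      wa <- .water_atoms(1000L + i, wserial + 1L, bridge + wtab$dwell[i] * dir)
      wserial <- wserial + 3L
      w_atom_rows[[i]] <- c(wa, list(dir = dir))
      top <- rbind(top, wa$topology)
      base <- rbind(base, wa$coords)
      hyd <- rbind(hyd, wa$hydrogens)
    }
  }

  # H-bond plant waters around the acylimine carbonyl oxygen
  hc <- NULL
  hb_rows <- list()
  if (!is.null(spec$hbond_counts)) {
    hc <- as.integer(rep_len(spec$hbond_counts, nf))
    kmax <- max(hc)
    if (kmax > 0L) {
      # anchored to the imidazolinone oxygen (static under carbonyl
      # flips), aimed into the solvent-free -y half-space
      o2 <- base[which(top$name == "O2" & top$resname == "CRO"), ]
      for (j in seq_len(kmax)) {
        phi <- 2 * pi * (j - 1) / max(kmax, 1L)
        dir <- c(0.5 * cos(phi), -1, 0.5 * sin(phi))
        dir <- dir / sqrt(sum(dir^2))
        bonded_o <- o2 + 0.28 * dir
        far_o <- o2 + 0.60 * dir
        wa <- .water_atoms(2000L + j, wserial + 1L, far_o)
        # hydrogen H1 points back at the acceptor (near-zero H-D-A angle)
        wa$coords[2, ] <- far_o - 0.10 * dir
        wserial <- wserial + 3L
        hb_rows[[j]] <- list(wa = wa, bonded_o = bonded_o, far_o = far_o,
                             dir = dir)
        top <- rbind(top, wa$topology)
        base <- rbind(base, wa$coords)
        hyd <- rbind(hyd, wa$hydrogens)
      }
    }
  }

  na <- nrow(top)
  coords <- array(base, c(na, 3, nf))  # replicates base across frames

  # scripted water escape paths
  truth_waters <- NULL
  if (n_w > 0L) {
    for (i in seq_len(n_w)) {
      oi <- which(top$resid == 1000L + i & top$name == "O")
      dir <- w_atom_rows[[i]]$dir
      u <- rep(wtab$dwell[i], nf)
      censored <- is.na(wtab$exit_time[i])
      if (!censored) {
        out <- times >= wtab$exit_time[i] - 1e-9
        u[out] <- 2.2 + 0.1 * (times[out] - wtab$exit_time[i])
      }
      for (ax in 1:3) {
        coords[oi, ax, ] <- bridge[ax] + u * dir[ax]
        coords[oi + 1L, ax, ] <- coords[oi, ax, ] +
          c(0.095, 0, 0)[ax]
        coords[oi + 2L, ax, ] <- coords[oi, ax, ] +
          c(-0.024, 0.092, 0)[ax]
      }
    }
    truth_waters <- data.frame(
      water_id = wtab$water_id, resid = 1000L + seq_len(n_w),
      residency_ns = ifelse(is.na(wtab$exit_time), spec$duration,
                            wtab$exit_time),
      region = wtab$region, censored = is.na(wtab$exit_time),
      stringsAsFactors = FALSE)
  }

  # acylimine carbonyl flips: toggle at each planted time
  if (length(spec$flips) > 0L) {
    io1 <- which(top$name == "O1" & top$resname == "CRO")
    ica1 <- which(top$name == "CA1" & top$resname == "CRO")
    ic1 <- which(top$name == "C1" & top$resname == "CRO")
    o1_flip <- .rot180(base[io1, ], base[ic1, ], base[ic1, ] - base[ica1, ])
    nflips <- vapply(times, function(t)
      sum(spec$flips <= t + 1e-9), numeric(1))
    flipped <- nflips %% 2 == 1
    for (ax in 1:3) coords[io1, ax, flipped] <- o1_flip[ax]
  }

  # scripted H-bond counts, realised geometrically
  if (!is.null(hc) && length(hb_rows) > 0L) {
    for (j in seq_along(hb_rows)) {
      r <- hb_rows[[j]]
      oj <- which(top$resid == 2000L + j & top$name == "O")
      bonded <- hc >= j
      for (ax in 1:3) {
        coords[oj, ax, bonded] <- r$bonded_o[ax]
        coords[oj + 1L, ax, bonded] <- r$bonded_o[ax] - 0.10 * r$dir[ax]
        # H2 and the far-position H1 keep their base offsets
      }
    }
  }

  # gap breathing: A145 Calpha oscillates along the A145-K198 axis
  truth_breathing <- NULL
  if (!is.null(spec$breathing)) {
    ia <- which(top$name == "CA" & top$resid == 145)
    ik <- which(top$name == "CA" & top$resid == 198)
    u <- base[ik, ] - base[ia, ]
    d0 <- sqrt(sum(u^2)); u <- u / d0
    amp <- spec$breathing$amplitude
    disp <- amp * sin(2 * pi * times / spec$breathing$period)
    for (ax in 1:3) coords[ia, ax, ] <- base[ia, ax] + disp * u[ax]
    truth_breathing <- data.frame(time_ns = times, distance_nm = d0 - disp)
  }

  if (spec$noise_sd > 0) {
    coords <- coords + .with_seed(spec$seed,
      array(stats::rnorm(na * 3 * nf, 0, spec$noise_sd), c(na, 3, nf)))
  }

  traj <- trajectory(top, coords, times, hydrogens = hyd)
  truth <- structure(list(
    waters = truth_waters, flips = spec$flips,
    hbond_counts = hc, breathing = truth_breathing,
    duration = spec$duration, frame_interval = spec$frame_interval,
    noise_sd = spec$noise_sd, seed = spec$seed), class = "ground_truth")
  list(trajectory = traj, truth = truth)
}

#' Serialize / restore a planted ground-truth schedule
#'
#' @param truth a `ground_truth`
#' @param path JSON output path
#' @return `write_ground_truth`: invisibly, `path`;
#'   `read_ground_truth`: the restored `ground_truth`
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("waters", "breathing"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]])
  if (is.null(x$flips)) x$flips <- numeric(0)
  x$flips <- as.numeric(x$flips)
  structure(x, class = "ground_truth")
}

#' Specification of a synthetic titration
#'
#' @param model planted `ionization_model` (ground truth)
#' @param basis species basis spectra (default [default_basis()])
#' @param ph pH points; default the 4.5-11 buffer ladder used for
#'   FP titrations
#' @param wavelengths wavelength grid, nm
#' @param noise_sd Gaussian absorbance noise sd (0 = noiseless)
#' @param seed RNG seed
#' @return object of class `titration_spec`
#' @export
titration_spec <- function(model, basis = default_basis(model),
                           ph = c(4.5, 5, 5.5, 6, 7, 8, 9, 10, 11),
                           wavelengths = seq(350, 650, by = 1),
                           noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "ionization_model"))
  if (any(ph < 0 | ph > 14)) stop("pH points must lie in [0, 14]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(model = model, basis = basis, ph = ph,
                 wavelengths = wavelengths, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate a synthetic titration series
#'
#' Per-pH spectrum = [predict_spectrum()] of the planted model plus
#' Gaussian noise (clipped at zero absorbance). Reproducible from the
#' seed.
#'
#' @param spec a [titration_spec()]
#' @return list with `series` (a `titration_series`) and `truth` (the
#'   planted `ionization_model`)
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  a <- t(vapply(spec$ph, function(p)
    predict_spectrum(p, spec$model, spec$basis, spec$wavelengths),
    numeric(length(spec$wavelengths))))
  if (spec$noise_sd > 0) {
    a <- a + .with_seed(spec$seed,
      matrix(stats::rnorm(length(a), 0, spec$noise_sd), nrow(a), ncol(a)))
    a <- pmax(a, 0)
  }
  list(series = titration_series(spec$ph, spec$wavelengths, a),
       truth = spec$model)
}
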