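#' Construct a trajectory object
#'
#' A trajectory couples a topology (one row per atom, author residue
#' numbering preserved) with an ordered series of coordinate frames.
#' Coordinates are stored in nanometres and times in nanoseconds
#' throughout the package; Angstroms appear only at PDB file boundaries
#' and in crystal-structure RMSD reporting.
#'
#' @param topology data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`. Serials must be unique.
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`, nm.
#' @param times numeric vector of frame times in ns, strictly increasing
#'   and uniformly spaced (within a relative tolerance of 1e-6).
#' @param hydrogens optional data.frame with columns `donor` and
#'   `hydrogen` (atom serials) declaring covalently bonded hydrogens for
#'   hydrogen-bond donor atoms. Required by [find_hbonds()].
#' @return An object of class `chromo_traj`.
#' @export
trajectory <- function(topology, coords, times, hydrogens = NULL) {
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0L)
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(topology$serial))
    stop("duplicate atom serials in topology: ",
         paste(unique(topology$serial[duplicated(topology$serial)]), collapse = ", "))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("coordinate count (", dim(coords)[1], ") does not equal topology atom count (",
         nrow(topology), ")")
  if (dim(coords)[3] < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (length(times) != dim(coords)[3])
    stop("length(times) must equal the number of frames")
  if (any(times < 0)) stop("frame times must be non-negative")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * max(dt))
      stop("frame spacing is not uniform within tolerance")
  }
  if (!is.null(hydrogens)) {
    if (!all(c("donor", "hydrogen") %in% names(hydrogens)))
      stop("hydrogens must have columns 'donor' and 'hydrogen'")
    unknown <- setdiff(c(hydrogens$donor, hydrogens$hydrogen), topology$serial)
    if (length(unknown) > 0L)
      stop("hydrogens table references unknown serials: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(topology = as.data.frame(topology, stringsAsFactors = FALSE),
                 coords = coords, times = as.numeric(times),
                 hydrogens = hydrogens),
            class = "chromo_traj")
}

#' @export
print.chromo_traj <- function(x, ...) {
  cat(sprintf("<chromo_traj> %d atoms, %d frame(s), %.4g-%.4g ns\n",
              n_atoms(x), n_frames(x), x$times[1], x$times[n_frames(x)]))
  cat("  residues:", length(unique(paste(x$topology$chain, x$topology$resid))),
      " chains:", paste(unique(x$topology$chain), collapse = ","), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `chromo_traj`
#' @return integer count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj a `chromo_traj`
#' @param i frame index
#' @return n_atoms x 3 matrix, nm
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  traj$coords[, , i, drop = TRUE]
}

#' Declare an atom selection
#'
#' Selections are predicates over atom name, residue name, author residue
#' id, chain and element. Resolution against a topology is deterministic
#' and order-preserving (topology order). `NULL` fields match anything.
#'
#' @param name,resname,resid,chain,element optional vectors of admissible
#'   values for the corresponding topology columns.
#' @return An object of class `atom_selection`.
#' @export
atom_select <- function(name = NULL, resname = NULL, resid = NULL,
                        chain = NULL, element = NULL) {
  structure(list(name = name, resname = resname, resid = resid,
                 chain = chain, element = element),
            class = "atom_selection")
}

#' Resolve an atom selection against a topology
#'
#' @param traj a `chromo_traj` (or a bare topology data.frame)
#' @param sel an `atom_selection`, or an integer vector of atom indices
#'   (returned unchanged after bounds checking)
#' @return integer vector of atom indices in topology order
#' @export
resolve_selection <- function(traj, sel) {
  top <- if (inherits(traj, "chromo_traj")) traj$topology else traj
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(top))) stop("selection index out of range")
    return(idx)
  }
  if (!inherits(sel, "atom_selection")) stop("not an atom_selection")
  keep <- rep(TRUE, nrow(top))
  if (!is.null(sel$name))    keep <- keep & top$name    %in% sel$name
  if (!is.null(sel$resname)) keep <- keep & top$resname %in% sel$resname
  if (!is.null(sel$resid))   keep <- keep & top$resid   %in% sel$resid
  if (!is.null(sel$chain))   keep <- keep & top$chain   %in% sel$chain
  if (!is.null(sel$element)) keep <- keep & top$element %in% sel$element
  which(keep)
}

.resolve_nonempty <- function(traj, sel, what = "selection") {
  idx <- resolve_selection(traj, sel)
  if (length(idx) == 0L) stop(what, " resolves to no atoms")
  idx
}

# -- PDB input/output ---------------------------------------------------

# Validates MODEL blocks of a (possibly multi-model) PDB file at line
# level: per-model atom counts and atom identity/ordering must agree with
# model 1. bio3d does the coordinate parsing; this enforces the ordering
# contract it does not check.
.validate_pdb_models <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) return(invisible(1L))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  ident <- NULL
  for (m in seq_along(model_starts)) {
    block <- lines[model_starts[m]:model_ends[m]]
    at <- block[grepl("^(ATOM  |HETATM)", block)]
    id <- substr(at, 13, 27)  # name, altloc, resname, chain, resid
    if (m == 1L) {
      ident <- id
    } else {
      if (length(id) != length(ident))
        stop("inconsistent atom count in model ", m, " of ", path,
             " (", length(id), " vs ", length(ident), ")")
      if (!identical(id, ident))
        stop("atom ordering in model ", m, " of ", path,
             " differs from model 1")
    }
  }
  invisible(length(model_starts))
}

.topology_from_bio3d <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(a$elety), 1, 1)
  }
  elem <- trimws(elem)
  elem[elem == ""] <- substr(trimws(a$elety[elem == ""]), 1, 1)
  data.frame(serial = a$eleno, name = trimws(a$elety), element = elem,
             resname = trimws(a$resid), resid = a$resno,
             chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             stringsAsFactors = FALSE)
}

#' Read a single-model PDB structure
#'
#' Coordinates are converted from Angstrom to nm; atom metadata (author
#' residue numbering, chain ids, atom names) is preserved unchanged. The
#' result is a one-frame trajectory at time 0.
#'
#' @param path path to a PDB file
#' @return a `chromo_traj` with one frame
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nmod <- .validate_pdb_models(lines, path)
  if (nmod > 1L) stop(path, " has ", nmod, " models; use read_trajectory()")
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no coordinate records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  top <- .topology_from_bio3d(pdb)
  if (anyDuplicated(top$serial))
    stop("duplicate atom serials in ", path, ": ",
         paste(unique(top$serial[duplicated(top$serial)]), collapse = ", "))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  trajectory(top, array(xyz, c(nrow(top), 3, 1)), times = 0)
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL block. Atom ordering must be identical across
#' models; frame times are assigned from a declared interval (the file
#' format carries none).
#'
#' @param path path to a multi-model PDB file
#' @param frame_interval time between frames, ns (default 0.01 ns, the
#'   cadence that stores a 1000 ns run as 100,001 frames)
#' @param start_time time of the first frame, ns
#' @return a `chromo_traj`
#' @export
read_trajectory <- function(path, frame_interval = 0.01, start_time = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_models(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- .topology_from_bio3d(pdb)
  if (anyDuplicated(top$serial))
    stop("duplicate atom serials in ", path)
  nf <- nrow(pdb$xyz)
  coords <- array(0, c(nrow(top), 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
  trajectory(top, coords, times = start_time + (seq_len(nf) - 1) * frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' nm coordinates are converted to Angstrom and written in fixed PDB
#' columns, one MODEL block per frame.
#'
#' @param traj a `chromo_traj`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "chromo_traj"))
  top <- traj$topology
  nf <- n_frames(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3L * n_atoms(traj))
  for (i in seq_len(nf))
    xyz[i, ] <- as.numeric(t(traj$coords[, , i])) * 10  # nm -> A
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = rep("ATOM", nrow(top)),
                     eleno = top$serial, elety = top$name,
                     resid = top$resname, resno = top$resid,
                     chain = top$chain, elesy = top$element)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

# -- Region definitions -------------------------------------------------

#' Load interstrand exit-region definitions
#'
#' Each region is an interstrand gate defined by a pair of residue-range
#' segments (chain + inclusive residue interval). The config is a
#' whitespace-delimited table with a header line and columns
#' `region segment chain start end` (two rows, segments 1 and 2, per
#' region). The shipped default encodes the four-barrel-gate taxonomy:
#' Reg 1 = S7A-bulge (139-145) x S10, Reg 2 = S7B (146-153) x S10,
#' Reg 3 = S7A-bulge x S8, Reg 4 = S3 x S11, with S3/S8/S10/S11 residue
#' ranges shipped as editable defaults (they are a modelling choice, not
#' constants).
#'
#' @param path path to a region config file; default: the config shipped
#'   with the package, which matches the synthetic barrel template.
#' @return a named list of class `region_set`; each element has
#'   `seg1` and `seg2`, each a list with `chain`, `start`, `end`.
#' @export
load_regions <- function(path = system.file("extdata", "regions_default.cfg",
                                            package = "chromodyn")) {
  if (!file.exists(path)) stop("region config not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("region", "segment", "chain", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region config must have columns: ", paste(need, collapse = " "))
  regions <- list()
  for (lab in unique(tab$region)) {
    rows <- tab[tab$region == lab, , drop = FALSE]
    if (nrow(rows) != 2L || !setequal(rows$segment, c(1, 2)))
      stop("region '", lab, "' must have exactly segments 1 and 2")
    rows <- rows[order(rows$segment), , drop = FALSE]
    segs <- lapply(seq_len(2), function(i) {
      if (rows$start[i] > rows$end[i])
        stop("region '", lab, "' segment ", i, ": reversed interval ",
             rows$start[i], "-", rows$end[i])
      list(chain = rows$chain[i], start = rows$start[i], end = rows$end[i])
    })
    if (lab %in% names(regions)) stop("duplicate region label: ", lab)
    regions[[lab]] <- list(seg1 = segs[[1]], seg2 = segs[[2]])
  }
  structure(regions, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", length(x), "region(s)\n")
  for (lab in names(x)) {
    r <- x[[lab]]
    cat(sprintf("  %-8s %s %d-%d  x  %s %d-%d\n", lab,
                r$seg1$chain, r$seg1$start, r$seg1$end,
                r$seg2$chain, r$seg2$start, r$seg2$end))
  }
  invisible(x)
}

# Region gate centroid: mean CA position over both residue segments in
# one frame. Errors if any segment matches no CA atom.
.region_centroid <- function(traj, region, frame_idx) {
  xyz <- frame_coords(traj, frame_idx)
  top <- traj$topology
  pick <- function(seg) {
    idx <- which(top$name == "CA" & top$chain == seg$chain &
                 top$resid >= seg$start & top$resid <= seg$end)
    if (length(idx) == 0L)
      stop("region segment ", seg$chain, " ", seg$start, "-", seg$end,
           " matches no CA atoms in topology")
    idx
  }
  idx <- c(pick(region$seg1), pick(region$seg2))
  colMeans(xyz[idx, , drop = FALSE])
}

# -- Series container ---------------------------------------------------

#' Construct a per-frame series statistic
#'
#' @param times frame times, ns
#' @param values per-frame values (nm for distances/RMSD, degrees for
#'   angles)
#' @param label descriptive label
#' @return object of class `chromo_series`
#' @export
series_stat <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (!all(is.finite(values))) stop("non-finite values in series")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "chromo_series")
}

#' @export
print.chromo_series <- function(x, ...) {
  cat(sprintf("<chromo_series> '%s': %d points, mean %.4g (sd %.3g)\n",
              x$label, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Write a series as TSV (time_ns, value)
#' @param series a `chromo_series`
#' @param path output path
#' @param value_col name for the value column
#' @return invisibly, `path`
#' @export
write_series_tsv <- function(series, path, value_col = "value_nm") {
  df <- data.frame(time_ns = series$times, v = series$values)
  names(df)[2] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
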