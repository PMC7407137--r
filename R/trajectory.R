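#' Per-frame water z-coordinate slice of a trajectory
#'
#' Holds the only trajectory information the crossing counter needs: the
#' z-coordinate of every tracked water molecule at every saved frame, the
#' frame times, and (optionally) the periodic box height along z used to
#' recognise image wraps.
#'
#' @param z numeric matrix, frames x molecules, of z-coordinates in Angstrom.
#' @param times_ps strictly increasing per-frame times in picoseconds;
#'   defaults to `0, 10, 20, ...` (10 ps save interval).
#' @param molecule_ids stable molecule identifiers (column names of `z`).
#' @param box_z optional periodic box height along z in Angstrom.
#' @return An object of class `trajectory_slice`.
#' @export
trajectory_slice <- function(z, times_ps = NULL, molecule_ids = NULL,
                             box_z = NULL) {
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z)))
    stop("`z` must be finite for every molecule in every frame",
         call. = FALSE)
  n_frames <- nrow(z)
  if (is.null(times_ps)) times_ps <- (seq_len(n_frames) - 1) * 10
  if (length(times_ps) != n_frames)
    stop("`times_ps` length must equal the number of frames", call. = FALSE)
  if (n_frames > 1 && any(diff(times_ps) <= 0))
    stop("`times_ps` must be strictly increasing", call. = FALSE)
  if (is.null(molecule_ids)) {
    molecule_ids <- colnames(z)
    if (is.null(molecule_ids)) molecule_ids <- as.character(seq_len(ncol(z)))
  }
  if (anyDuplicated(molecule_ids))
    stop("`molecule_ids` must be unique", call. = FALSE)
  if (length(molecule_ids) != ncol(z))
    stop("`molecule_ids` length must equal the number of molecules",
         call. = FALSE)
  colnames(z) <- as.character(molecule_ids)
  if (!is.null(box_z) && (!is.numeric(box_z) || box_z <= 0))
    stop("`box_z` must be a positive scalar", call. = FALSE)
  structure(
    list(z = z, times_ps = as.numeric(times_ps),
         molecule_ids = as.character(molecule_ids),
         n_frames = n_frames, n_molecules = ncol(z), box_z = box_z),
    class = "trajectory_slice")
}

#' @export
print.trajectory_slice <- function(x, ...) {
  cat(sprintf("<trajectory_slice> %d frames x %d molecules, t = %g..%g ps%s\n",
              x$n_frames, x$n_molecules, x$times_ps[1],
              x$times_ps[x$n_frames],
              if (is.null(x$box_z)) "" else sprintf(", box_z = %g A", x$box_z)))
  invisible(x)
}

#' Membrane slab bounded by two z-planes
#'
#' The slab approximates the bilayer hydrophobic region: molecules with
#' `z > z_upper` are "above", `z < z_lower` are "below", and anything else
#' (boundary values included) is "inside".
#'
#' @param z_lower,z_upper slab bounds in Angstrom, `z_upper > z_lower`.
#' @return An object of class `membrane_slab`.
#' @export
membrane_slab <- function(z_lower, z_upper) {
  if (!is.numeric(z_lower) || !is.numeric(z_upper) ||
      length(z_lower) != 1L || length(z_upper) != 1L)
    stop("slab bounds must be scalars", call. = FALSE)
  if (!(z_upper > z_lower))
    stop("`z_upper` must exceed `z_lower`", call. = FALSE)
  structure(list(z_lower = z_lower, z_upper = z_upper),
            class = "membrane_slab")
}

#' @export
print.membrane_slab <- function(x, ...) {
  cat(sprintf("<membrane_slab> z in [%g, %g] A (thickness %g A)\n",
              x$z_lower, x$z_upper, x$z_upper - x$z_lower))
  invisible(x)
}

#' Infer membrane slab bounds from lipid reference atoms
#'
#' Places the slab planes at the time-averaged mean z of each leaflet's
#' reference atoms (typically lipid phosphates), splitting leaflets by the
#' per-frame median z — the standard convention when the bilayer midplane is
#' not known in advance.
#'
#' @param lipid_z numeric matrix, frames x reference atoms, of z-coordinates
#'   in Angstrom (a vector is treated as a single frame).
#' @return A [membrane_slab()].
#' @export
infer_slab <- function(lipid_z) {
  if (is.null(dim(lipid_z))) lipid_z <- matrix(lipid_z, nrow = 1)
  lipid_z <- as.matrix(lipid_z)
  if (ncol(lipid_z) < 2L)
    stop("need at least one reference atom per leaflet", call. = FALSE)
  if (anyNA(lipid_z) || any(!is.finite(lipid_z)))
    stop("lipid reference z-coordinates must be finite", call. = FALSE)
  per_frame <- t(apply(lipid_z, 1, function(zrow) {
    mid <- median(zrow)
    up <- zrow[zrow > mid]
    lo <- zrow[zrow < mid]
    if (length(up) == 0L || length(lo) == 0L)
      stop("degenerate leaflet: all reference atoms on one side of the ",
           "median in some frame", call. = FALSE)
    c(lower = mean(lo), upper = mean(up))
  }))
  membrane_slab(mean(per_frame[, "lower"]), mean(per_frame[, "upper"]))
}

#' Write / read a trajectory slice as TSV plus JSON sidecar
#'
#' Long format `frame,molecule_id,z` with a sidecar (`<path>.json`) holding
#' frame times, box height and any schedule/slab metadata.
#'
#' @param traj a [trajectory_slice()].
#' @param path TSV file path.
#' @param meta optional metadata list stored in the sidecar.
#' @return `write_trajectory_tsv()` returns `path` invisibly;
#'   `read_trajectory_tsv()` returns a `trajectory_slice`.
#' @export
write_trajectory_tsv <- function(traj, path, meta = list()) {
  stopifnot(inherits(traj, "trajectory_slice"))
  df <- data.frame(
    frame = rep(seq_len(traj$n_frames), times = traj$n_molecules),
    molecule_id = rep(traj$molecule_ids, each = traj$n_frames),
    z = as.vector(traj$z))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(times_ps = traj$times_ps, meta = meta)
  if (!is.null(traj$box_z)) side$box_z <- traj$box_z
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- read.delim(path)
  if (!all(c("frame", "molecule_id", "z") %in% names(df)))
    stop("trajectory TSV must have columns frame,molecule_id,z",
         call. = FALSE)
  ids <- unique(df$molecule_id)
  frames <- sort(unique(df$frame))
  z <- matrix(NA_real_, length(frames), length(ids),
              dimnames = list(NULL, as.character(ids)))
  z[cbind(match(df$frame, frames), match(df$molecule_id, ids))] <- df$z
  if (anyNA(z))
    stop("molecule absent from a frame in trajectory TSV", call. = FALSE)
  times_ps <- NULL
  box_z <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    times_ps <- side$times_ps
    box_z <- side$box_z
  }
  trajectory_slice(z, times_ps = times_ps,
                   molecule_ids = as.character(ids), box_z = box_z)
}

parse_selection <- function(sel, what) {
  # minimal "resname A B ... [and] name X Y ..." parser; also accepts a
  # ready-made list(resid = ..., elety = ...)
  if (is.list(sel)) return(sel)
  toks <- strsplit(trimws(sel), "\\s+")[[1]]
  toks <- toks[toks != "and"]
  out <- list()
  key <- NULL
  for (tk in toks) {
    if (tk %in% c("resname", "resid")) key <- "resid"
    else if (tk %in% c("name", "elety")) key <- "elety"
    else if (is.null(key))
      stop(sprintf("cannot parse %s selection '%s'", what, sel),
           call. = FALSE)
    else out[[key]] <- c(out[[key]], tk)
  }
  if (length(out) == 0L)
    stop(sprintf("empty %s selection '%s'", what, sel), call. = FALSE)
  out
}

select_atoms <- function(atom, sel, what) {
  keep <- rep(TRUE, nrow(atom))
  if (!is.null(sel$resid)) keep <- keep & atom$resid %in% sel$resid
  if (!is.null(sel$elety)) keep <- keep & atom$elety %in% sel$elety
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("%s selection matched no atoms (%s)", what,
                 paste(unlist(sel), collapse = " ")), call. = FALSE)
  idx
}

#' Read a standard MD trajectory into a z-coordinate slice
#'
#' Extracts per-frame water-oxygen z-coordinates and lipid-phosphate
#' z-coordinates from a topology (multi-model PDB) plus optional separate
#' coordinate file (DCD), using the bio3d reader. Selections are
#' `"resname ... name ..."` strings or `list(resid=, elety=)`.
#'
#' @param topology_path PDB file; if `coordinates_path` is `NULL` its MODEL
#'   records provide the frames.
#' @param coordinates_path optional DCD trajectory file.
#' @param water_selection selection for water oxygens (default matches
#'   common TIP3P/SPC water naming).
#' @param lipid_selection selection for lipid reference atoms (default
#'   phosphate P).
#' @param dt_ps frame save interval in picoseconds (default 10).
#' @param box_z optional periodic box height along z in Angstrom.
#' @return A list with `traj` (a [trajectory_slice()] of water oxygens) and
#'   `lipid_z` (frames x atoms matrix for [infer_slab()]).
#' @export
read_standard_trajectory <- function(topology_path, coordinates_path = NULL,
                                     water_selection =
                                       "resname TIP3 TIP3P HOH SOL WAT name OH2 OW O",
                                     lipid_selection = "name P P8",
                                     dt_ps = 10, box_z = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB/DCD trajectories requires the bio3d package",
         call. = FALSE)
  if (!file.exists(topology_path))
    stop("topology file not found: ", topology_path, call. = FALSE)
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE)
  if (is.null(coordinates_path)) {
    xyz <- pdb$xyz
  } else {
    if (!file.exists(coordinates_path))
      stop("coordinate file not found: ", coordinates_path, call. = FALSE)
    xyz <- bio3d::read.dcd(coordinates_path)
    if (ncol(xyz) != 3L * nrow(pdb$atom))
      stop("topology and coordinates disagree on atom count", call. = FALSE)
  }
  xyz <- as.matrix(xyz)
  wsel <- parse_selection(water_selection, "water")
  lsel <- parse_selection(lipid_selection, "lipid")
  widx <- select_atoms(pdb$atom, wsel, "water")
  lidx <- select_atoms(pdb$atom, lsel, "lipid")
  zcol <- function(i) xyz[, 3L * i, drop = FALSE]
  wz <- do.call(cbind, lapply(widx, zcol))
  lz <- do.call(cbind, lapply(lidx, zcol))
  ids <- paste0(pdb$atom$resid[widx], pdb$atom$resno[widx])
  if (anyDuplicated(ids)) ids <- paste0(ids, "_", pdb$atom$eleno[widx])
  traj <- trajectory_slice(wz, times_ps = (seq_len(nrow(wz)) - 1) * dt_ps,
                           molecule_ids = ids, box_z = box_z)
  list(traj = traj, lipid_z = lz)
}
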