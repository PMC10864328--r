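#' Extract bond unit vectors from an MD trajectory
#'
#' Resolves labelled heavy-atom/light-atom pairs (e.g. backbone N and its
#' amide H) in a topology, and returns the per-frame unit vectors pointing
#' from the heavy to the light atom. The intra-pair displacement is always
#' taken with the minimum-image convention under the (orthorhombic) periodic
#' box, so bonds straddling a box edge are handled correctly.
#'
#' Supported inputs are multi-model PDB files (topology + frames in one
#' file) or a DCD trajectory with a PDB topology, both read through
#' \pkg{bio3d}, plus the package's own plain-text vector tables via
#' [read_vector_table()]. XTC/TRR/GRO files are not supported; convert them
#' with standard MD tooling first.
#'
#' @param trajectory_path multi-model PDB or DCD file with the coordinates.
#' @param topology_path PDB topology; may be omitted when `trajectory_path`
#'   is itself a (multi-model) PDB.
#' @param pairs data frame describing the bonds, either with columns
#'   `label`, `resno`, `atom_heavy`, `atom_light` (atom names resolved per
#'   residue number) or with columns `label`, `idx_heavy`, `idx_light`
#'   (1-based atom indices into the topology). Missing `atom_heavy` /
#'   `atom_light` default to `"N"` / `"H"`.
#' @param dt frame spacing in ps (PDB/DCD files carry no reliable time
#'   axis). Default 1.
#' @param box optional numeric length-3 orthorhombic box (same length unit
#'   as the coordinates) used for the minimum-image displacement; when
#'   `NULL`, the first `CRYST1` record of the trajectory/topology is used if
#'   present, otherwise no periodic wrapping is applied.
#' @return A [vector_trajectory()].
#' @export
extract_bond_vectors <- function(trajectory_path, topology_path = NULL,
                                 pairs, dt = 1, box = NULL) {
  if (is.null(topology_path)) topology_path <- trajectory_path
  top <- bio3d::read.pdb(topology_path, verbose = FALSE)
  is_dcd <- grepl("\\.dcd$", trajectory_path, ignore.case = TRUE)
  if (is_dcd) {
    xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  } else {
    traj <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
    xyz <- traj$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(top$atom))
    stop("trajectory and topology disagree on the number of atoms")
  if (is.null(box)) box <- .read_cryst1(if (is_dcd) topology_path else trajectory_path)

  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$label)) stop("'pairs' must have a 'label' column")
  if (!is.null(pairs$idx_heavy) && !is.null(pairs$idx_light)) {
    ih <- as.integer(pairs$idx_heavy); il <- as.integer(pairs$idx_light)
    nat <- nrow(top$atom)
    if (any(ih < 1L | ih > nat) || any(il < 1L | il > nat))
      stop("atom index in 'pairs' outside the topology")
  } else {
    if (is.null(pairs$resno)) stop("'pairs' needs either resno/atom columns or idx columns")
    if (is.null(pairs$atom_heavy)) pairs$atom_heavy <- "N"
    if (is.null(pairs$atom_light)) pairs$atom_light <- "H"
    find_atom <- function(resno, elety, lab) {
      hit <- which(top$atom$resno == resno & trimws(top$atom$elety) == elety)
      if (length(hit) != 1L)
        stop(sprintf("selection error for site '%s': atom '%s' in residue %d %s",
                     lab, elety, resno,
                     if (length(hit)) "is ambiguous" else "not found"))
      hit
    }
    ih <- mapply(find_atom, pairs$resno, pairs$atom_heavy, pairs$label)
    il <- mapply(find_atom, pairs$resno, pairs$atom_light, pairs$label)
  }

  n <- nrow(xyz)
  vecs <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- xyz[, (3L * ih[k] - 2L):(3L * ih[k]), drop = FALSE]
    b <- xyz[, (3L * il[k] - 2L):(3L * il[k]), drop = FALSE]
    d <- b - a
    if (!is.null(box)) d <- minimum_image(d, box)
    nrm <- sqrt(rowSums(d^2))
    if (any(nrm == 0))
      stop(sprintf("zero-length bond for site '%s'", pairs$label[k]))
    d / nrm
  })
  names(vecs) <- pairs$label
  vector_trajectory(dt * (seq_len(n) - 1L), vecs, pairs$label, normalize = TRUE)
}

#' Minimum-image displacement
#'
#' Wraps displacement vectors into the primary image of an orthorhombic box.
#'
#' @param d numeric vector of length 3 or an `n x 3` matrix of displacements.
#' @param box numeric length-3 box edge lengths (same units as `d`).
#' @return Wrapped displacements, same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("'box' must be 3 positive edge lengths")
  vec <- is.null(dim(d))
  if (vec) d <- matrix(d, ncol = 3L)
  for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  if (vec) drop(d) else d
}

.read_cryst1 <- function(path) {
  if (!grepl("\\.pdb$", path, ignore.case = TRUE)) return(NULL)
  lines <- readLines(path, n = 500L, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) return(NULL)
  f <- suppressWarnings(as.numeric(strsplit(trimws(substr(cr[1L], 7, 54)), "\\s+")[[1]]))
  if (length(f) < 6 || any(is.na(f))) return(NULL)
  if (any(abs(f[4:6] - 90) > 1e-6))
    stop("non-orthorhombic box in CRYST1; supply 'box' explicitly or pre-wrap the trajectory")
  f[1:3]
}
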