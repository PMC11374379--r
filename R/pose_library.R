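# Persistence and sampling of pre-computed pairwise docking landscapes:
# the ranked low-energy matches for each ordered protein pair, stored in
# a diff-able TSV format and drawn from uniformly during MC runs.

#' Construct a pose list
#'
#' Ranked low-energy docking matches for one ordered (ligand, receptor)
#' pair. Energies must be sorted ascending; rotations must be orthonormal
#' with determinant +1.
#'
#' @param ligand_label,receptor_label Non-empty identifiers.
#' @param params The [dock_params()] the list was computed with.
#' @param energies Numeric vector (ascending).
#' @param rotations K x 9 matrix, each row a 3x3 rotation stored row-major.
#' @param translations K x 3 matrix of ligand-center offsets relative to
#'   the receptor center, Angstrom.
#' @return Object of class `pose_list`.
#' @export
pose_list <- function(ligand_label, receptor_label, params,
                      energies, rotations, translations) {
  stopifnot(nzchar(ligand_label), nzchar(receptor_label))
  k <- length(energies)
  if (k < 1L) stop("pose list must be non-empty")
  rotations <- matrix(rotations, k, 9)
  translations <- matrix(translations, k, 3)
  if (is.unsorted(energies)) stop("pose energies must be sorted ascending")
  if (!all(is.finite(energies))) stop("pose energies must be finite")
  for (i in c(1L, k)) {  # spot-check ends; full check on load
    m <- matrix(rotations[i, ], 3, 3, byrow = TRUE)
    if (max(abs(crossprod(m) - diag(3))) > 1e-6 || abs(det(m) - 1) > 1e-6) {
      stop("rotation ", i, " is not orthonormal with determinant +1")
    }
  }
  structure(
    list(
      ligand_label = ligand_label, receptor_label = receptor_label,
      params = params, energies = as.numeric(energies),
      rotations = rotations, translations = translations
    ),
    class = "pose_list"
  )
}

#' @export
print.pose_list <- function(x, ...) {
  cat(sprintf(
    "<pose_list> %s -> %s: %d poses, energy range [%.3f, %.3f]\n",
    x$ligand_label, x$receptor_label, length(x$energies),
    min(x$energies), max(x$energies)
  ))
  invisible(x)
}

#' Number of poses in a pose list
#' @param x A `pose_list`.
#' @return Integer count.
#' @export
n_poses <- function(x) length(x$energies)

#' Extract one pose from a pose list
#'
#' @param pl A `pose_list`.
#' @param i Rank index.
#' @return List with `rotation` (3x3), `translation` (3-vector),
#'   `energy`, `index`.
#' @export
get_pose <- function(pl, i) {
  stopifnot(i >= 1, i <= n_poses(pl))
  list(
    rotation = matrix(pl$rotations[i, ], 3, 3, byrow = TRUE),
    translation = as.numeric(pl$translations[i, ]),
    energy = pl$energies[i],
    index = as.integer(i)
  )
}

#' Save a pose list to a TSV file
#'
#' Format: '#'-prefixed header lines (format version, labels, docking
#' parameters, pose count), then one row per pose with columns
#' `rank  energy  r11..r33 (row-major)  tx ty tz` at full precision.
#'
#' @param pl A `pose_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_poselist <- function(pl, path) {
  stopifnot(inherits(pl, "pose_list"))
  p <- pl$params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# crowdhop-poselist v1",
    sprintf("# ligand\t%s", pl$ligand_label),
    sprintf("# receptor\t%s", pl$receptor_label),
    sprintf("# grid_step\t%.17g", p$grid_step),
    sprintf("# repulsion\t%.17g", p$repulsion),
    sprintf("# rotation_interval\t%.17g", p$rotation_interval),
    sprintf("# top_k\t%d", p$top_k),
    sprintf("# surface_thickness\t%d", p$surface_thickness),
    sprintf("# n_poses\t%d", n_poses(pl)),
    paste(c("rank", "energy", paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
            "tx", "ty", "tz"), collapse = "\t")
  ), con)
  tab <- cbind(seq_len(n_poses(pl)), pl$energies, pl$rotations, pl$translations)
  utils::write.table(
    format(tab, digits = 17, scientific = FALSE, trim = TRUE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Load a pose list from a TSV file
#'
#' Validates the header, energy sortedness and rotation orthonormality;
#' a truncated or out-of-order file raises an error.
#'
#' @param path Path to a file written by [save_poselist()].
#' @return A `pose_list`.
#' @export
load_poselist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) < 1L || !grepl("^# crowdhop-poselist v1", hdr[1])) {
    stop("not a crowdhop pose-library file: ", path)
  }
  hval <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    if (length(ln) != 1L) stop("malformed header: missing ", key)
    sub(paste0("^# ", key, "\t"), "", ln)
  }
  n_declared <- as.integer(hval("n_poses"))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1L]  # drop column-name row
  if (length(body) != n_declared) {
    stop("truncated pose-library file: declared ", n_declared,
         " poses, found ", length(body))
  }
  tab <- utils::read.table(text = body, sep = "\t")
  if (ncol(tab) != 14L) stop("malformed pose row(s) in ", path)
  energies <- tab[[2]]
  if (is.unsorted(energies)) stop("pose energies out of order in ", path)
  rotations <- as.matrix(tab[, 3:11])
  for (i in seq_len(nrow(rotations))) {
    m <- matrix(rotations[i, ], 3, 3, byrow = TRUE)
    if (max(abs(crossprod(m) - diag(3))) > 1e-6 || abs(det(m) - 1) > 1e-6) {
      stop("non-orthonormal rotation at rank ", i, " in ", path)
    }
  }
  params <- dock_params(
    grid_step = as.numeric(hval("grid_step")),
    repulsion = as.numeric(hval("repulsion")),
    rotation_interval = as.numeric(hval("rotation_interval")),
    top_k = as.integer(hval("top_k")),
    surface_thickness = as.integer(hval("surface_thickness"))
  )
  pose_list(
    ligand_label = hval("ligand"), receptor_label = hval("receptor"),
    params = params, energies = energies,
    rotations = rotations, translations = as.matrix(tab[, 12:14])
  )
}

#' Draw a pose uniformly at random from a pose list
#'
#' Uses the current R random number stream (seed upstream with
#' `set.seed()` for reproducibility).
#'
#' @param pl A `pose_list`.
#' @return As [get_pose()]: `rotation`, `translation`, `energy`, `index`.
#' @export
sample_pose <- function(pl) {
  get_pose(pl, sample.int(n_poses(pl), 1L))
}

#' Assemble a landscape set from pose lists
#'
#' @param pose_lists List of `pose_list` objects covering every ordered
#'   (ligand, receptor) type pair of a simulated system.
#' @return Object of class `landscape_set` keyed by
#'   `"<ligand>|<receptor>"`.
#' @export
landscape_set <- function(pose_lists) {
  keys <- vapply(pose_lists, function(pl) {
    stopifnot(inherits(pl, "pose_list"))
    paste(pl$ligand_label, pl$receptor_label, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate (ligand, receptor) pair")
  structure(stats::setNames(pose_lists, keys), class = "landscape_set")
}

#' Look up the pose list for an ordered type pair
#'
#' @param ls A `landscape_set`.
#' @param ligand_label,receptor_label Type labels.
#' @return A `pose_list`.
#' @export
get_landscape <- function(ls, ligand_label, receptor_label) {
  key <- paste(ligand_label, receptor_label, sep = "|")
  pl <- ls[[key]]
  if (is.null(pl)) stop("no pose library for pair ", key)
  pl
}
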