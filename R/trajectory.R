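# Trajectory container and plain-text I/O (multi-frame XYZ, minimal PDB).

#' Coordinate trajectory
#'
#' @param coords Numeric array of dimension `n_atoms x 3 x n_frames`
#'   (Angstrom), or a list of `n_atoms x 3` matrices.
#' @param dt Frame spacing in ps.
#' @param atoms Data frame of atom metadata with columns `name`, `resid`,
#'   `chain` (chain doubles as the subunit tag).
#' @param box Optional orthorhombic box lengths, numeric length 3 (Angstrom).
#' @param metadata Named provenance list.
#' @return A `trajectory`.
#' @export
trajectory <- function(coords, dt = 1, atoms = NULL, box = NULL,
                       metadata = list()) {
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  n <- dim(coords)[1]
  if (is.null(atoms))
    atoms <- data.frame(name = rep("X", n), resid = seq_len(n),
                        chain = rep("A", n), stringsAsFactors = FALSE)
  if (nrow(atoms) != n) stop("atom metadata rows must match atom count")
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(list(coords = coords, dt = dt, atoms = atoms, box = box,
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames, dt = %.4g ps%s\n",
              dim(x$coords)[1], dim(x$coords)[3], x$dt,
              if (is.null(x$box)) "" else
                sprintf(", box %s A", paste(signif(x$box, 4), collapse = "x"))))
  invisible(x)
}

n_frames <- function(t) dim(t$coords)[3]
n_atoms <- function(t) dim(t$coords)[1]

#' Resolve an atom selection
#'
#' Selections address atoms by any combination of chain/subunit tag,
#' residue index range and atom name; `NULL` components match everything.
#' There is deliberately no general selection language.
#'
#' @param t A [trajectory()].
#' @param chain Chain/subunit tag(s), or `NULL`.
#' @param resid Residue indices (vector or range), or `NULL`.
#' @param name Atom name(s), or `NULL`.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(t, chain = NULL, resid = NULL, name = NULL) {
  stopifnot(inherits(t, "trajectory"))
  keep <- rep(TRUE, n_atoms(t))
  if (!is.null(chain)) {
    if (!all(chain %in% t$atoms$chain))
      stop("unknown chain tag(s) ", paste(setdiff(chain, t$atoms$chain), collapse = ", "),
           "; available: ", paste(unique(t$atoms$chain), collapse = ", "))
    keep <- keep & t$atoms$chain %in% chain
  }
  if (!is.null(resid)) keep <- keep & t$atoms$resid %in% resid
  if (!is.null(name)) {
    if (!all(name %in% t$atoms$name))
      stop("unknown atom name(s) ", paste(setdiff(name, t$atoms$name), collapse = ", "),
           "; available: ", paste(unique(t$atoms$name), collapse = ", "))
    keep <- keep & t$atoms$name %in% name
  }
  idx <- which(keep)
  if (length(idx) == 0) stop("selection matches no atoms")
  idx
}

#' Read/write multi-frame XYZ
#'
#' Standard XYZ: per frame an atom count line, a comment line (the writer
#' stores `t=<ps>` there), then `name x y z` rows. All frames must have the
#' same atom count.
#'
#' @param path File path.
#' @param dt Frame spacing in ps used if the comment lines carry no times.
#' @return `read_xyz()` returns a [trajectory()].
#' @export
read_xyz <- function(path, dt = 1) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  names_first <- NULL
  times <- numeric(0)
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na)) stop("malformed XYZ: expected atom count at line ", pos)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("t=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    rows <- lines[(pos + 2L):(pos + 1L + na)]
    fields <- strsplit(trimws(rows), "\\s+")
    nm <- vapply(fields, `[[`, character(1), 1)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (is.null(names_first)) names_first <- nm
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + na
  }
  if (length(frames) == 0) stop("no frames in ", path)
  if (length(times) > 1 && !anyNA(times)) dt <- diff(times)[1]
  trajectory(frames, dt = dt,
             atoms = data.frame(name = names_first,
                                resid = seq_along(names_first),
                                chain = rep("A", length(names_first)),
                                stringsAsFactors = FALSE))
}

#' @rdname read_xyz
#' @param t A [trajectory()].
#' @export
write_xyz <- function(t, path) {
  stopifnot(inherits(t, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  na <- n_atoms(t)
  for (f in seq_len(n_frames(t))) {
    writeLines(as.character(na), con)
    writeLines(sprintf("t=%.6g", (f - 1) * t$dt), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", t$atoms$name,
                       t$coords[, 1, f], t$coords[, 2, f], t$coords[, 3, f]),
               con)
  }
  invisible(path)
}

#' Read atom metadata (and one frame) from a PDB file
#'
#' Minimal fixed-column parser of `ATOM`/`HETATM` records, enough to attach
#' residue and chain/subunit metadata to a trajectory. Chain identifiers
#' A/B/C are conventionally the alpha/beta/gamma subunits of a
#' heterotrimeric channel.
#'
#' @param path PDB file.
#' @return A list with `atoms` (data frame: name, resid, chain, resname)
#'   and `coords` (N x 3 matrix).
#' @export
read_pdb_metadata <- function(path) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    name = trimws(substr(rec, 13, 16)),
    resname = trimws(substr(rec, 18, 20)),
    chain = trimws(substr(rec, 22, 22)),
    resid = as.integer(trimws(substr(rec, 23, 26))),
    stringsAsFactors = FALSE)
  coords <- cbind(as.numeric(substr(rec, 31, 38)),
                  as.numeric(substr(rec, 39, 46)),
                  as.numeric(substr(rec, 47, 54)))
  list(atoms = atoms, coords = coords)
}

#' Read/write an energy time series CSV
#'
#' Format: columns `t_ps,total,elec,vdw` (kcal/mol).
#'
#' @param path File path.
#' @return `read_energy_series()` returns a data frame.
#' @export
read_energy_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_ps", "total", "elec", "vdw")
  if (!all(need %in% names(df)))
    stop("energy CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_energy_series
#' @param df Data frame with columns `t_ps,total,elec,vdw`.
#' @export
write_energy_series <- function(df, path) {
  utils::write.csv(df[, c("t_ps", "total", "elec", "vdw")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Ligand RMSD time series
#'
#' @param times Times in ns.
#' @param values RMSD values in Angstrom (>= 0).
#' @param align_selection,measure_selection Free-form descriptors of the
#'   atom selections used for superposition and measurement.
#' @param metadata Named provenance list.
#' @return An `rmsd_series`.
#' @export
rmsd_series <- function(times, values, align_selection = NULL,
                        measure_selection = NULL, metadata = list()) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (any(values < 0)) stop("RMSD values must be >= 0")
  structure(list(times = times, values = values,
                 align_selection = align_selection,
                 measure_selection = measure_selection,
                 metadata = metadata),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %d frames, %.4g-%.4g ns, mean %.3f A\n",
              length(x$values), min(x$times), max(x$times), mean(x$values)))
  invisible(x)
}
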