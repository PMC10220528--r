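#' Read a PDB topology and its first frame
#'
#' Parses ATOM/HETATM fixed-column records, an optional CRYST1 box and
#' CONECT bond records. Only orthorhombic boxes are supported; a CRYST1 with
#' any cell angle different from 90 degrees is rejected. Roles are left
#' unassigned (see [assign_roles()]).
#'
#' @param path path to a PDB file.
#' @return `list(topology = hs_topology, frame = hs_frame)`; `frame$box` is
#'   NULL when the file has no CRYST1 record.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB file: ", path)
  box <- NULL
  name <- character(); element <- character()
  resid <- integer(); resname <- character()
  xyz <- list(); bonds <- list()
  serial_map <- integer()  # PDB serial -> atom row
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    rec <- substr(ln, 1, 6)
    if (rec == "CRYST1") {
      abc <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                           substr(ln, 25, 33))))
      ang <- suppressWarnings(as.numeric(c(substr(ln, 34, 40), substr(ln, 41, 47),
                                           substr(ln, 48, 54))))
      if (any(is.na(abc))) stop(sprintf("line %d: malformed CRYST1 record", i))
      if (any(is.na(ang)) || any(abs(ang - 90) > 1e-3))
        stop(sprintf("line %d: only orthorhombic boxes are supported (angles must be 90)", i))
      box <- abc
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (nchar(ln) < 54) stop(sprintf("line %d: truncated %s record", i, trimws(rec)))
      co <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                          substr(ln, 47, 54))))
      if (any(is.na(co)))
        stop(sprintf("line %d: missing or malformed coordinates", i))
      serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
      nm <- trimws(substr(ln, 13, 16))
      rn <- trimws(substr(ln, 18, 20))
      ri <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      if (is.na(ri)) stop(sprintf("line %d: malformed residue number", i))
      el <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
      if (el == "") el <- toupper(substr(gsub("[^A-Za-z].*", "", nm), 1, 1))
      name <- c(name, nm); element <- c(element, el)
      resid <- c(resid, ri); resname <- c(resname, rn)
      xyz[[length(xyz) + 1L]] <- co
      if (!is.na(serial)) serial_map[as.character(serial)] <- length(xyz)
    } else if (rec == "CONECT") {
      flds <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                   "\\s+")[[1]]))
      if (length(flds) >= 2 && !any(is.na(flds))) {
        a <- serial_map[as.character(flds[1])]
        for (b0 in flds[-1]) {
          b <- serial_map[as.character(b0)]
          if (!is.na(a) && !is.na(b) && a < b)
            bonds[[length(bonds) + 1L]] <- c(a, b)
        }
      }
    }
  }
  if (!length(xyz)) stop("no ATOM/HETATM records in ", path)
  coords <- do.call(rbind, xyz)
  atoms <- data.frame(name = name, element = element, resid = resid,
                      resname = resname, stringsAsFactors = FALSE)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  topo <- hs_topology(atoms, bonds, n_residues_polymer = max(1L, length(unique(resid))))
  list(topology = topo, frame = hs_frame(coords, box = box))
}

#' Write a topology + frame as PDB
#'
#' @param topology an [hs_topology()].
#' @param frame an [hs_frame()]; a CRYST1 record is emitted when `frame$box`
#'   is set.
#' @param path output path.
#' @param write_conect write CONECT records for the topology bonds.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, frame, path, write_conect = TRUE) {
  atoms <- topology$atoms
  co <- frame$coords
  if (nrow(co) != nrow(atoms)) stop("frame/topology atom count mismatch")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(frame$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       frame$box[1], frame$box[2], frame$box[3], 90, 90, 90), con)
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$name[i]
    nm_field <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
    writeLines(sprintf("ATOM  %5d %s %-3s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       i %% 100000, nm_field, substr(atoms$resname[i], 1, 3),
                       atoms$resid[i] %% 10000, co[i, 1], co[i, 2], co[i, 3],
                       1, 0, substr(atoms$element[i], 1, 2)), con)
  }
  if (write_conect && nrow(topology$bonds) > 0) {
    for (k in seq_len(nrow(topology$bonds))) {
      b <- topology$bonds[k, ]
      writeLines(sprintf("CONECT%5d%5d", b[1], b[2]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ layout repeated per frame: atom-count line, comment line,
#' then `element x y z` rows. All frames must share one atom count.
#'
#' @param path path to the XYZ file.
#' @param box orthorhombic box (length 3, Angstrom) applied to every frame,
#'   or NULL.
#' @return list of [hs_frame()] objects in file order.
#' @export
read_xyz_multi <- function(path, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  frames <- list(); i <- 1L; n_atoms <- NA_integer_; t <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(n) || n < 1) stop(sprintf("line %d: expected an atom-count line", i))
    if (is.na(n_atoms)) n_atoms <- n
    else if (n != n_atoms)
      stop(sprintf("line %d: atom count %d differs from first frame's %d", i, n, n_atoms))
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated frame starting at line %d", i))
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    co <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      if (length(rows[[k]]) < 4)
        stop(sprintf("line %d: expected 'element x y z'", i + 1L + k))
      co[k, ] <- as.numeric(rows[[k]][2:4])
    }
    if (any(is.na(co))) stop(sprintf("malformed coordinates in frame at line %d", i))
    frames[[length(frames) + 1L]] <- hs_frame(co, box = box, time = t)
    t <- t + 1
    i <- i + 2L + n
  }
  frames
}

#' Write frames as multi-frame XYZ
#'
#' Coordinates are printed with 6 decimals, so a read/write round trip is
#' exact at that precision.
#'
#' @param frames list of [hs_frame()] (or a single frame).
#' @param path output path.
#' @param elements per-atom element symbols; defaults to "C".
#' @return `path`, invisibly.
#' @export
write_xyz_multi <- function(frames, path, elements = NULL) {
  if (inherits(frames, "hs_frame")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$coords)
    el <- if (is.null(elements)) rep("C", n) else elements
    writeLines(as.character(n), con)
    writeLines(sprintf("frame t=%g", f$time), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", el,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  invisible(path)
}
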