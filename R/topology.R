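#' Molecular topology
#'
#' Ordered atom table plus bond list and the polymer degree of polymerization.
#' Atom roles drive every analysis in the package: the chain metrics use
#' `backbone` and `terminal_carbon`, the solvation RDF uses `terminal_carbon`
#' vs `water_oxygen`, and the hydrogen-bond module uses the oxygen classes.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (1-based residue index) and `resname`.
#' @param bonds integer matrix with two columns, one row per bond
#'   (unordered atom-index pairs), or NULL for no bonds.
#' @param n_residues_polymer degree of polymerization N (>= 1).
#' @param roles optional logical matrix `nrow(atoms)` x 7 with columns
#'   `backbone`, `sidechain`, `terminal_carbon`, `mainchain_oxygen`,
#'   `sidechain_oxygen`, `water_oxygen`, `water_hydrogen`. Defaults to all
#'   FALSE (roles unassigned).
#' @return an object of class `hs_topology`.
#' @seealso [assign_roles()], [select_role()]
#' @export
hs_topology <- function(atoms, bonds = NULL, n_residues_polymer = 1L, roles = NULL) {
  required <- c("name", "element", "resid", "resname")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("atoms must be a data.frame with columns name, element, resid, resname")
  n <- nrow(atoms)
  if (n < 1) stop("topology needs at least one atom")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1 | bonds > n)) stop("bond references a nonexistent atom index")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
  }
  if (is.null(roles)) {
    roles <- matrix(FALSE, n, length(.hs_roles), dimnames = list(NULL, .hs_roles))
  }
  if (!is.matrix(roles) || nrow(roles) != n || !all(.hs_roles %in% colnames(roles)))
    stop("roles must be a logical matrix with one row per atom and the 7 role columns")
  roles <- roles[, .hs_roles, drop = FALSE]
  n_residues_polymer <- as.integer(n_residues_polymer)
  if (is.na(n_residues_polymer) || n_residues_polymer < 1)
    stop("n_residues_polymer must be >= 1")
  topo <- structure(
    list(atoms = atoms, bonds = bonds, roles = roles,
         n_residues_polymer = n_residues_polymer),
    class = "hs_topology")
  validate_roles(topo)
  topo
}

validate_roles <- function(topology) {
  roles <- topology$roles
  water <- roles[, "water_oxygen"] | roles[, "water_hydrogen"]
  polymer <- rowSums(roles[, .hs_polymer_roles, drop = FALSE]) > 0
  if (any(water & polymer))
    stop("water roles and polymer roles are mutually exclusive per atom")
  if (any(roles[, "terminal_carbon"] & !roles[, "sidechain"]))
    stop("terminal_carbon atoms must also be tagged sidechain")
  if (any(roles[, "mainchain_oxygen"] & roles[, "sidechain_oxygen"]))
    stop("mainchain_oxygen and sidechain_oxygen are mutually exclusive")
  invisible(topology)
}

#' @export
print.hs_topology <- function(x, ...) {
  cat(sprintf("<hs_topology> %d atoms, %d bonds, N = %d polymer residues\n",
              nrow(x$atoms), nrow(x$bonds), x$n_residues_polymer))
  counts <- colSums(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(counts)[counts > 0],
                                counts[counts > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' Single trajectory frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param box orthorhombic box edge lengths (Angstrom, length 3), or NULL if
#'   unknown; analyses requiring periodic boundaries reject a NULL box.
#' @param time frame time in ps.
#' @return an object of class `hs_frame`.
#' @export
hs_frame <- function(coords, box = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || !is.numeric(coords)) stop("coords must be an n x 3 numeric matrix")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive orthorhombic edge lengths")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "hs_frame")
}

#' Multi-frame trajectory
#'
#' @param topology an [hs_topology()].
#' @param frames list of [hs_frame()] objects with the same atom count as the
#'   topology.
#' @param temperature temperature label in K (NA if not applicable).
#' @return an object of class `hs_trajectory`.
#' @export
hs_trajectory <- function(topology, frames, temperature = NA_real_) {
  if (!inherits(topology, "hs_topology")) stop("topology must be an hs_topology")
  if (!is.list(frames) || length(frames) < 1) stop("trajectory needs >= 1 frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "hs_frame")) stop("frames must be hs_frame objects")
    if (nrow(frames[[i]]$coords) != n)
      stop(sprintf("frame %d has %d atoms; topology has %d",
                   i, nrow(frames[[i]]$coords), n))
  }
  structure(list(topology = topology, frames = frames,
                 temperature = as.numeric(temperature)),
            class = "hs_trajectory")
}

#' @export
print.hs_trajectory <- function(x, ...) {
  cat(sprintf("<hs_trajectory> %d frames x %d atoms, T = %s K\n",
              length(x$frames), nrow(x$topology$atoms),
              format(x$temperature)))
  invisible(x)
}

#' Assign atom roles from a (residue name, atom name) pattern map
#'
#' Role assignment is pattern-driven rather than inferred from the bond graph:
#' the analyses only need role sets, and different polymer chemistries differ
#' only in which atom names play which role. Patterns are shell-style globs
#' matched against residue and atom names.
#'
#' @param topology an [hs_topology()].
#' @param role_map list of rules, each `list(resname = <glob>, name = <glob>,
#'   roles = <character vector of role tags>)`. Later rules add to earlier
#'   ones (tags are unioned per atom).
#' @param check if TRUE (default) enforce that every polymer (non-water)
#'   oxygen ends up classified as exactly one of mainchain/sidechain oxygen,
#'   and that every residue with side-chain atoms has exactly one
#'   terminal carbon.
#' @return the topology with roles filled in.
#' @export
assign_roles <- function(topology, role_map, check = TRUE) {
  if (!inherits(topology, "hs_topology")) stop("topology must be an hs_topology")
  atoms <- topology$atoms
  roles <- matrix(FALSE, nrow(atoms), length(.hs_roles),
                  dimnames = list(NULL, .hs_roles))
  for (rule in role_map) {
    if (is.null(rule$roles)) stop("role_map rule is missing its 'roles' field")
    bad <- setdiff(rule$roles, .hs_roles)
    if (length(bad)) stop("unknown role tag(s): ", paste(bad, collapse = ", "))
    res_pat <- if (is.null(rule$resname)) "*" else rule$resname
    name_pat <- if (is.null(rule$name)) "*" else rule$name
    hit <- grepl(utils::glob2rx(res_pat), atoms$resname) &
           grepl(utils::glob2rx(name_pat), atoms$name)
    roles[hit, rule$roles] <- TRUE
  }
  topology$roles <- roles
  validate_roles(topology)
  if (check) {
    is_water <- roles[, "water_oxygen"] | roles[, "water_hydrogen"]
    poly_ox <- which(atoms$element == "O" & !is_water)
    n_class <- roles[poly_ox, "mainchain_oxygen"] + roles[poly_ox, "sidechain_oxygen"]
    if (any(n_class != 1)) {
      bad <- poly_ox[n_class != 1]
      stop("polymer oxygen(s) not classified as exactly one of mainchain/",
           "sidechain oxygen: atom index ",
           paste(bad, collapse = ", "), " (residue ",
           paste(unique(atoms$resid[bad]), collapse = ", "), ")")
    }
    side_res <- unique(atoms$resid[roles[, "sidechain"]])
    for (r in side_res) {
      k <- sum(roles[, "terminal_carbon"] & atoms$resid == r)
      if (k != 1)
        stop(sprintf("residue %d has %d terminal carbons; expected exactly 1", r, k))
    }
  }
  topology
}

#' Select atom indices by role
#'
#' @param topology an [hs_topology()].
#' @param role one of the seven role tags.
#' @return ascending integer vector of atom indices (possibly empty).
#' @export
select_role <- function(topology, role) {
  if (!inherits(topology, "hs_topology")) stop("topology must be an hs_topology")
  if (length(role) != 1 || !(role %in% .hs_roles))
    stop("unknown role: ", paste(role, collapse = ", "),
         " (expected one of ", paste(.hs_roles, collapse = ", "), ")")
  sort(which(topology$roles[, role]))
}
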