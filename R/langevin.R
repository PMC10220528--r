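#' Overdamped Langevin bead-spring toy simulation
#'
#' NVT Euler-Maruyama integration of a linear bead-spring polymer in an
#' explicit bead solvent, in reduced units (kB = 1, bead mass = 1, energies
#' in units of the WCA epsilon). All beads repel via WCA; solvent beads
#' additionally feel a Lennard-Jones attraction of depth `terminal_epsilon`
#' towards the designated "terminal" polymer beads (every second bead, a
#' stand-in for side-chain end groups whose hydration shell the RDF analyses
#' track). Because terminal beads are partly occluded by their backbone
#' neighbours, the measured first-shell g(r) falls below 1 once temperature
#' outweighs the attraction - a planted analogue of hydration-shell melting.
#'
#' @param n_monomers polymer beads (>= 2).
#' @param solvent_count solvent beads.
#' @param temperature reduced temperature (kB = 1).
#' @param terminal_epsilon solvent/terminal-bead LJ well depth (reduced).
#' @param bond_k harmonic bond constant (energy / Angstrom^2).
#' @param bend_k bending stiffness (energy; `U = bend_k (1 + cos theta)` per
#'   interior bead). The semiflexible default keeps the terminal beads'
#'   occlusion geometry - and hence the planted shell intensity - from
#'   drifting on slow conformational timescales that desk-scale runs cannot
#'   average over; set to 0 for a fully flexible chain.
#' @param bead_sigma bead diameter (Angstrom); also the bond rest length.
#' @param backbone_sigma_factor WCA diameter multiplier for non-terminal
#'   polymer beads toward the solvent, emulating bulky backbone groups that
#'   partially shield the terminal beads' hydration shell; this occlusion is
#'   what drives the measured first-shell g below 1 at high temperature.
#' @param friction Langevin friction gamma (ps^-1); `dt * friction < 1`.
#' @param dt time step (ps).
#' @param n_steps total integration steps.
#' @param n_equil steps discarded before sampling.
#' @param stride sampling interval in steps.
#' @param density reduced bead number density `n sigma^3 / V` setting the box.
#' @param seed RNG seed.
#' @return an [hs_trajectory()]; polymer beads (roles `backbone`, terminal
#'   ones also `sidechain`+`terminal_carbon`) then solvent beads (role
#'   `water_oxygen`).
#' @export
run_toy_langevin <- function(n_monomers = 16, solvent_count = 200,
                             temperature = 1.0, terminal_epsilon = 0.75,
                             bond_k = 25, bend_k = 40, bead_sigma = 3.4,
                             backbone_sigma_factor = 1.1, friction = 0.7,
                             dt = 0.004, n_steps = 16000, n_equil = 2000,
                             stride = 20, density = 0.15, seed = 1) {
  if (n_monomers < 2) stop("n_monomers must be >= 2")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(friction, "friction", positive = TRUE)
  if (dt * friction >= 1) stop("unstable step: need dt * friction < 1")
  if (density <= 0 || density > 0.8)
    stop("reduced density must be in (0, 0.8] (overlap limit)")
  n <- n_monomers + solvent_count
  L <- (n * bead_sigma^3 / density)^(1 / 3)
  box <- rep(L, 3)
  set.seed(seed)
  # initial polymer: straight rod through the box centre in a random
  # direction (the relaxed state of the semiflexible chain)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  poly <- t(box / 2 + outer(u * bead_sigma, seq_len(n_monomers) - (n_monomers + 1) / 2))
  # solvent on a jittered cubic grid, skipping polymer overlaps
  k <- ceiling((2 * n)^(1 / 3)); s <- L / k
  grid <- as.matrix(expand.grid(x = (seq_len(k) - 0.5), y = (seq_len(k) - 0.5),
                                z = (seq_len(k) - 0.5))) * s
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  solv <- matrix(NA_real_, solvent_count, 3); got <- 0L
  for (i in seq_len(nrow(grid))) {
    if (got >= solvent_count) break
    cand <- grid[i, ] + runif(3, -0.1, 0.1) * s
    d2 <- min(rowSums(min_image(sweep(poly, 2, cand), box)^2))
    if (d2 > (0.9 * bead_sigma)^2) { got <- got + 1L; solv[got, ] <- cand }
  }
  if (got < solvent_count) stop("could not place solvent without overlaps; lower density")
  coords0 <- wrap_coords(rbind(poly, solv), box)
  is_terminal <- rep(FALSE, n_monomers)
  is_terminal[seq(2, n_monomers, by = 2)] <- TRUE
  raw <- cpp_toy_langevin(coords0, n_monomers, is_terminal, box, bond_k,
                          bend_k, bead_sigma, terminal_epsilon,
                          backbone_sigma_factor, temperature,
                          friction, dt, as.integer(n_steps),
                          as.integer(n_equil), as.integer(stride))
  if (!length(raw)) stop("no frames sampled; check n_steps/n_equil/stride")
  frames <- lapply(seq_along(raw), function(i)
    hs_frame(raw[[i]], box = box, time = (n_equil + (i - 1) * stride) * dt))
  atoms <- data.frame(
    name = c(ifelse(is_terminal, "CT", "CB"), rep("OW", solvent_count)),
    element = c(rep("C", n_monomers), rep("O", solvent_count)),
    resid = c(seq_len(n_monomers), n_monomers + seq_len(solvent_count)),
    resname = c(rep("TOY", n_monomers), rep("SOL", solvent_count)),
    stringsAsFactors = FALSE)
  roles <- matrix(FALSE, n, length(.hs_roles), dimnames = list(NULL, .hs_roles))
  roles[seq_len(n_monomers), "backbone"] <- TRUE
  roles[which(is_terminal), c("sidechain", "terminal_carbon")] <- TRUE
  roles[n_monomers + seq_len(solvent_count), "water_oxygen"] <- TRUE
  bonds <- cbind(seq_len(n_monomers - 1L), seq_len(n_monomers - 1L) + 1L)
  topo <- hs_topology(atoms, bonds, n_residues_polymer = n_monomers, roles = roles)
  hs_trajectory(topo, frames, temperature = temperature)
}

#' Write a trajectory as a PDB + multi-frame XYZ fixture with a role map
#'
#' Synthetic data flows through the same on-disk path as real data: the
#' topology and first frame go to `<base>.pdb`, all frames to `<base>.xyz`,
#' and a role map reconstructed from the topology roles to `<base>_roles.yaml`.
#'
#' @param trajectory an [hs_trajectory()].
#' @param dir output directory (created if needed).
#' @param base file basename.
#' @return named list of the three paths.
#' @export
write_fixture <- function(trajectory, dir, base = "fixture") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  topo <- trajectory$topology
  paths <- list(pdb = file.path(dir, paste0(base, ".pdb")),
                xyz = file.path(dir, paste0(base, ".xyz")),
                roles = file.path(dir, paste0(base, "_roles.yaml")))
  write_pdb(topo, trajectory$frames[[1]], paths$pdb)
  write_xyz_multi(trajectory$frames, paths$xyz, elements = topo$atoms$element)
  yaml::write_yaml(role_map_from_topology(topo), paths$roles)
  invisible(paths)
}

#' Reconstruct a (resname, atom name) role map from assigned roles
#'
#' @param topology an [hs_topology()] with roles assigned.
#' @return role-map list usable with [assign_roles()].
#' @export
role_map_from_topology <- function(topology) {
  atoms <- topology$atoms
  key <- paste(atoms$resname, atoms$name, sep = "\r")
  rules <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    tags <- .hs_roles[colSums(topology$roles[idx, , drop = FALSE]) > 0]
    if (!length(tags)) next
    parts <- strsplit(k, "\r")[[1]]
    rules[[length(rules) + 1L]] <- list(resname = parts[1], name = parts[2],
                                        roles = as.list(tags))
  }
  rules
}

#' Read a role map from YAML
#'
#' @param path YAML file: a list of `{resname, name, roles}` rules.
#' @return role-map list for [assign_roles()].
#' @export
read_role_map <- function(path) {
  rules <- yaml::read_yaml(path)
  lapply(rules, function(r) list(resname = r$resname, name = r$name,
                                 roles = unlist(r$roles)))
}
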