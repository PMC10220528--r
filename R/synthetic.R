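#' Freely jointed chain ensemble
#'
#' Draws `n_samples` independent freely jointed chain (FJC) configurations:
#' random walks of `n_bonds` steps of fixed length `b` with uniformly random
#' directions. The ensemble satisfies the ideal-chain closed forms
#' `<L^2> = N b^2` and `<Rg^2> -> N b^2 / 6` (large N), which anchor the
#' chain-metrics tests.
#'
#' @param n_bonds number of bonds N (>= 1).
#' @param b bond length (Angstrom).
#' @param n_samples number of independent configurations.
#' @param seed RNG seed.
#' @return an [hs_trajectory()] whose frames are the samples; all beads are
#'   tagged `backbone`, `n_residues_polymer = n_bonds`, box unset.
#' @export
gen_fjc <- function(n_bonds, b = 1, n_samples = 1000, seed = 1) {
  if (n_bonds < 1) stop("n_bonds must be >= 1")
  stopifnot_scalar(b, "b", positive = TRUE)
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(seed)
  n_beads <- n_bonds + 1L
  # all step vectors at once: isotropic unit vectors scaled to b
  g <- matrix(rnorm(3 * n_bonds * n_samples), ncol = 3)
  g <- g / sqrt(rowSums(g^2)) * b
  frames <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    steps <- g[((s - 1) * n_bonds + 1):(s * n_bonds), , drop = FALSE]
    co <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    frames[[s]] <- hs_frame(co, box = NULL, time = s - 1)
  }
  # first bead shares residue 1 so that residue count equals the degree of
  # polymerization (= bond count), preserving N across fixture round trips
  atoms <- data.frame(name = "C", element = "C",
                      resid = c(1L, seq_len(n_bonds)),
                      resname = "FJC", stringsAsFactors = FALSE)
  roles <- matrix(FALSE, n_beads, length(.hs_roles), dimnames = list(NULL, .hs_roles))
  roles[, "backbone"] <- TRUE
  bonds <- cbind(seq_len(n_bonds), seq_len(n_bonds) + 1L)
  topo <- hs_topology(atoms, bonds, n_residues_polymer = n_bonds, roles = roles)
  hs_trajectory(topo, frames)
}

#' Uniform (ideal-gas) point cloud in a periodic box
#'
#' @param n_points number of points (>= 1).
#' @param box orthorhombic box edges (Angstrom; a scalar is recycled).
#' @param seed RNG seed.
#' @return an [hs_frame()].
#' @export
gen_ideal_gas <- function(n_points, box, seed = 1) {
  if (n_points < 1) stop("n_points must be >= 1")
  box <- rep(as.numeric(box), length.out = 3)
  set.seed(seed)
  co <- cbind(runif(n_points, 0, box[1]), runif(n_points, 0, box[2]),
              runif(n_points, 0, box[3]))
  hs_frame(co, box = box)
}

#' Solvent cloud with a planted Gaussian hydration shell
#'
#' Samples "water oxygen" point clouds whose expected radial density around
#' each fixed reference atom is `rho * g*(r)` with
#' `g*(r) = 1 + (A - 1) * exp(-(r - r0)^2 / (2 sigma^2))`, i.e. a Gaussian
#' first-shell bump (A > 1) or depletion (A < 1) on a flat bulk background.
#' Sampling is accept/reject thinning of a uniform cloud against `g*` using
#' the minimum-image distance to the nearest reference, so several reference
#' atoms and frames share one generator; profile independence is enforced by
#' requiring references at least `2 * (r0 + 4 sigma)` apart.
#'
#' @param r0 shell radius (Angstrom).
#' @param sigma shell width (Angstrom).
#' @param amplitude target g at r0 (dimensionless, >= 0).
#' @param bulk_density far-field number density rho (Angstrom^-3).
#' @param box box edge (scalar or length 3, Angstrom).
#' @param n_ref number of reference atoms (placed on a cubic grid unless
#'   `ref_coords` is given).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param ref_coords optional `n_ref x 3` matrix of reference positions.
#' @return an [hs_trajectory()]; reference atoms (tagged
#'   `sidechain`+`terminal_carbon`) come first, then `water_oxygen` points.
#' @export
gen_shell_cloud <- function(r0, sigma, amplitude, bulk_density, box,
                            n_ref = 1, n_frames = 1, seed = 1,
                            ref_coords = NULL) {
  stopifnot_scalar(r0, "r0", positive = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (amplitude < 0) stop("amplitude must be >= 0")
  stopifnot_scalar(bulk_density, "bulk_density", positive = TRUE)
  box <- rep(as.numeric(box), length.out = 3)
  if (r0 + 4 * sigma >= min(box) / 2)
    stop("shell does not fit: need r0 + 4*sigma < box/2")
  set.seed(seed)
  if (is.null(ref_coords)) {
    k <- ceiling(n_ref^(1 / 3))
    s <- box / k
    if (min(s) < 2 * (r0 + 4 * sigma))
      stop("reference spheres would overlap: need spacing >= 2*(r0 + 4*sigma)")
    gpts <- as.matrix(expand.grid(x = (seq_len(k) - 0.5) * s[1],
                                  y = (seq_len(k) - 0.5) * s[2],
                                  z = (seq_len(k) - 0.5) * s[3]))
    ref_coords <- gpts[seq_len(n_ref), , drop = FALSE]
  } else {
    ref_coords <- as.matrix(ref_coords)
    if (nrow(ref_coords) != n_ref) stop("ref_coords must have n_ref rows")
    if (n_ref > 1) {
      for (i in seq_len(n_ref - 1)) for (j in (i + 1):n_ref) {
        d <- sqrt(sum(min_image(ref_coords[i, ] - ref_coords[j, ], box)^2))
        if (d < 2 * (r0 + 4 * sigma))
          stop("reference spheres overlap: inter-reference distance < 2*(r0 + 4*sigma)")
      }
    }
  }
  A <- amplitude
  gstar <- function(r) 1 + (A - 1) * exp(-(r - r0)^2 / (2 * sigma^2))
  vol <- prod(box)
  # per-reference excess particle count of the shell relative to bulk
  shell_excess <- (A - 1) * integrate(function(r)
    4 * pi * r^2 * exp(-(r - r0)^2 / (2 * sigma^2)), 0, r0 + 8 * sigma)$value
  n_total <- max(1L, round(bulk_density * (vol + n_ref * shell_excess)))
  M <- max(1, A)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    acc <- matrix(numeric(0), ncol = 3)
    while (nrow(acc) < n_total) {
      m <- ceiling((n_total - nrow(acc)) * M * 1.3) + 50L
      cand <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]), runif(m, 0, box[3]))
      dmin <- rep(Inf, m)
      for (i in seq_len(n_ref)) {
        dx <- min_image(sweep(cand, 2, ref_coords[i, ]), box)
        dmin <- pmin(dmin, sqrt(rowSums(dx^2)))
      }
      keep <- runif(m) < gstar(dmin) / M
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    frames[[f]] <- hs_frame(rbind(ref_coords, acc[seq_len(n_total), , drop = FALSE]),
                            box = box, time = f - 1)
  }
  n_at <- n_ref + n_total
  atoms <- data.frame(
    name = c(rep("CT", n_ref), rep("OW", n_total)),
    element = c(rep("C", n_ref), rep("O", n_total)),
    resid = c(seq_len(n_ref), n_ref + seq_len(n_total)),
    resname = c(rep("REF", n_ref), rep("HOH", n_total)),
    stringsAsFactors = FALSE)
  roles <- matrix(FALSE, n_at, length(.hs_roles), dimnames = list(NULL, .hs_roles))
  roles[seq_len(n_ref), c("sidechain", "terminal_carbon")] <- TRUE
  roles[n_ref + seq_len(n_total), "water_oxygen"] <- TRUE
  topo <- hs_topology(atoms, NULL, n_residues_polymer = n_ref, roles = roles)
  hs_trajectory(topo, frames)
}

#' Hydrogen-bond geometry fixture with planted margins
#'
#' Builds acceptor oxygens and single water molecules at exact geometries:
#' `n_bonded` donor/acceptor pairs that satisfy both criteria with a margin,
#' `n_miss_distance` pairs that violate only the distance criterion and
#' `n_miss_angle` pairs that violate only the angle criterion. Explicit
#' margins make the boundary convention (<= / >=) auditable.
#'
#' @param n_bonded,n_miss_distance,n_miss_angle site counts per category.
#' @param criteria an [hbond_criteria()].
#' @param seed RNG seed (sites get random rigid orientations).
#' @param margin_d_in distance below `d_max` for satisfying pairs (Angstrom).
#' @param margin_d_out distance above `d_max` for distance near-misses.
#' @param margin_angle angle margin in degrees.
#' @return `list(topology, frame)`; acceptors are tagged `mainchain_oxygen`,
#'   waters `water_oxygen`/`water_hydrogen` with O-H bonds in the topology.
#' @export
gen_hbond_fixture <- function(n_bonded, n_miss_distance, n_miss_angle,
                              criteria = hbond_criteria(), seed = 1,
                              margin_d_in = 0.2, margin_d_out = 0.3,
                              margin_angle = 10) {
  set.seed(seed)
  specs <- rbind(
    if (n_bonded > 0) cbind(d = criteria$d_max - margin_d_in,
                            ang = criteria$angle_min + margin_angle)[rep(1, n_bonded), , drop = FALSE],
    if (n_miss_distance > 0) cbind(d = criteria$d_max + margin_d_out,
                                   ang = criteria$angle_min + margin_angle)[rep(1, n_miss_distance), , drop = FALSE],
    if (n_miss_angle > 0) cbind(d = criteria$d_max - margin_d_in,
                                ang = criteria$angle_min - margin_angle)[rep(1, n_miss_angle), , drop = FALSE])
  n_sites <- if (is.null(specs)) 0L else nrow(specs)
  if (n_sites == 0) stop("fixture needs at least one site")
  if (any(specs[, "ang"] > 180) || any(specs[, "ang"] <= 0))
    stop("planted angle out of (0, 180]; shrink margin_angle")
  coords <- list(); name <- character(); element <- character()
  resid <- integer(); resname <- character(); bonds <- list()
  role_rows <- list()
  k <- ceiling(n_sites^(1 / 3)); spacing <- 12
  grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))) * spacing
  for (s in seq_len(n_sites)) {
    local <- hbond_site_geometry(specs[s, "d"], specs[s, "ang"], oh = 0.96)
    # random rigid rotation for generality
    rot <- random_rotation_matrix()
    placed <- sweep(local %*% t(rot), 2, grid[s, ], "+")
    base <- length(coords)
    coords <- c(coords, split(placed, row(placed)))
    name <- c(name, c("OE", "OW", "H1", "H2"))
    element <- c(element, c("O", "O", "H", "H"))
    resid <- c(resid, c(2L * s - 1L, rep(2L * s, 3)))
    resname <- c(resname, c("PGE", rep("HOH", 3)))
    bonds <- c(bonds, list(c(base + 2L, base + 3L), c(base + 2L, base + 4L)))
    role_rows[[s]] <- c("mainchain_oxygen", "water_oxygen", "water_hydrogen", "water_hydrogen")
  }
  co <- do.call(rbind, lapply(coords, as.numeric))
  n_at <- nrow(co)
  roles <- matrix(FALSE, n_at, length(.hs_roles), dimnames = list(NULL, .hs_roles))
  roles[cbind(seq_len(n_at), match(unlist(role_rows), .hs_roles))] <- TRUE
  atoms <- data.frame(name = name, element = element, resid = resid,
                      resname = resname, stringsAsFactors = FALSE)
  topo <- hs_topology(atoms, do.call(rbind, bonds),
                      n_residues_polymer = n_sites, roles = roles)
  list(topology = topo, frame = hs_frame(co, box = NULL))
}

# local geometry of one site: rows = acceptor O, donor O, H (the H-bond
# hydrogen), H2 (spectator). Acceptor at origin, donor on +x at distance d,
# H placed 0.96 A from the donor so that the donor-H...acceptor angle (at H)
# equals `angle` degrees.
hbond_site_geometry <- function(d, angle, oh = 0.96) {
  donor <- c(d, 0, 0)
  h_at <- function(phi) {
    u <- c(-cos(phi), sin(phi), 0)   # direction from donor, phi = 0 points at acceptor
    donor + oh * u
  }
  ang_at <- function(phi) {
    h <- h_at(phi)
    vD <- donor - h; vA <- -h
    acos(sum(vD * vA) / sqrt(sum(vD^2) * sum(vA^2))) * 180 / pi
  }
  phi <- if (angle >= 180 - 1e-9) 0 else
    uniroot(function(p) ang_at(p) - angle, c(1e-9, pi * 0.9), tol = 1e-12)$root
  h <- h_at(phi)
  h2 <- donor + oh * c(cos(1.823), 0, sin(1.823))  # ~104.5 deg away, off-plane
  rbind(c(0, 0, 0), donor, h, h2)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Tabulated first-peak intensity curve
#'
#' Builds a peak curve directly from temperatures and intensities (or an
#' intensity function), for testing the crossing-temperature statistic
#' without any trajectory.
#'
#' @param temperatures temperatures (K).
#' @param intensity intensities at those temperatures, or a function of T.
#' @param r_peak optional peak positions (defaults to NA).
#' @return an `hs_peak_curve` (see [peak_intensity_curve()]).
#' @export
gen_peak_curve <- function(temperatures, intensity, r_peak = NULL) {
  if (is.function(intensity)) intensity <- intensity(temperatures)
  if (length(intensity) != length(temperatures))
    stop("temperatures and intensities must have equal length")
  o <- order(temperatures)
  new_peak_curve(temperatures[o], if (is.null(r_peak)) rep(NA_real_, length(o)) else r_peak[o],
                 intensity[o])
}
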