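# shared in-code fixtures; no data files

# simplified poly(glycidyl ether)-like topology: per residue a 3-atom
# backbone (C1 anchor, C2, O1 = main-chain ether oxygen) and a 3-atom side
# chain (C3, O2 = side-chain oxygen, C4 = terminal carbon), laid out on a
# rigid deterministic geometry so distances are known exactly
make_pge_topology <- function(n_res, box = NULL) {
  per <- data.frame(
    name = c("C1", "C2", "O1", "C3", "O2", "C4"),
    element = c("C", "C", "O", "C", "O", "C"),
    dx = c(0.0, 1.5, 3.0, 0.0, 0.0, 0.0),
    dy = c(0.0, 0.0, 0.0, 1.5, 3.0, 4.5),
    stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    data.frame(name = per$name, element = per$element, resid = r,
               resname = "PGE", stringsAsFactors = FALSE)
  }))
  coords <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    cbind(per$dx + (r - 1) * 4.5, per$dy, 0)
  }))
  bonds <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    o <- (r - 1) * 6
    b <- rbind(c(o + 1, o + 2), c(o + 2, o + 3),    # C1-C2-O1
               c(o + 1, o + 4), c(o + 4, o + 5), c(o + 5, o + 6))  # C1-C3-O2-C4
    if (r < n_res) b <- rbind(b, c(o + 3, o + 7))   # O1 - next C1
    b
  }))
  topo <- hs_topology(atoms, bonds, n_residues_polymer = n_res)
  topo <- assign_roles(topo, pge_role_map())
  list(topology = topo, frame = hs_frame(coords, box = box))
}

pge_role_map <- function() list(
  list(resname = "PGE", name = "C1", roles = "backbone"),
  list(resname = "PGE", name = "C2", roles = "backbone"),
  list(resname = "PGE", name = "O1", roles = c("backbone", "mainchain_oxygen")),
  list(resname = "PGE", name = "C3", roles = "sidechain"),
  list(resname = "PGE", name = "O2", roles = c("sidechain", "sidechain_oxygen")),
  list(resname = "PGE", name = "C4", roles = c("sidechain", "terminal_carbon")),
  list(resname = "HOH", name = "OW", roles = "water_oxygen"),
  list(resname = "HOH", name = "H*", roles = "water_hydrogen"))

# a single water (O, H1, H2) at a given O position, with the H1 direction
# controllable so H-bond geometry can be planted
make_water <- function(o_pos, h1_dir, oh = 0.96) {
  h1 <- o_pos + oh * h1_dir / sqrt(sum(h1_dir^2))
  perp <- c(-h1_dir[2], h1_dir[1], 0.3)
  h2 <- o_pos + oh * perp / sqrt(sum(perp^2))
  rbind(o_pos, h1, h2)
}

random_rigid_motion <- function(coords) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  sweep(coords %*% t(R), 2, runif(3, -20, 20), "+")
}

# brute-force O(n*m) distance histogram oracle (pure R, no kernel reuse)
oracle_dist_hist <- function(ref, target, box, dr, nbins) {
  counts <- integer(nbins)
  for (i in seq_len(nrow(ref))) for (j in seq_len(nrow(target))) {
    d <- ref[i, ] - target[j, ]
    d <- d - box * round(d / box)
    dist <- sqrt(sum(d^2))
    k <- floor(dist / dr) + 1
    if (dist > 0 && k <= nbins) counts[k] <- counts[k] + 1L
  }
  counts
}

# brute-force all-pairs H-bond oracle (no cutoff acceleration)
oracle_hbonds <- function(coords, box, donor_pairs, acceptors, d_max, angle_min) {
  mi <- function(v) if (is.null(box)) v else v - box * round(v / box)
  out <- list()
  for (k in seq_len(nrow(donor_pairs))) {
    d_at <- donor_pairs[k, 1]; h <- donor_pairs[k, 2]
    for (a in acceptors) {
      if (a == d_at || a == h) next
      if (sqrt(sum(mi(coords[d_at, ] - coords[a, ])^2)) > d_max) next
      vHD <- mi(coords[d_at, ] - coords[h, ]); vHA <- mi(coords[a, ] - coords[h, ])
      ang <- acos(max(-1, min(1, sum(vHD * vHA) / sqrt(sum(vHD^2) * sum(vHA^2))))) * 180 / pi
      if (ang >= angle_min) out[[length(out) + 1L]] <- c(d_at, h, a)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
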