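#' Geometric hydrogen-bond criteria
#'
#' Classic distance/angle definition: donor-heavy-atom to acceptor distance
#' `d(D...A) <= d_max` and donor-H-acceptor angle (measured at the hydrogen)
#' `>= angle_min`. The defaults (3.5 Angstrom, 150 degrees) are a documented
#' package choice; both are configurable and boundary comparisons are strict
#' `<=` / `>=`.
#'
#' @param d_max maximum D...A distance (Angstrom).
#' @param angle_min minimum D-H...A angle (degrees, in (0, 180]).
#' @return an `hs_hbond_criteria` list.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 150) {
  stopifnot_scalar(d_max, "d_max", positive = TRUE)
  if (angle_min <= 0 || angle_min > 180) stop("angle_min must be in (0, 180]")
  structure(list(d_max = d_max, angle_min = angle_min),
            class = "hs_hbond_criteria")
}

# donor (heavy, H) pairs from topology bonds, for heavy atoms whose element
# is in `heavy_elements` and hydrogens identified by element "H"
donor_pairs_from_topology <- function(topology, atom_subset = NULL,
                                      heavy_elements = c("O", "N")) {
  atoms <- topology$atoms
  b <- rbind(topology$bonds, topology$bonds[, 2:1, drop = FALSE])
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  heavy <- atoms$element[b[, 1]] %in% heavy_elements & atoms$element[b[, 2]] == "H"
  out <- b[heavy, , drop = FALSE]
  if (!is.null(atom_subset)) out <- out[out[, 1] %in% atom_subset, , drop = FALSE]
  out
}

#' Detect hydrogen bonds in a frame
#'
#' Reports every (donor heavy atom, hydrogen, acceptor) triple with
#' `d(D...A) <= d_max` and `angle(D-H...A) >= angle_min`, using minimum-image
#' distances when the frame has a box. Candidate pairs come from a compiled
#' cutoff search; angles are evaluated only for candidates.
#'
#' @param frame an [hs_frame()].
#' @param topology an [hs_topology()] (validates that each H is bonded to its
#'   donor).
#' @param donor_pairs 2-column matrix of (donor heavy atom, hydrogen) index
#'   pairs; defaults to all water O-H pairs in the topology.
#' @param acceptors acceptor atom indices; defaults to polymer oxygens
#'   (mainchain + sidechain classes).
#' @param criteria an [hbond_criteria()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle`.
#' @export
find_hbonds <- function(frame, topology, donor_pairs = NULL, acceptors = NULL,
                        criteria = hbond_criteria()) {
  if (is.null(donor_pairs)) {
    wo <- select_role(topology, "water_oxygen")
    donor_pairs <- donor_pairs_from_topology(topology, atom_subset = wo,
                                             heavy_elements = "O")
  }
  donor_pairs <- matrix(as.integer(donor_pairs), ncol = 2)
  if (is.null(acceptors))
    acceptors <- sort(c(select_role(topology, "mainchain_oxygen"),
                        select_role(topology, "sidechain_oxygen")))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (!nrow(donor_pairs) || !length(acceptors)) return(empty)
  bkey <- paste(pmin(topology$bonds[, 1], topology$bonds[, 2]),
                pmax(topology$bonds[, 1], topology$bonds[, 2]))
  pkey <- paste(pmin(donor_pairs[, 1], donor_pairs[, 2]),
                pmax(donor_pairs[, 1], donor_pairs[, 2]))
  if (!all(pkey %in% bkey))
    stop("donor hydrogen not bonded to its heavy atom in the topology")
  co <- frame$coords
  box <- frame$box
  use_pbc <- !is.null(box)
  if (!use_pbc) box <- c(1, 1, 1)
  donors_u <- sort(unique(donor_pairs[, 1]))
  cand <- cpp_pairs_within(co[donors_u, , drop = FALSE],
                           co[acceptors, , drop = FALSE],
                           box, criteria$d_max, use_pbc)
  if (!nrow(cand)) return(empty)
  res <- empty
  for (k in seq_len(nrow(cand))) {
    d_at <- donors_u[cand[k, 1]]
    a_at <- acceptors[cand[k, 2]]
    if (d_at == a_at) next
    hset <- donor_pairs[donor_pairs[, 1] == d_at, 2]
    vDA <- co[a_at, ] - co[d_at, ]
    if (use_pbc) vDA <- min_image(vDA, frame$box)
    dist_da <- sqrt(sum(vDA^2))
    for (h in hset) {
      if (h == a_at) next
      vHD <- co[d_at, ] - co[h, ]
      vHA <- co[a_at, ] - co[h, ]
      if (use_pbc) { vHD <- min_image(vHD, frame$box); vHA <- min_image(vHA, frame$box) }
      cosang <- sum(vHD * vHA) / sqrt(sum(vHD^2) * sum(vHA^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= criteria$angle_min)
        res <- rbind(res, data.frame(donor = d_at, hydrogen = h, acceptor = a_at,
                                     distance = dist_da, angle = ang))
    }
  }
  res
}

#' Polymer-water hydrogen-bond averages split by oxygen class
#'
#' Counts water-donated hydrogen bonds to polymer oxygens per frame, split by
#' acceptor class (main-chain vs side-chain oxygen), averages over frames and
#' normalizes by the number of oxygens in each class, giving the per-oxygen
#' mean bond count that table-style reports use.
#'
#' @param trajectory an [hs_trajectory()] with roles and water O-H bonds.
#' @param criteria an [hbond_criteria()].
#' @return an `hs_hbond_stats`: list with `per_frame` (data.frame
#'   `mainchain`/`sidechain` counts), class means, oxygen counts, and
#'   per-oxygen normalized means.
#' @export
hbond_averages <- function(trajectory, criteria = hbond_criteria()) {
  topo <- trajectory$topology
  mo <- select_role(topo, "mainchain_oxygen")
  so <- select_role(topo, "sidechain_oxygen")
  if (!length(mo) && !length(so)) stop("no polymer oxygens; assign roles first")
  wo <- select_role(topo, "water_oxygen")
  dp <- donor_pairs_from_topology(topo, atom_subset = wo, heavy_elements = "O")
  counts <- t(vapply(trajectory$frames, function(f) {
    hb <- find_hbonds(f, topo, donor_pairs = dp, acceptors = c(mo, so),
                      criteria = criteria)
    c(mainchain = sum(hb$acceptor %in% mo), sidechain = sum(hb$acceptor %in% so))
  }, numeric(2)))
  means <- colMeans(counts)
  structure(list(
    per_frame = as.data.frame(counts),
    mean_mainchain = means[["mainchain"]], mean_sidechain = means[["sidechain"]],
    n_mainchain_oxygen = length(mo), n_sidechain_oxygen = length(so),
    per_oxygen_mainchain = if (length(mo)) means[["mainchain"]] / length(mo) else NA_real_,
    per_oxygen_sidechain = if (length(so)) means[["sidechain"]] / length(so) else NA_real_),
    class = "hs_hbond_stats")
}

#' Intrapolymer hydrogen bonds
#'
#' Counts hydrogen bonds whose donor and acceptor both belong to the polymer.
#' With the default donor definition (O-H and N-H only) a pure polyether has
#' no donors at all, so the count is exactly zero in every frame; the C-H
#' donor mode exists for sensitivity analysis of that assumption.
#'
#' @param trajectory an [hs_trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param include_ch_donors also treat polymer C-H groups as donors.
#' @return list with `mean_count` and `per_frame`.
#' @export
intrapolymer_hbonds <- function(trajectory, criteria = hbond_criteria(),
                                include_ch_donors = FALSE) {
  topo <- trajectory$topology
  atoms <- topo$atoms
  roles <- topo$roles
  is_water <- roles[, "water_oxygen"] | roles[, "water_hydrogen"]
  poly <- which(!is_water)
  heavy <- if (include_ch_donors) c("O", "N", "C") else c("O", "N")
  dp <- donor_pairs_from_topology(topo, atom_subset = poly,
                                  heavy_elements = heavy)
  dp <- dp[!is_water[dp[, 2]], , drop = FALSE]
  acceptors <- poly[atoms$element[poly] %in% c("O", "N")]
  per_frame <- vapply(trajectory$frames, function(f) {
    if (!nrow(dp) || !length(acceptors)) return(0)
    hb <- find_hbonds(f, topo, donor_pairs = dp, acceptors = acceptors,
                      criteria = criteria)
    nrow(hb[hb$donor != hb$acceptor, , drop = FALSE])
  }, numeric(1))
  list(mean_count = mean(per_frame), per_frame = per_frame)
}
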