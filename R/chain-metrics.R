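#' Radius of gyration of a selection
#'
#' `Rg^2 = (1/N') sum_n (R_n - R_c)^2` over the N' selected atoms with R_c
#' their centroid. Unweighted by default, matching the usual convention for
#' chain-extension analysis; supply `masses` for a mass-weighted variant.
#' When the frame has a periodic box the selection is first made whole across
#' images by walking the selection order, so a chain wrapped by the box does
#' not inflate Rg.
#'
#' @param frame an [hs_frame()].
#' @param selection integer atom indices (order = chain order for unwrapping).
#' @param masses optional per-selected-atom masses.
#' @param unwrap make the selection whole across periodic images first.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection, masses = NULL, unwrap = TRUE) {
  if (!length(selection)) stop("selection is empty")
  co <- frame$coords[selection, , drop = FALSE]
  if (unwrap && !is.null(frame$box)) {
    co <- unwrap_path(co, frame$box)
    span <- apply(co, 2, function(v) diff(range(v)))
    if (any(span > frame$box / 2 * 1.999) && any(span > frame$box))
      warning("unwrapped chain spans more than the box; Rg may be unreliable")
  }
  if (is.null(masses)) {
    cen <- colMeans(co)
    sqrt(mean(rowSums(sweep(co, 2, cen)^2)))
  } else {
    if (length(masses) != nrow(co)) stop("masses must match the selection length")
    w <- masses / sum(masses)
    cen <- colSums(co * w)
    sqrt(sum(w * rowSums(sweep(co, 2, cen)^2)))
  }
}

#' Rg time series over a trajectory
#'
#' @param trajectory an [hs_trajectory()].
#' @param selection atom indices; defaults to all polymer-role atoms.
#' @param ... passed to [radius_of_gyration()].
#' @return `data.frame(time, rg)`.
#' @export
rg_series <- function(trajectory, selection = NULL, ...) {
  if (is.null(selection)) {
    roles <- trajectory$topology$roles
    selection <- which(rowSums(roles[, .hs_polymer_roles, drop = FALSE]) > 0)
    if (!length(selection)) selection <- seq_len(nrow(trajectory$topology$atoms))
  }
  data.frame(
    time = vapply(trajectory$frames, function(f) f$time, numeric(1)),
    rg = vapply(trajectory$frames, radius_of_gyration, numeric(1),
                selection = selection, ...))
}

#' Rg distribution with peak detection
#'
#' Normalized histogram of an Rg series plus local-maximum detection on a
#' Gaussian-smoothed copy. The principal peak is the global maximum of the
#' smoothed density; a series is flagged multimodal when at least two peaks
#' exceed the prominence threshold. The reported `sd` is the sample SD
#' (n - 1) of the raw series, not of the histogram.
#'
#' @param values Rg series (numeric, >= 3 values) or the data.frame from
#'   [rg_series()].
#' @param bin_width histogram bin width (Angstrom).
#' @param smooth_bandwidth Gaussian kernel SD in bins used before peak
#'   detection.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   maximum smoothed density.
#' @return an `hs_rg_distribution`: list with `bin_edges`, `density` (raw),
#'   `smoothed`, `peaks` (data.frame rg/density/prominence), `principal_peak`,
#'   `sd`, `multimodal`.
#' @export
rg_distribution <- function(values, bin_width = 0.1, smooth_bandwidth = 2,
                            prominence_frac = 0.05) {
  if (is.data.frame(values)) values <- values$rg
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 samples for a distribution")
  if (bin_width <= 0) stop("bin_width must be > 0")
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi - lo < bin_width) { lo <- lo - bin_width / 2; hi <- lo + bin_width }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)
  dens <- h$density
  centers <- h$mids
  sm <- gauss_smooth(dens, smooth_bandwidth)
  pk <- find_peaks(sm)
  thr <- prominence_frac * max(sm)
  keep <- pk$prominence >= thr
  peaks <- data.frame(rg = centers[pk$index[keep]],
                      density = sm[pk$index[keep]],
                      prominence = pk$prominence[keep])
  peaks <- peaks[order(-peaks$density), , drop = FALSE]
  structure(list(
    bin_edges = edges, density = dens, smoothed = sm, mids = centers,
    peaks = peaks,
    principal_peak = if (nrow(peaks)) peaks$rg[1] else NA_real_,
    sd = if (length(values) >= 2) sample_sd(values) else 0,
    multimodal = nrow(peaks) >= 2), class = "hs_rg_distribution")
}

gauss_smooth <- function(x, bandwidth_bins) {
  if (bandwidth_bins <= 0) return(x)
  half <- ceiling(4 * bandwidth_bins)
  w <- dnorm(-half:half, sd = bandwidth_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    wi <- w[j - i + half + 1]
    out[i] <- sum(x[j] * wi) / sum(wi)
  }
  out
}

# local maxima with a simple prominence measure: height above the higher of
# the two valley minima separating the peak from taller terrain (or the edge)
find_peaks <- function(x) {
  n <- length(x)
  idx <- integer(); prom <- numeric()
  for (i in seq_len(n)) {
    left <- if (i > 1) x[i - 1] else -Inf
    right <- if (i < n) x[i + 1] else -Inf
    if (x[i] > left && x[i] >= right) {
      lmin <- x[i]; j <- i; l_edge <- FALSE
      while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
      if (j == 1) l_edge <- TRUE
      rmin <- x[i]; j <- i; r_edge <- FALSE
      while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
      if (j == n) r_edge <- TRUE
      # a peak with no higher terrain on either side is the global max: its
      # prominence is its full height (densities are >= 0)
      p <- if (l_edge && r_edge) x[i] else x[i] - max(lmin, rmin)
      idx <- c(idx, i); prom <- c(prom, p)
    }
  }
  list(index = idx, prominence = prom)
}

#' End-to-end length of a backbone
#'
#' Euclidean distance between the first and last atoms of an ordered backbone
#' selection, after making the backbone whole across periodic images.
#'
#' @param frame an [hs_frame()].
#' @param backbone_selection ordered (head to tail) atom indices.
#' @return L in Angstrom.
#' @export
end_to_end_length <- function(frame, backbone_selection) {
  if (length(backbone_selection) < 2) stop("backbone selection needs >= 2 atoms")
  co <- frame$coords[backbone_selection, , drop = FALSE]
  if (!is.null(frame$box)) co <- unwrap_path(co, frame$box)
  sqrt(sum((co[nrow(co), ] - co[1, ])^2))
}

#' Fully extended main-chain length
#'
#' `sum_of_bonds` sums consecutive backbone bond lengths (exact for the
#' freely jointed test chains); `zigzag` multiplies that contour length by
#' sin(109.47/2 degrees) = 0.8165, the all-trans projection appropriate for
#' tetrahedral all-atom backbones.
#'
#' @param topology an [hs_topology()] with backbone roles and bonds.
#' @param frame an [hs_frame()] supplying bond geometry.
#' @param mode `"sum_of_bonds"` (default) or `"zigzag"`.
#' @return Lmax in Angstrom.
#' @export
lmax <- function(topology, frame, mode = c("sum_of_bonds", "zigzag")) {
  mode <- match.arg(mode)
  bb <- select_role(topology, "backbone")
  if (length(bb) < 2) stop("need >= 2 backbone atoms")
  bonded <- topology$bonds
  key <- paste(pmin(bonded[, 1], bonded[, 2]), pmax(bonded[, 1], bonded[, 2]))
  for (i in seq_len(length(bb) - 1)) {
    k <- paste(min(bb[i], bb[i + 1]), max(bb[i], bb[i + 1]))
    if (!(k %in% key))
      stop(sprintf("backbone is disconnected between atoms %d and %d", bb[i], bb[i + 1]))
  }
  co <- frame$coords[bb, , drop = FALSE]
  if (!is.null(frame$box)) co <- unwrap_path(co, frame$box)
  contour <- sum(sqrt(rowSums((co[-1, , drop = FALSE] - co[-nrow(co), , drop = FALSE])^2)))
  if (mode == "zigzag") contour * sin(109.47 / 2 * pi / 180) else contour
}

#' Chain-extension statistics with the ideal-chain coil/globule criterion
#'
#' Computes the per-frame end-to-end length L of the backbone, the extended
#' length Lmax (averaged over frames, constant for rigid-bond chains), the
#' ratio `mean(L)/Lmax`, and the ideal-chain reference `1/sqrt(N)` for the
#' degree of polymerization N. A chain is called a coil when the ratio
#' exceeds the reference, a globule otherwise. `sd` is the sample SD of the
#' per-frame L/Lmax series and `cv = sd/ratio`.
#'
#' @param trajectory an [hs_trajectory()] with backbone roles assigned.
#' @param mode passed to [lmax()].
#' @return an `hs_chain_extension`: list with `L_bar`, `L_max`, `ratio`,
#'   `ideal_ref`, `state`, `sd`, `cv`, `n_residues`, `ratio_series`.
#' @export
chain_extension_stats <- function(trajectory, mode = "sum_of_bonds") {
  if (!length(trajectory$frames)) stop("trajectory has no frames")
  topo <- trajectory$topology
  bb <- select_role(topo, "backbone")
  L <- vapply(trajectory$frames, end_to_end_length, numeric(1),
              backbone_selection = bb)
  Lm <- mean(vapply(trajectory$frames, function(f) lmax(topo, f, mode), numeric(1)))
  series <- L / Lm
  ratio <- mean(series)
  N <- topo$n_residues_polymer
  ref <- ideal_chain_ref(N)
  s <- if (length(series) >= 2) sample_sd(series) else 0
  structure(list(
    L_bar = mean(L), L_max = Lm, ratio = ratio, ideal_ref = ref,
    state = if (ratio > ref) "coil" else "globule",
    sd = s, cv = if (ratio != 0) s / ratio else NA_real_,
    n_residues = N, ratio_series = series,
    temperature = trajectory$temperature), class = "hs_chain_extension")
}

#' Ideal-chain extension reference
#'
#' For a freely jointed / ideal chain with degree of polymerization N the
#' expected ratio of mean end-to-end length to fully extended length scales
#' as `1/sqrt(N)` (root-mean-square length `sqrt(N) b` over contour `N b`).
#' Chains with a larger measured ratio are classified as coils, smaller as
#' globules.
#'
#' @param n_residues degree of polymerization N (>= 1).
#' @return `1/sqrt(N)`.
#' @export
ideal_chain_ref <- function(n_residues) {
  if (any(n_residues < 1)) stop("n_residues must be >= 1")
  1 / sqrt(n_residues)
}

#' Average chain-extension ratios over temperatures
#'
#' @param stats list of `hs_chain_extension` objects, or a numeric vector of
#'   per-temperature ratios.
#' @return list with `mean`, `sd` (sample SD over temperatures) and `cv`.
#' @export
temperature_average <- function(stats) {
  ratios <- if (is.numeric(stats)) stats else
    vapply(stats, function(s) s$ratio, numeric(1))
  if (length(ratios) < 1) stop("no ratios supplied")
  m <- mean(ratios)
  s <- if (length(ratios) >= 2) sample_sd(ratios) else 0
  list(mean = m, sd = s, cv = if (m != 0) s / m else NA_real_)
}

#' Time-averaged side-chain lengths
#'
#' For each polymer residue carrying a side chain, measures the distance from
#' the residue's main-chain anchor (the backbone atom bonded to a side-chain
#' atom of the same residue) to its terminal carbon, per frame, and averages
#' over time; the chain value is the mean over residues.
#'
#' @param trajectory an [hs_trajectory()] with roles and bonds assigned.
#' @return list with `per_residue` (named numeric, time-averaged length per
#'   residue), `chain_mean`, and `n_frames`.
#' @export
side_chain_lengths <- function(trajectory) {
  topo <- trajectory$topology
  atoms <- topo$atoms
  roles <- topo$roles
  term <- which(roles[, "terminal_carbon"])
  if (!length(term)) stop("no terminal_carbon atoms; assign roles first")
  res_ids <- sort(unique(atoms$resid[term]))
  bonds <- rbind(topo$bonds, topo$bonds[, 2:1, drop = FALSE])
  anchor <- integer(length(res_ids)); terminal <- integer(length(res_ids))
  for (i in seq_along(res_ids)) {
    r <- res_ids[i]
    t_at <- term[atoms$resid[term] == r]
    if (length(t_at) != 1) stop(sprintf("residue %d lacks a unique terminal carbon", r))
    bb_res <- which(roles[, "backbone"] & atoms$resid == r)
    side_res <- which(roles[, "sidechain"] & atoms$resid == r)
    a <- bb_res[vapply(bb_res, function(j)
      any(bonds[, 1] == j & bonds[, 2] %in% side_res), logical(1))]
    if (!length(a)) stop(sprintf("residue %d has no backbone anchor bonded to its side chain", r))
    anchor[i] <- a[1]; terminal[i] <- t_at
  }
  per_frame <- vapply(trajectory$frames, function(f) {
    d <- f$coords[terminal, , drop = FALSE] - f$coords[anchor, , drop = FALSE]
    if (!is.null(f$box)) d <- min_image(d, f$box)
    sqrt(rowSums(d^2))
  }, numeric(length(res_ids)))
  per_frame <- matrix(per_frame, nrow = length(res_ids))
  per_res <- rowMeans(per_frame)
  names(per_res) <- res_ids
  list(per_residue = per_res, chain_mean = mean(per_res),
       n_frames = length(trajectory$frames))
}

#' Temperature statistics for per-temperature scalar values
#'
#' Mean over temperatures, sample SD (n - 1) and CV, the convention used for
#' table-style fluctuation summaries.
#'
#' @param values numeric vector of per-temperature values.
#' @return list with `mean`, `sd`, `cv`.
#' @export
temperature_stats <- function(values) {
  m <- mean(values)
  s <- if (length(values) >= 2) sample_sd(values) else 0
  list(mean = m, sd = s, cv = if (m != 0) s / m else NA_real_)
}
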