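#' Radial distribution function with periodic boundaries
#'
#' Histogram of minimum-image distances from each reference atom to each
#' target atom, normalized to `g(r) = <n(r)> / (4 pi r^2 dr rho)` with `rho`
#' the bulk target density (mean target count over mean box volume) and r the
#' bin centre, averaged over references and frames. Valid up to half the
#' smallest box edge (minimum-image limit).
#'
#' @param trajectory an [hs_trajectory()] whose frames carry a box.
#' @param ref_selection reference atom indices (e.g. side-chain terminal
#'   carbons).
#' @param target_selection target atom indices (e.g. water oxygens); must be
#'   disjoint from the references.
#' @param dr bin width (Angstrom).
#' @param r_max histogram range; defaults to `min(box)/2 - dr`.
#' @return an `hs_rdf`: list with `r_centers`, `g`, `raw_counts`, `n_ref`,
#'   `n_frames`, `bulk_density`, `dr`.
#' @export
rdf <- function(trajectory, ref_selection, target_selection, dr = 0.1,
                r_max = NULL) {
  if (!length(ref_selection)) stop("reference selection is empty")
  if (!length(target_selection)) stop("target selection is empty")
  if (length(intersect(ref_selection, target_selection)))
    stop("reference and target selections must be disjoint")
  if (dr <= 0) stop("dr must be > 0")
  boxes <- lapply(trajectory$frames, function(f) f$box)
  if (any(vapply(boxes, is.null, logical(1))))
    stop("rdf requires a periodic box on every frame")
  min_edge <- min(vapply(boxes, min, numeric(1)))
  if (is.null(r_max)) r_max <- min_edge / 2 - dr
  if (r_max > min_edge / 2 + 1e-9)
    stop(sprintf("r_max = %.3f exceeds the minimum-image limit min(box)/2 = %.3f",
                 r_max, min_edge / 2))
  nbins <- floor(r_max / dr + 1e-9)
  if (nbins < 1) stop("r_max too small for the requested dr")
  counts <- integer(nbins)
  vols <- numeric(length(trajectory$frames))
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    counts <- counts + cpp_dist_hist_pbc(
      f$coords[ref_selection, , drop = FALSE],
      f$coords[target_selection, , drop = FALSE],
      f$box, dr, nbins, FALSE)
    vols[i] <- prod(f$box)
  }
  n_frames <- length(trajectory$frames)
  rho <- length(target_selection) / mean(vols)
  r_centers <- (seq_len(nbins) - 0.5) * dr
  shell_vol <- 4 * pi * r_centers^2 * dr
  g <- counts / (n_frames * length(ref_selection) * shell_vol * rho)
  structure(list(r_centers = r_centers, g = g, raw_counts = counts,
                 n_ref = length(ref_selection), n_frames = n_frames,
                 bulk_density = rho, dr = dr), class = "hs_rdf")
}

#' Average RDFs over replicates
#'
#' Averages g(r) curves computed on a shared radial grid (the default
#' replicate-handling order: average g first, then detect peaks).
#'
#' @param rdfs list of `hs_rdf` objects with identical grids.
#' @return an `hs_rdf` with summed counts and averaged g.
#' @export
rdf_average <- function(rdfs) {
  if (!length(rdfs)) stop("no RDFs to average")
  r0 <- rdfs[[1]]$r_centers
  for (x in rdfs) if (length(x$r_centers) != length(r0) || any(abs(x$r_centers - r0) > 1e-9))
    stop("RDF grids differ; recompute with shared dr and r_max")
  g <- Reduce(`+`, lapply(rdfs, `[[`, "g")) / length(rdfs)
  structure(list(r_centers = r0, g = g,
                 raw_counts = Reduce(`+`, lapply(rdfs, `[[`, "raw_counts")),
                 n_ref = rdfs[[1]]$n_ref,
                 n_frames = sum(vapply(rdfs, `[[`, numeric(1), "n_frames")),
                 bulk_density = mean(vapply(rdfs, `[[`, numeric(1), "bulk_density")),
                 dr = rdfs[[1]]$dr), class = "hs_rdf")
}

#' First solvation-shell peak
#'
#' Peak of g(r) inside the first-shell radial window after optional 3-point
#' moving-average smoothing: the global maximum within the window, required
#' to also be an interior local maximum of the full curve (its immediate
#' neighbours, inside the window or not, must not exceed it). A monotone
#' decreasing profile therefore reports no peak - a valid outcome distinct
#' from an error - and exact ties resolve to the smallest r because the scan
#' takes the first maximum. The interior-local-maximum requirement rather
#' than a literal "first local maximum anywhere in the window" makes the
#' detector robust to counting noise on the flat approach to the shell.
#'
#' @param x an `hs_rdf`, or a list/data.frame with `r_centers`/`g`.
#' @param r_window search window in Angstrom, default `c(2, 5.5)` around the
#'   typical ~3.6 Angstrom hydrophobic hydration shell.
#' @param smooth apply 3-point smoothing before the search.
#' @return list with `found`, `r`, `g` (intensity on the smoothed curve when
#'   `smooth = TRUE`) and `g_raw` (unsmoothed g at the same bin; the 3-point
#'   average attenuates narrow shells slightly, so planted-amplitude
#'   comparisons use this field). All NA when not found.
#' @export
first_peak <- function(x, r_window = c(2, 5.5), smooth = TRUE) {
  r <- x$r_centers; g <- x$g
  if (length(r) < 3) stop("need at least 3 bins")
  gs <- if (smooth) smooth3(g) else g
  in_win <- which(r >= r_window[1] & r <= r_window[2])
  none <- list(found = FALSE, r = NA_real_, g = NA_real_, g_raw = NA_real_)
  if (!length(in_win)) return(none)
  n <- length(gs)
  is_lmax <- function(i) {
    left <- if (i > 1) gs[i - 1] else Inf     # grid edge cannot be a peak
    right <- if (i < n) gs[i + 1] else Inf
    gs[i] > left && gs[i] >= right
  }
  i <- in_win[which.max(gs[in_win])]          # ties: which.max takes smallest r
  if (is_lmax(i))
    return(list(found = TRUE, r = r[i], g = gs[i], g_raw = g[i]))
  # window maximum sits on a window edge (curve still rising/falling there):
  # fall back to the highest interior local maximum, if any
  cand <- in_win[vapply(in_win, is_lmax, logical(1))]
  if (length(cand)) {
    i <- cand[which.max(gs[cand])]
    return(list(found = TRUE, r = r[i], g = gs[i], g_raw = g[i]))
  }
  none
}

smooth3 <- function(g) {
  n <- length(g)
  out <- g
  if (n >= 3) out[2:(n - 1)] <- (g[1:(n - 2)] + g[2:(n - 1)] + g[3:n]) / 3
  out
}

new_peak_curve <- function(temperatures, r_peak, intensity) {
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(data.frame(temperature = temperatures, r_peak = r_peak,
                       intensity = intensity), class = c("hs_peak_curve", "data.frame"))
}

#' First-peak intensity versus temperature
#'
#' Applies [first_peak()] with one shared window to per-temperature RDFs and
#' tabulates the curve that the crossing-temperature statistic consumes.
#' Input order does not matter; the curve is sorted by temperature. Missing
#' peaks are recorded as NA.
#'
#' @param rdfs list of `hs_rdf` objects.
#' @param temperatures matching temperatures (K).
#' @param r_window,smooth passed to [first_peak()].
#' @return an `hs_peak_curve` data.frame: `temperature`, `r_peak`, `intensity`.
#' @export
peak_intensity_curve <- function(rdfs, temperatures, r_window = c(2, 5.5),
                                 smooth = TRUE) {
  if (length(rdfs) != length(temperatures))
    stop("rdfs and temperatures must have equal length")
  o <- order(temperatures)
  pk <- lapply(rdfs[o], first_peak, r_window = r_window, smooth = smooth)
  new_peak_curve(temperatures[o],
                 vapply(pk, `[[`, numeric(1), "r"),
                 vapply(pk, `[[`, numeric(1), "g"))
}

#' Crossing temperature of the first-shell intensity (TCRP)
#'
#' The temperature at which the first-hydration-shell peak intensity drops
#' below the bulk value g(r) = 1: the first adjacent temperature pair with
#' `g(Ti) >= threshold > g(Ti+1)` is located and the crossing is linearly
#' interpolated inside it. When no pair brackets the threshold (e.g. every
#' intensity stays above 1) the result is "no crossing", which is a valid
#' outcome, not an error.
#'
#' @param curve an `hs_peak_curve` (or data.frame with `temperature` and
#'   `intensity`).
#' @param threshold bulk-density threshold, default 1.0.
#' @return an `hs_tcrp`: list with `found`, `tcrp` (K, NA if none),
#'   `bracket` (length-2 K), `method`.
#' @export
tcrp <- function(curve, threshold = 1.0) {
  tt <- curve$temperature; g <- curve$intensity
  if (any(!is.finite(g))) stop("non-finite peak intensity in curve")
  if (length(tt) >= 2 && any(diff(tt) <= 0)) stop("temperatures must be strictly increasing")
  if (length(tt) >= 2) {
    for (i in seq_len(length(tt) - 1)) {
      if (g[i] >= threshold && g[i + 1] < threshold) {
        t_cross <- tt[i] + (g[i] - threshold) / (g[i] - g[i + 1]) * (tt[i + 1] - tt[i])
        return(structure(list(found = TRUE, tcrp = t_cross,
                              bracket = c(tt[i], tt[i + 1]),
                              method = "linear_interpolation"), class = "hs_tcrp"))
      }
    }
  }
  structure(list(found = FALSE, tcrp = NA_real_, bracket = c(NA_real_, NA_real_),
                 method = "linear_interpolation"), class = "hs_tcrp")
}

#' @export
print.hs_tcrp <- function(x, ...) {
  if (x$found)
    cat(sprintf("TCRP = %.1f K (bracketed by %g and %g K, %s)\n",
                x$tcrp, x$bracket[1], x$bracket[2], x$method))
  else cat("TCRP: no crossing (intensity never drops below threshold)\n")
  invisible(x)
}
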