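#' Areal concentration histogram of settled tracers
#'
#' Bins the settled tracers along the floor in half-open bins `[x, x + dx)`
#' and normalizes by the uniform-settling value `n0 = N/(L dz)`, giving
#' `n/n0 = counts * L / (N dx)` per bin (the out-of-plane thickness cancels).
#' The maximal possible value, all tracers in one bin, is `L/dx`.
#'
#' @param ens A [initialize_tracers()] ensemble.
#' @param dom A [domain()] object.
#' @param dx Bin width (m); default the reference analysis width 2.5e-4 m.
#'   If it does not divide `L`, the last bin is truncated and the histogram
#'   is flagged with attribute `truncated`.
#' @param t Evaluation time (s), recorded on the histogram.
#' @return An object of class `cc_histogram`.
#' @export
areal_concentration <- function(ens, dom, dx = 2.5e-4, t = NA_real_) {
  if (dx <= 0) stop("bin width dx must be positive")
  nbin <- ceiling(dom$L / dx - 1e-9)
  edges <- c((0:(nbin - 1)) * dx, dom$L)
  truncated <- abs(nbin * dx - dom$L) > 1e-9 * dom$L
  xs <- ens$x[ens$settled]
  counts <- if (length(xs) == 0) integer(nbin)
            else tabulate(pmin(floor(xs / dx) + 1L, nbin), nbins = nbin)
  structure(list(bin_edges = edges,
                 centers = (edges[-length(edges)] + edges[-1]) / 2,
                 counts = counts,
                 n_over_n0 = counts * dom$L / (ens$N * dx),
                 dx = dx, t = t, N = ens$N, L = dom$L),
            class = "cc_histogram", truncated = truncated)
}

#' Position of the tracer pile
#'
#' Centre of the bin with maximal `n/n0`; ties are broken toward smaller x
#' (the leftmost maximal bin).
#'
#' @param h A [areal_concentration()] histogram with at least one nonzero bin.
#' @return Peak position (m).
#' @export
find_peak <- function(h) {
  if (all(h$counts == 0)) stop("empty histogram: no settled tracers to locate")
  h$centers[which.max(h$n_over_n0)]
}

#' Maximal horizontal velocity per column
#'
#' For each x-column of the grid, the maximum over y of the horizontal
#' velocity; its decay with x traces the extent of the convective roll.
#'
#' @param flow A [fluid_field()] object.
#' @return Numeric vector of length `Nx` (m s^-1) with the column centres
#'   (m) as attribute `x`.
#' @export
max_ux_profile <- function(flow) {
  prof <- apply(flow$ux, 1, max)
  attr(prof, "x") <- (seq_len(flow$Nx) - 0.5) * flow$dx
  prof
}

#' Downstream extent of the convective vortex
#'
#' The smallest x beyond which the maximal-horizontal-velocity profile stays
#' below the threshold: 0 if it never reaches it, the domain length if it
#' never drops below it. Suspended tracers pile up near this edge, where the
#' forward flow becomes negligible.
#'
#' @param profile A [max_ux_profile()] vector (attribute `x` gives the
#'   column centres; otherwise supply `x`).
#' @param threshold Velocity threshold (m s^-1), positive. A common choice
#'   is a few percent of the profile maximum.
#' @param x Column centre positions (m), if not carried by `profile`.
#' @return Position (m).
#' @export
vortex_extent <- function(profile, threshold, x = attr(profile, "x")) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(x)) stop("profile carries no x coordinates")
  above <- which(profile >= threshold)
  if (length(above) == 0) return(0)
  i <- max(above)
  if (i == length(profile)) return(x[i] + (x[2] - x[1]) / 2)
  (x[i] + x[i + 1]) / 2
}
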