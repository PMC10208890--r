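#' Per-residue root-mean-square fluctuation
#'
#' \code{RMSF(j) = sqrt(mean over frames of |x_j(i) - <x_j>|^2)} with
#' \code{<x_j>} the per-residue mean position over all frames, computed on
#' the selected atom after rigid-body superposition. For isotropic Gaussian
#' noise of SD sigma per coordinate the expectation is \code{sigma*sqrt(3)}.
#'
#' @param traj a \code{backbone_trajectory} with at least 2 frames.
#' @param selection atom used, default \code{"CA"}; \code{"backbone"}
#'   averages the four backbone atoms' fluctuations.
#' @param superpose superpose frames first (two-pass mean-structure
#'   protocol); set FALSE if the trajectory is already fitted.
#' @return object of class \code{flex_profile}: data.frame with
#'   \code{chain}, \code{resid}, \code{rmsf} (Angstrom) plus attributes
#'   \code{selection}, \code{n_frames}.
#' @export
compute_rmsf <- function(traj, selection = "CA", superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF undefined for fewer than 2 frames")
  if (superpose) traj <- superpose_frames(traj)
  atoms <- if (identical(selection, "backbone")) 1:4 else
    match(match.arg(selection, BACKBONE_ATOMS), BACKBONE_ATOMS)
  msf <- 0
  for (a in atoms) {
    x <- traj$coords[, a, , , drop = FALSE]
    dim(x) <- c(dim(x)[1], 3, nf)
    mu <- apply(x, c(1, 2), mean)
    msf <- msf + apply((x - array(mu, dim(x)))^2, 1, sum) / nf
  }
  out <- data.frame(chain = traj$residues$chain, resid = traj$residues$resid,
                    rmsf = sqrt(msf / length(atoms)), stringsAsFactors = FALSE)
  attr(out, "selection") <- selection
  attr(out, "n_frames") <- nf
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' Difference of two per-residue profiles (variant minus wild type)
#'
#' @param wt,variant named numeric vectors, or data.frames carrying a
#'   per-residue value column (e.g. \code{flex_profile}s); residue sets
#'   must match.
#' @param value column name used when data.frames are supplied.
#' @return named numeric vector of differences (variant - wt), names are
#'   residue keys.
#' @export
delta_profile <- function(wt, variant, value = "rmsf") {
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      v <- x[[value]]
      names(v) <- residue_key(x$chain, x$resid)
      v
    } else x
  }
  a <- as_vec(wt)
  b <- as_vec(variant)
  if (is.null(names(a)) || is.null(names(b)))
    stop("profiles must be named by residue")
  if (!identical(names(a), names(b)))
    stop("residue sets differ between profiles")
  b - a
}

#' Hotspot residues of a difference profile
#'
#' Residues whose value is at least \code{k} standard deviations above the
#' mean of the profile (population SD by default; the conventional 2-sigma
#' call for delta-RMSF and delta-EEC maps). An all-equal profile has zero
#' SD and yields an empty set.
#'
#' @param delta named numeric vector (residue keys to values).
#' @param k sigma multiplier (default 2).
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return character vector of residue keys passing the threshold.
#' @export
hotspots <- function(delta, k = 2, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- delta[is.finite(delta)]
  if (length(v) < 3L) stop("need at least 3 residues with defined values")
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (!is.finite(s) || s == 0) return(character(0))
  names(v)[v >= mean(v) + k * s]
}
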