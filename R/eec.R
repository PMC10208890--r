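#' Per-residue electrostatic energy time series
#'
#' Symmetrizes the directed Kabsch-Sander energies into per-pair couplings
#' \code{e_ij(t) = E(i->j, t) + E(j->i, t)} and sums each residue's
#' couplings over its unmasked partners, giving the total electrostatic
#' energy series \code{E_i(t)} whose correlations define the allosteric
#' network. Masked entries contribute zero. Passing a trajectory computes
#' the series frame by frame without materializing the full tensor (the
#' memory-light path for long runs); the two routes are identical.
#'
#' @param x an \code{\link{energy_tensor}} or a \code{backbone_trajectory}.
#' @param constants \code{\link{ks_constants}} for the trajectory route.
#' @param include_interchain evaluate cross-chain pairs (trajectory route).
#' @return F x R numeric matrix; residues with no unmasked partner carry an
#'   \code{"isolated"} attribute listing them.
#' @export
residue_energy_series <- function(x, constants = ks_constants(),
                                  include_interchain = TRUE) {
  if (inherits(x, "energy_tensor")) {
    E <- x$energies
    R <- dim(E)[1]
    nf <- dim(E)[3]
    ser <- matrix(0, nf, R)
    for (f in seq_len(nf)) {
      ef <- E[, , f]
      ef[is.na(ef)] <- 0
      s <- ef + t(ef)
      ser[f, ] <- rowSums(s)
    }
    iso <- which(rowSums(x$mask | t(x$mask)) == 0)
  } else {
    stopifnot(inherits(x, "backbone_trajectory"))
    res <- x$residues
    R <- nrow(res)
    nf <- n_frames(x)
    mask <- ks_pair_mask(res, include_interchain)
    ser <- matrix(0, nf, R)
    for (f in seq_len(nf)) {
      fr <- x$coords[, , , f]
      H <- place_amide_hydrogens(x, f)
      Hf <- H
      Hf[is.na(Hf)] <- 0
      Nc <- matrix(fr[, 1, ], R, 3)
      Cc <- matrix(fr[, 3, ], R, 3)
      Oc <- matrix(fr[, 4, ], R, 3)
      e <- constants$coupling *
        (1 / dist_mat(Nc, Oc) + 1 / dist_mat(Hf, Cc) -
         1 / dist_mat(Nc, Cc) - 1 / dist_mat(Hf, Oc))
      e[!mask] <- 0
      ser[f, ] <- rowSums(e + t(e))
    }
    iso <- which(rowSums(mask | t(mask)) == 0)
  }
  attr(ser, "isolated") <- iso
  ser
}

#' Correlation adjacency matrix of the electrostatic network
#'
#' \code{a(i, j) = |Pearson correlation(E_i(t), E_j(t))|} for distinct
#' residues, zero on the diagonal. Pairs where either series has zero
#' variance get weight zero with a warning. An alternative mode weights
#' edges by mean absolute pair coupling instead of correlation (sensitivity
#' analysis for the network construction).
#'
#' @param series F x R matrix from \code{\link{residue_energy_series}}.
#' @param mode \code{"correlation"} (default) or \code{"energy"}.
#' @param tensor required for \code{mode = "energy"}: the
#'   \code{\link{energy_tensor}} whose mean absolute symmetrized couplings
#'   are used, normalized to [0, 1].
#' @return symmetric R x R matrix with entries in [0, 1], zero diagonal.
#' @export
build_adjacency <- function(series, mode = c("correlation", "energy"),
                            tensor = NULL) {
  mode <- match.arg(mode)
  if (mode == "energy") {
    stopifnot(inherits(tensor, "energy_tensor"))
    E <- tensor$energies
    E[is.na(E)] <- 0
    m <- apply(abs(E + aperm(E, c(2, 1, 3))), c(1, 2), mean)
    diag(m) <- 0
    if (max(m) > 0) m <- m / max(m)
    return(m)
  }
  if (nrow(series) < 10L) stop("need at least 10 frames to correlate")
  v <- apply(series, 2, stats::var)
  flat <- v < .Machine$double.eps
  if (any(flat))
    warning(length(which(flat)), " residue series with zero variance; edges set to 0")
  a <- suppressWarnings(abs(stats::cor(series)))
  a[flat, ] <- 0
  a[, flat] <- 0
  diag(a) <- 0
  a[!is.finite(a)] <- 0
  a
}

#' Eigenvector centrality of a non-negative symmetric network
#'
#' Principal eigenvector by shifted power iteration (iterating A + I, which
#' has the same eigenvectors as A but a strictly dominant top eigenvalue
#' even for bipartite graphs, whose +/-lambda pairs stall the plain
#' iteration) from a uniform start vector - deterministic and
#' bit-reproducible - normalized to unit Euclidean norm with non-negative
#' sign. Perron-Frobenius guarantees a non-negative principal eigenvector
#' for a connected non-negative matrix.
#'
#' @param adjacency symmetric non-negative matrix (zero diagonal).
#' @param tol convergence tolerance on the successive-iterate infinity
#'   norm (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return object of class \code{centrality_profile}: list with
#'   \code{centrality} (unit-norm non-negative vector), \code{converged},
#'   \code{iterations}.
#' @export
eigenvector_centrality <- function(adjacency, tol = 1e-10, max_iter = 10000L) {
  A <- as.matrix(adjacency)
  if (any(A < 0) || any(!is.finite(A))) stop("adjacency must be finite and non-negative")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (all(A == 0)) stop("all-zero adjacency: centrality undefined")
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v2 <- as.vector(A %*% v) + v  # shifted iteration: (A + I) v
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) stop("power iteration annihilated the start vector")
    v2 <- v2 / nrm
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      converged <- TRUE
      break
    }
    v <- v2
  }
  if (!converged) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    gap <- if (n >= 2) abs(ev[1]) - abs(ev[2]) else NA_real_
    stop(sprintf(
      "power iteration did not converge in %d iterations (spectral gap %.3g)",
      max_iter, gap))
  }
  if (sum(v) < 0) v <- -v
  v[abs(v) < tol] <- 0
  if (any(v < 0))
    warning("negative centrality components (disconnected network?); check adjacency")
  structure(list(centrality = abs(v), converged = converged, iterations = it),
            class = "centrality_profile")
}

#' @export
print.centrality_profile <- function(x, ...) {
  cat(sprintf("Eigenvector centrality: %d residues, converged in %d iteration(s)\n",
              length(x$centrality), x$iterations))
  invisible(x)
}

#' Centrality difference profile and hotspot calls
#'
#' \code{delta = variant - wt} per residue, with hotspots called on the
#' increase side at \code{mean + k * sigma} (residues whose importance to
#' the electrostatic network grows upon mutation); decreases are reported
#' separately and not thresholded.
#'
#' @param wt,variant \code{centrality_profile}s over the same residues, or
#'   plain numeric vectors of equal length.
#' @param k sigma multiplier for the hotspot call (default 2).
#' @param residue_keys optional character keys naming the residues.
#' @return list with \code{delta} (named vector), \code{hotspots}
#'   (keys of >= k-sigma increases), \code{decreases} (keys with
#'   delta < 0).
#' @export
delta_eec <- function(wt, variant, k = 2, residue_keys = NULL) {
  cw <- if (inherits(wt, "centrality_profile")) wt$centrality else wt
  cv <- if (inherits(variant, "centrality_profile")) variant$centrality else variant
  if (length(cw) != length(cv)) stop("residue sets differ between profiles")
  if (is.null(residue_keys)) residue_keys <- as.character(seq_along(cw))
  d <- stats::setNames(cv - cw, residue_keys)
  list(delta = d, hotspots = hotspots(d, k = k),
       decreases = names(d)[d < 0])
}
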