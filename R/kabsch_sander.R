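#' Kabsch-Sander electrostatic constants
#'
#' Partial charges and dimensionality factor of the backbone hydrogen-bond
#' electrostatic energy: 0.42 e on the carbonyl group, 0.20 e on the amide
#' group, and f = 332 kcal A/mol, giving q1*q2*f = 27.888 kcal A/mol.
#' A minimum-distance guard flags steric clashes instead of letting 1/d
#' terms blow up.
#'
#' @param q1 carbonyl partial charge (e).
#' @param q2 amide partial charge (e).
#' @param f dimensionality factor (kcal A/mol).
#' @param min_distance clash guard in Angstrom (default 0.5).
#' @return object of class \code{ks_constants}.
#' @export
ks_constants <- function(q1 = 0.42, q2 = 0.20, f = 332, min_distance = 0.5) {
  structure(list(q1 = q1, q2 = q2, f = f, min_distance = min_distance,
                 coupling = q1 * q2 * f),
            class = "ks_constants")
}

#' Kabsch-Sander energy from the four donor/acceptor distances
#'
#' \code{E = q1 q2 f (1/dON + 1/dCH - 1/dCN - 1/dOH)} in kcal/mol, where O
#' and C belong to the acceptor's carbonyl group and N and H to the donor's
#' amide group. The energy is homogeneous of degree -1 in the distances and
#' vanishes when dON = dCN and dCH = dOH.
#'
#' @param d_on,d_ch,d_cn,d_oh interatomic distances in Angstrom
#'   (vectorized).
#' @param constants a \code{\link{ks_constants}}.
#' @return energy in kcal/mol; \code{NA} where any distance is below the
#'   clash guard.
#' @export
ks_energy <- function(d_on, d_ch, d_cn, d_oh, constants = ks_constants()) {
  e <- constants$coupling * (1 / d_on + 1 / d_ch - 1 / d_cn - 1 / d_oh)
  clash <- d_on < constants$min_distance | d_ch < constants$min_distance |
    d_cn < constants$min_distance | d_oh < constants$min_distance
  e[clash] <- NA_real_
  e
}

#' Reconstruct amide hydrogen positions for one frame
#'
#' Standard DSSP reconstruction: \code{H(i) = N(i) + u} where u is the unit
#' vector from the previous residue's carbonyl O toward its C, i.e. an N-H
#' bond of 1.0 A anti-parallel to the preceding C=O. Chain-start residues
#' and prolines carry no amide hydrogen and get \code{NA} rows.
#'
#' @param traj a \code{backbone_trajectory}.
#' @param frame frame index.
#' @return R x 3 matrix of H coordinates (Angstrom), \code{NA} where no H
#'   exists.
#' @export
place_amide_hydrogens <- function(traj, frame = 1L) {
  fr <- frame_coords(traj, frame)
  res <- traj$residues
  R <- nrow(res)
  H <- matrix(NA_real_, R, 3)
  if (R < 2L) return(H)
  prev_ok <- c(FALSE, res$chain[-1] == res$chain[-R])
  donors <- which(prev_ok & res$resname != "PRO")
  if (length(donors)) {
    v <- fr[donors - 1L, 3, , drop = FALSE] - fr[donors - 1L, 4, , drop = FALSE]
    v <- matrix(v, length(donors), 3)
    len <- sqrt(rowSums(v^2))
    if (any(len < 1e-6)) stop("degenerate C=O bond; cannot place amide H")
    H[donors, ] <- matrix(fr[donors, 1, ], length(donors), 3) + v / len
  }
  H
}

# donor validity and pair mask shared by energy_tensor and the DSSP layer.
# Masked pairs: identical residue, sequence-adjacent within a chain
# (|i-j| <= 1; no backbone H-bond is possible), donors without amide H.
ks_pair_mask <- function(residues, include_interchain = TRUE) {
  R <- nrow(residues)
  prev_ok <- c(FALSE, residues$chain[-1] == residues$chain[-R])
  has_h <- prev_ok & residues$resname != "PRO"
  mask <- matrix(TRUE, R, R)          # TRUE = pair evaluated (donor x acceptor)
  mask[!has_h, ] <- FALSE
  diag(mask) <- FALSE
  same_chain <- outer(residues$chain, residues$chain, "==")
  adj <- abs(outer(seq_len(R), seq_len(R), "-")) == 1L
  mask[adj & same_chain] <- FALSE
  if (!include_interchain) mask[!same_chain] <- FALSE
  mask
}

#' Kabsch-Sander energy tensor of a trajectory
#'
#' Evaluates the directed donor-to-acceptor electrostatic energy for every
#' unmasked ordered residue pair in every frame, producing an R x R x F
#' array (kcal/mol) indexed [donor, acceptor, frame]. Chain-start residues
#' and prolines cannot donate; identical and sequence-adjacent pairs are
#' masked. Distances below the clash guard yield either an \code{NA}
#' sentinel plus a clash report (default) or the DSSP-compatible clamp.
#'
#' @param traj a \code{backbone_trajectory}.
#' @param constants a \code{\link{ks_constants}}.
#' @param clash \code{"sentinel"} (NA + report) or \code{"clamp"} (fixed
#'   minimum energy, DSSP convention).
#' @param clamp_energy energy used in clamp mode (kcal/mol).
#' @param include_interchain evaluate pairs across chains (default TRUE;
#'   relevant for oligomers whose termini pack at subunit interfaces).
#' @return object of class \code{energy_tensor}: list with \code{energies}
#'   (R x R x F, NA at masked entries), \code{mask}, \code{residues},
#'   \code{clashes} (data.frame).
#' @export
energy_tensor <- function(traj, constants = ks_constants(),
                          clash = c("sentinel", "clamp"),
                          clamp_energy = -9.9, include_interchain = TRUE) {
  clash <- match.arg(clash)
  res <- traj$residues
  R <- nrow(res)
  nf <- n_frames(traj)
  mask <- ks_pair_mask(res, include_interchain)
  E <- array(NA_real_, c(R, R, nf))
  clashes <- list()
  for (f in seq_len(nf)) {
    fr <- traj$coords[, , , f]
    H <- place_amide_hydrogens(traj, f)
    Nc <- matrix(fr[, 1, ], R, 3)
    Cc <- matrix(fr[, 3, ], R, 3)
    Oc <- matrix(fr[, 4, ], R, 3)
    Hf <- H
    Hf[is.na(Hf)] <- 0  # masked anyway
    d_on <- dist_mat(Nc, Oc)   # [donor N, acceptor O]
    d_cn <- dist_mat(Nc, Cc)
    d_oh <- dist_mat(Hf, Oc)
    d_ch <- dist_mat(Hf, Cc)
    e <- constants$coupling * (1 / d_on + 1 / d_ch - 1 / d_cn - 1 / d_oh)
    md <- constants$min_distance
    cl <- (d_on < md | d_ch < md | d_cn < md | d_oh < md) & mask
    if (any(cl)) {
      idx <- which(cl, arr.ind = TRUE)
      clashes[[length(clashes) + 1L]] <-
        data.frame(frame = f, donor = idx[, 1], acceptor = idx[, 2])
      e[cl] <- if (clash == "clamp") clamp_energy else NA_real_
    }
    e[!mask] <- NA_real_
    E[, , f] <- e
  }
  structure(list(energies = E, mask = mask, residues = res,
                 clashes = if (length(clashes)) do.call(rbind, clashes)
                           else data.frame(frame = integer(0),
                                           donor = integer(0),
                                           acceptor = integer(0)),
                 constants = constants),
            class = "energy_tensor")
}

#' @export
print.energy_tensor <- function(x, ...) {
  d <- dim(x$energies)
  cat(sprintf("Kabsch-Sander energy tensor: %d x %d residues, %d frame(s); %d clash(es)\n",
              d[1], d[2], d[3], nrow(x$clashes)))
  invisible(x)
}
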