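SS3_CLASSES <- c("helix", "strand", "coil")

# Hydrogen bond indicator from one frame's energy matrix:
# hb[i, j] TRUE when the carbonyl of residue i accepts the amide H of
# residue j, i.e. E[donor = j, acceptor = i] < cutoff.
hbond_matrix <- function(E, cutoff = -0.5) {
  hb <- t(E) < cutoff
  hb[is.na(hb)] <- FALSE
  hb
}

#' Assign per-residue secondary structure for one frame
#'
#' Minimal Kabsch-Sander assignment from backbone H-bond patterns: an
#' H-bond is declared below the -0.5 kcal/mol cutoff; n-turns (n = 3, 4, 5)
#' where the carbonyl of residue i accepts from residue i+n; two
#' consecutive turns of matching stride define 3-10 (G), alpha (H), and pi
#' (I) helices; parallel/antiparallel bridge patterns define strands, with
#' bridges extended to ladders (E) and isolated bridges kept as B. The
#' priority cascade is H > E > G > I > B; everything else is coil. Bend and
#' turn states of the full assignment are not distinguished (they collapse
#' to coil in the 3-state simplification used downstream). The 8-to-3
#' mapping is H,G,I -> helix; E,B -> strand; else coil.
#'
#' @param tensor an \code{\link{energy_tensor}}.
#' @param frame frame index.
#' @param cutoff H-bond energy cutoff in kcal/mol (default -0.5).
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{class8} (H/G/I/E/B/-), \code{class3} (helix/strand/coil).
#' @export
assign_secondary_structure <- function(tensor, frame = 1L, cutoff = -0.5) {
  stopifnot(inherits(tensor, "energy_tensor"))
  E <- tensor$energies[, , frame]
  res <- tensor$residues
  lab <- dssp_labels_frame(E, res$chain, cutoff)
  data.frame(chain = res$chain, resid = res$resid, class8 = lab,
             class3 = map_ss3(lab), stringsAsFactors = FALSE)
}

map_ss3 <- function(lab) {
  ifelse(lab %in% c("H", "G", "I"), "helix",
         ifelse(lab %in% c("E", "B"), "strand", "coil"))
}

dssp_labels_frame <- function(E, chain, cutoff = -0.5) {
  R <- nrow(E)
  hb <- hbond_matrix(E, cutoff)
  same_run <- function(i, j) {
    # TRUE when i..j are consecutive residues of one chain (no break)
    chain[i] == chain[j]
  }
  turns <- list()
  for (n in 3:5) {
    t <- rep(FALSE, R)
    for (i in seq_len(max(0, R - n)))
      if (same_run(i, i + n) && hb[i, i + n]) t[i] <- TRUE
    turns[[n]] <- t
  }
  interior <- function(i) i > 1L && i < R && chain[i - 1] == chain[i] &&
    chain[i + 1] == chain[i]
  bridgeP <- matrix(FALSE, R, R)
  bridgeA <- matrix(FALSE, R, R)
  for (i in seq_len(R)) {
    if (!interior(i)) next
    for (j in seq_len(R)) {
      if (abs(i - j) < 3 && chain[i] == chain[j]) next
      if (!interior(j)) next
      if ((hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1]))
        bridgeP[i, j] <- TRUE
      if ((hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1]))
        bridgeA[i, j] <- TRUE
    }
  }
  isb <- bridgeP | bridgeA
  strand <- rep("-", R)
  for (i in seq_len(R)) {
    js <- which(isb[i, ])
    if (!length(js)) next
    ext <- FALSE
    for (j in js) {
      if (i + 1L <= R && ((j + 1L <= R && isb[i + 1, j + 1]) ||
                          (j - 1L >= 1L && isb[i + 1, j - 1]))) ext <- TRUE
      if (i - 1L >= 1L && ((j + 1L <= R && isb[i - 1, j + 1]) ||
                           (j - 1L >= 1L && isb[i - 1, j - 1]))) ext <- TRUE
    }
    strand[i] <- if (ext) "E" else "B"
  }
  lab <- rep("-", R)
  mark_helix <- function(lab, n, code) {
    t <- turns[[n]]
    for (i in 2:max(2, R - n))
      if (i > 1L && t[i - 1] && t[i] && same_run(i - 1, i + n))
        for (k in i:(i + n - 1L)) if (lab[k] == "-") lab[k] <- code
    lab
  }
  if (R > 5L) lab <- mark_helix(lab, 4L, "H")
  lab[strand == "E" & lab == "-"] <- "E"
  if (R > 4L) lab <- mark_helix(lab, 3L, "G")
  if (R > 6L) lab <- mark_helix(lab, 5L, "I")
  lab[strand == "B" & lab == "-"] <- "B"
  lab
}

#' Per-residue secondary-structure probabilities over a trajectory
#'
#' Assigns 3-state secondary structure to every residue in every frame and
#' reduces to the fraction of frames spent in each class. Fractions sum to
#' one per residue by construction and are invariant to frame order.
#'
#' @param x a \code{backbone_trajectory} or an \code{\link{energy_tensor}}.
#' @param cutoff H-bond energy cutoff (kcal/mol).
#' @param constants \code{\link{ks_constants}} used when \code{x} is a
#'   trajectory.
#' @return object of class \code{ss_profile}: list with \code{prob}
#'   (R x 3 matrix, columns helix/strand/coil), \code{labels} (F x R
#'   character matrix of 3-state labels), \code{residues}.
#' @export
ss_probabilities <- function(x, cutoff = -0.5, constants = ks_constants()) {
  tensor <- if (inherits(x, "energy_tensor")) x else
    energy_tensor(x, constants, clash = "clamp")
  res <- tensor$residues
  nf <- dim(tensor$energies)[3]
  R <- nrow(res)
  labels <- matrix(NA_character_, nf, R)
  for (f in seq_len(nf))
    labels[f, ] <- map_ss3(dssp_labels_frame(tensor$energies[, , f],
                                             res$chain, cutoff))
  prob <- sapply(SS3_CLASSES, function(cl) colMeans(labels == cl))
  prob <- matrix(prob, R, 3, dimnames = list(NULL, SS3_CLASSES))
  structure(list(prob = prob, labels = labels, residues = res),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat(sprintf("Secondary-structure profile: %d residues, %d frame(s)\n",
              nrow(x$prob), nrow(x$labels)))
  cat(sprintf("mean fractions: helix %.2f, strand %.2f, coil %.2f\n",
              mean(x$prob[, 1]), mean(x$prob[, 2]), mean(x$prob[, 3])))
  invisible(x)
}

#' Per-residue secondary-structure probability differences
#'
#' \code{variant - wt} class-probability differences. Negative helix values
#' mean the variant loses helical structure at that residue (e.g. a
#' helix-to-coil conversion shows up as negative helix and positive coil).
#' The three differences sum to zero per residue.
#'
#' @param wt,variant \code{ss_profile} objects over the same residues.
#' @return data.frame with \code{chain}, \code{resid}, \code{d_helix},
#'   \code{d_strand}, \code{d_coil}.
#' @export
delta_ss <- function(wt, variant) {
  stopifnot(inherits(wt, "ss_profile"), inherits(variant, "ss_profile"))
  if (!identical(residue_key(wt$residues$chain, wt$residues$resid),
                 residue_key(variant$residues$chain, variant$residues$resid)))
    stop("residue sets differ between profiles")
  d <- variant$prob - wt$prob
  data.frame(chain = wt$residues$chain, resid = wt$residues$resid,
             d_helix = d[, "helix"], d_strand = d[, "strand"],
             d_coil = d[, "coil"], stringsAsFactors = FALSE)
}
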