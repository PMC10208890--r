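#' @importFrom stats rnorm sd setNames cor
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Construct a backbone trajectory
#'
#' A backbone trajectory holds the N, CA, C, O coordinates (in Angstrom) of
#' every residue over one or more frames, together with per-residue metadata
#' (chain, residue number, 3-letter name). Residues are keyed by
#' (chain, resid); multi-chain assemblies such as homotrimers are supported.
#'
#' @param coords numeric array of dimension \code{c(R, 4, 3, F)}; the second
#'   dimension is ordered N, CA, C, O and the third is x, y, z.
#' @param residues data.frame with columns \code{chain}, \code{resid},
#'   \code{resname} (3-letter code), one row per residue, ordered by chain
#'   then residue number.
#' @param check validate invariants (finite coordinates, residue names,
#'   CA-CA chain continuity). Continuity violations warn, they do not fail.
#' @return object of class \code{backbone_trajectory}.
#' @export
backbone_trajectory <- function(coords, residues, check = TRUE) {
  if (length(dim(coords)) == 3L) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 4L, dim(coords)[2] == 4L, dim(coords)[3] == 3L)
  residues$chain <- as.character(residues$chain)
  residues$resid <- as.integer(residues$resid)
  residues$resname <- as.character(residues$resname)
  if (nrow(residues) != dim(coords)[1])
    stop("residue table does not match coordinate array")
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"), NULL)
  obj <- structure(list(coords = coords, residues = residues),
                   class = "backbone_trajectory")
  if (check) validate_trajectory(obj)
  obj
}

validate_trajectory <- function(traj) {
  co <- traj$coords
  if (!all(is.finite(co))) stop("non-finite coordinates in trajectory")
  res <- traj$residues
  bad <- !(res$resname %in% AA3)
  if (any(bad))
    stop("non-standard residue name(s): ",
         paste(unique(res$resname[bad]), collapse = ", "))
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    if (any(diff(res$resid[idx]) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  # chain-break check on every frame: consecutive CA-CA < 4.5 A (warn only)
  nf <- n_frames(traj)
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    if (length(idx) < 2L) next
    ca <- co[idx, "CA", , , drop = FALSE]
    dim(ca) <- c(length(idx), 3L, nf)
    d2 <- apply((ca[-1, , , drop = FALSE] - ca[-length(idx), , , drop = FALSE])^2,
                c(1, 3), sum)
    d2 <- matrix(d2, length(idx) - 1L, nf)
    if (any(d2 >= 4.5^2)) {
      w <- which(rowSums(d2 >= 4.5^2) > 0)[1]
      warning(sprintf(
        "possible chain break in chain %s between residues %d and %d (CA-CA >= 4.5 A)",
        ch, res$resid[idx[w]], res$resid[idx[w + 1]]))
    }
  }
  invisible(traj)
}

#' @export
print.backbone_trajectory <- function(x, ...) {
  cat(sprintf("Backbone trajectory: %d residues, %d frame(s), chain(s) %s\n",
              n_residues(x), n_frames(x),
              paste(unique(x$residues$chain), collapse = ", ")))
  invisible(x)
}

#' Number of residues / frames in a trajectory
#' @param traj a \code{backbone_trajectory}.
#' @return integer count.
#' @export
n_residues <- function(traj) dim(traj$coords)[1]

#' @rdname n_residues
#' @export
n_frames <- function(traj) dim(traj$coords)[4]

#' Extract one frame's coordinates
#' @param traj a \code{backbone_trajectory}.
#' @param frame frame index (1-based).
#' @return array \code{c(R, 4, 3)} of coordinates in Angstrom.
#' @export
frame_coords <- function(traj, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  traj$coords[, , , frame, drop = FALSE][, , , 1]
}

#' Read backbone coordinate frames from a file
#'
#' Reads a (possibly multi-model) PDB file, or a plain whitespace-delimited
#' frame table with columns \code{frame chain resid atom x y z}. Only
#' backbone N, CA, C, O atoms are kept; hydrogens and side chains are
#' ignored. Every residue must provide all four backbone atoms in every
#' model. Alternate-location indicators and insertion codes are rejected.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension/content), \code{"pdb"}, or
#'   \code{"xyz"} (frame table).
#' @return a \code{backbone_trajectory}.
#' @export
read_structure_frames <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else {
      first <- readLines(path, n = 1L)
      if (grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST)", first)) "pdb" else "xyz"
    }
  }
  if (format == "pdb") read_pdb_frames(path) else read_xyz_table(path)
}

read_pdb_frames <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB (models may have inconsistent atoms): ",
                         conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT"))
  rows <- which(keep)  # original atom-table rows, for xyz column lookup
  at <- at[keep, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported; renumber the structure first")
  if (any(!is.na(at$alt) & at$alt != ""))
    stop("alternate location indicators are not supported; resolve altlocs first")
  bb <- at$elety %in% BACKBONE_ATOMS
  at <- at[bb, , drop = FALSE]
  rows <- rows[bb]
  if (nrow(at) == 0L) stop("no backbone atoms found")
  at$chain[is.na(at$chain)] <- "A"
  key <- residue_key(at$chain, at$resno)
  resk <- unique(key)
  R <- length(resk)
  ord <- match(resk, key)
  residues <- data.frame(chain = at$chain[ord], resid = at$resno[ord],
                         resname = at$resid[ord], stringsAsFactors = FALSE)
  # row index into 'at' for each residue x atom
  idx <- matrix(NA_integer_, R, 4L)
  for (a in seq_along(BACKBONE_ATOMS)) {
    sub <- which(at$elety == BACKBONE_ATOMS[a])
    idx[match(key[sub], resk), a] <- sub
  }
  if (any(is.na(idx))) {
    miss <- which(is.na(idx), arr.ind = TRUE)[1, ]
    stop(sprintf("residue %s %d (chain %s) is missing backbone atom %s",
                 residues$resname[miss[1]], residues$resid[miss[1]],
                 residues$chain[miss[1]], BACKBONE_ATOMS[miss[2]]))
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  co <- array(NA_real_, c(R, 4L, 3L, nf))
  for (a in 1:4) {
    cols0 <- (rows[idx[, a]] - 1L) * 3L
    for (k in 1:3) co[, a, k, ] <- t(xyz[, cols0 + k, drop = FALSE])
  }
  backbone_trajectory(co, residues)
}

read_xyz_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("frame", "chain", "resid", "atom", "x", "y", "z")
  if (!all(need %in% names(tb)))
    stop("frame table must have columns: ", paste(need, collapse = " "))
  frames <- sort(unique(tb$frame))
  f1 <- tb[tb$frame == frames[1], , drop = FALSE]
  key <- residue_key(f1$chain, f1$resid)
  resk <- unique(key)
  R <- length(resk)
  residues <- data.frame(chain = f1$chain[match(resk, key)],
                         resid = f1$resid[match(resk, key)],
                         resname = if ("resname" %in% names(f1))
                           f1$resname[match(resk, key)] else "ALA",
                         stringsAsFactors = FALSE)
  co <- array(NA_real_, c(R, 4L, 3L, length(frames)))
  for (fi in seq_along(frames)) {
    sub <- tb[tb$frame == frames[fi], , drop = FALSE]
    ri <- match(residue_key(sub$chain, sub$resid), resk)
    ai <- match(sub$atom, BACKBONE_ATOMS)
    ok <- !is.na(ri) & !is.na(ai)
    co[cbind(ri[ok], ai[ok], 1L, fi)] <- sub$x[ok]
    co[cbind(ri[ok], ai[ok], 2L, fi)] <- sub$y[ok]
    co[cbind(ri[ok], ai[ok], 3L, fi)] <- sub$z[ok]
  }
  if (any(is.na(co))) {
    miss <- which(is.na(co[, , 1, 1, drop = FALSE]), arr.ind = TRUE)
    if (nrow(miss) > 0)
      stop(sprintf("residue %s %d is missing backbone atom %s",
                   residues$chain[miss[1, 1]], residues$resid[miss[1, 1]],
                   BACKBONE_ATOMS[miss[1, 2]]))
    stop("incomplete coordinates in frame table")
  }
  backbone_trajectory(co, residues)
}

#' Write a trajectory to a multi-model PDB or frame-table file
#'
#' @param traj a \code{backbone_trajectory}.
#' @param path output file path.
#' @param format \code{"pdb"} (MODEL/ENDMDL records) or \code{"xyz"}
#'   (whitespace frame table, the second dialect read by
#'   \code{\link{read_structure_frames}}).
#' @return invisibly, \code{path}.
#' @export
write_structure_frames <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  res <- traj$residues
  nf <- n_frames(traj)
  R <- n_residues(traj)
  if (format == "xyz") {
    rows <- expand.grid(atom = BACKBONE_ATOMS, residue = seq_len(R),
                        frame = seq_len(nf), stringsAsFactors = FALSE)
    co <- aperm(traj$coords, c(2, 1, 4, 3))  # atom, residue, frame, xyz
    tb <- data.frame(frame = rows$frame, chain = res$chain[rows$residue],
                     resid = res$resid[rows$residue],
                     resname = res$resname[rows$residue], atom = rows$atom,
                     x = c(co[, , , 1]), y = c(co[, , , 2]), z = c(co[, , , 3]))
    utils::write.table(format(tb, digits = 10, trim = TRUE), path,
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    write_pdb_model(con, traj$coords[, , , f], res, bfac = rep(0, R))
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

write_pdb_model <- function(con, frame, residues, bfac) {
  serial <- 0L
  lines <- character(0)
  for (i in seq_len(nrow(residues))) {
    for (a in seq_along(BACKBONE_ATOMS)) {
      serial <- serial + 1L
      nm <- BACKBONE_ATOMS[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, " ", residues$resname[i], residues$chain[i],
        residues$resid[i], frame[i, a, 1], frame[i, a, 2], frame[i, a, 3],
        1.00, bfac[i], substr(nm, 1, 1)))
    }
  }
  writeLines(lines, con)
}

#' Write a per-residue scalar as the B-factor column of a PDB file
#'
#' Writes a single-model PDB in which every atom of a residue carries the
#' residue's scalar value in the B-factor column (two decimals, the PDB
#' field width). Residues without a value get the sentinel 0.00. Useful for
#' painting delta-RMSF, delta-EEC, or CSP maps onto a structure.
#'
#' @param traj a \code{backbone_trajectory}.
#' @param values named numeric vector; names are residue numbers
#'   (single-chain) or \code{"chain:resid"} keys.
#' @param path output path.
#' @param frame frame index to write (default 1).
#' @return invisibly, \code{path}.
#' @export
write_scalar_as_bfactor <- function(traj, values, path, frame = 1L) {
  if (any(!is.finite(values))) stop("non-finite value(s) in B-factor map")
  res <- traj$residues
  keys <- residue_key(res$chain, res$resid)
  nmv <- names(values)
  if (is.null(nmv)) stop("'values' must be a named vector")
  if (!any(grepl(":", nmv))) nmv <- residue_key(res$chain[1], nmv)
  bf <- rep(0, nrow(res))
  hit <- match(nmv, keys)
  bf[hit[!is.na(hit)]] <- values[!is.na(hit)]
  too_wide <- nchar(sprintf("%.2f", bf)) > 6L
  if (any(too_wide))
    stop("value(s) exceed the 6-character B-factor field width: ",
         paste(utils::head(bf[too_wide]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  write_pdb_model(con, traj$coords[, , , frame], res, bfac = bf)
  writeLines("END", con)
  invisible(path)
}

# optimal proper rotation (Kabsch, via SVD) mapping P onto Q, row vectors
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$u, s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition of trajectory frames
#'
#' Least-squares superposition of every frame onto a reference using the
#' SVD-based optimal rotation with the determinant correction that enforces
#' a proper rotation (no reflection). By default a two-pass protocol is
#' used: frames are first fitted to frame 1, the mean structure of the
#' fitted selection is computed, and all frames are then fitted to that
#' mean. This is the standard reference choice for fluctuation analysis.
#'
#' @param traj a \code{backbone_trajectory}.
#' @param reference frame index to fit against, or \code{NULL} (default) for
#'   the two-pass mean-structure protocol.
#' @param selection character vector of backbone atom names used in the fit
#'   (default \code{"CA"}).
#' @return a superposed \code{backbone_trajectory}.
#' @export
superpose_frames <- function(traj, reference = NULL, selection = "CA") {
  selection <- match.arg(selection, BACKBONE_ATOMS, several.ok = TRUE)
  ai <- match(selection, BACKBONE_ATOMS)
  sel_coords <- function(fr) {
    m <- NULL
    for (a in ai) m <- rbind(m, fr[, a, ])
    m
  }
  check_sel <- function(m) {
    if (nrow(m) < 3L) stop("need at least 3 selection atoms to superpose")
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] < 1e-8) stop("selection atoms are collinear; cannot superpose")
  }
  fit_all <- function(co, refmat) {
    nf <- dim(co)[4]
    cq <- colMeans(refmat)
    for (f in seq_len(nf)) {
      P <- sel_coords(co[, , , f])
      cp <- colMeans(P)
      rot <- kabsch_rotation(sweep(P, 2, cp), sweep(refmat, 2, cq))
      for (a in 1:4) {
        co[, a, , f] <- sweep(sweep(co[, a, , f, drop = FALSE][, 1, , 1],
                                    2, cp) %*% rot, 2, cq, "+")
      }
    }
    co
  }
  co <- traj$coords
  if (!is.null(reference)) {
    stopifnot(reference >= 1L, reference <= n_frames(traj))
    refmat <- sel_coords(co[, , , reference])
    check_sel(refmat)
    co <- fit_all(co, refmat)
  } else {
    refmat <- sel_coords(co[, , , 1])
    check_sel(refmat)
    co <- fit_all(co, refmat)
    nf <- dim(co)[4]
    acc <- 0
    for (f in seq_len(nf)) acc <- acc + sel_coords(co[, , , f])
    co <- fit_all(co, acc / nf)
  }
  out <- traj
  out$coords <- co
  out
}
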