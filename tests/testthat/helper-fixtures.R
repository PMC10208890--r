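# Shared fixtures and independent oracles, all built in code at test time.

# small multi-frame trajectory: helix base plus seeded Gaussian noise
noisy_helix <- function(n_residues = 10, n_frames = 5, sigma = 0.05,
                        seed = 42) {
  base <- build_ideal_helix(n_residues)
  generate_fluctuating_trajectory(
    base, fluctuation_spec(n_residues, n_frames, sigma, seed = seed))
}

# rigid-body transform of every frame (rotation about z by angle, then shift)
transform_traj <- function(traj, angle = pi / 2, shift = c(10, -3, 5)) {
  rot <- matrix(c(cos(angle), sin(angle), 0,
                  -sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3)
  co <- traj$coords
  for (f in seq_len(dim(co)[4]))
    for (a in 1:4)
      co[, a, , f] <- sweep(co[, a, , f] %*% rot, 2, shift, "+")
  out <- traj
  out$coords <- co
  out
}

# brute-force Kabsch-Sander tensor: naive per-pair loop, independent of
# the vectorized implementation
brute_ks_tensor <- function(traj, constants = ks_constants()) {
  res <- traj$residues
  R <- nrow(res)
  nf <- n_frames(traj)
  E <- array(NA_real_, c(R, R, nf))
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    for (j in seq_len(R)) {        # donor
      if (j == 1 || res$chain[j] != res$chain[j - 1] || res$resname[j] == "PRO")
        next
      v <- fr[j - 1, 3, ] - fr[j - 1, 4, ]
      H <- fr[j, 1, ] + v / sqrt(sum(v^2))
      for (i in seq_len(R)) {      # acceptor
        if (i == j) next
        if (res$chain[i] == res$chain[j] && abs(i - j) == 1) next
        d <- function(p, q) sqrt(sum((p - q)^2))
        E[j, i, f] <- constants$coupling *
          (1 / d(fr[j, 1, ], fr[i, 4, ]) + 1 / d(H, fr[i, 3, ]) -
           1 / d(fr[j, 1, ], fr[i, 3, ]) - 1 / d(H, fr[i, 4, ]))
      }
    }
  }
  E
}

# brute-force per-residue RMSF: plain loops over residues and frames
brute_rmsf <- function(traj) {
  R <- n_residues(traj)
  nf <- n_frames(traj)
  out <- numeric(R)
  for (j in seq_len(R)) {
    xs <- t(vapply(seq_len(nf), function(f) traj$coords[j, 2, , f],
                   numeric(3)))
    mu <- colMeans(xs)
    out[j] <- sqrt(mean(rowSums(sweep(xs, 2, mu)^2)))
  }
  out
}

# reference DSSP oracle: mdtraj's simplified assignment via the system
# python (independent implementation of the same H-bond pattern rules)
mdtraj_dssp <- function(pdb_path) {
  out_file <- tempfile(fileext = ".txt")
  script <- sprintf(
    "import mdtraj as md\nt = md.load(r'%s')\nss = md.compute_dssp(t, simplified=True)[0]\nopen(r'%s','w').write('\\n'.join(ss) + '\\n')",
    pdb_path, out_file)
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_file))
    stop("mdtraj oracle failed: ", paste(status, collapse = "\n"))
  readLines(out_file)
}

# packaged small-protein fixture shipped with bio3d (lysozyme)
lysozyme_pdb <- function() system.file("examples", "1hel.pdb", package = "bio3d")
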