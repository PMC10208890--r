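# Ideal backbone geometry (Engh-Huber bond lengths and angles, degrees)
GEOM <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
             a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.5)

# place atom D given A-B-C, bond length r, angle B-C-D, dihedral A-B-C-D
place_internal <- function(A, B, C, r, theta_deg, phi_deg) {
  theta <- theta_deg * pi / 180
  phi <- phi_deg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a single-frame ideal polypeptide backbone
#'
#' Constructs an all-alanine backbone from ideal bond lengths/angles and the
#' supplied phi/psi/omega dihedrals. The default dihedrals give a canonical
#' alpha helix (phi = -57, psi = -47 degrees; rise about 1.5 A per residue,
#' CA-CA 3.8 A, O(i)...N(i+4) about 3.1 A), the standard fixture for
#' hydrogen-bond and secondary-structure tests.
#'
#' @param n_residues number of residues (>= 2).
#' @param phi,psi,omega backbone dihedrals in degrees.
#' @param chain chain identifier.
#' @return a single-frame \code{backbone_trajectory}.
#' @export
build_ideal_helix <- function(n_residues, phi = -57, psi = -47, omega = 180,
                              chain = "A") {
  if (n_residues < 2L) stop("need at least 2 residues")
  g <- GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  th <- g$a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + g$b_CAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues)) {
    if (i < n_residues) {
      N[i + 1, ] <- place_internal(N[i, ], CA[i, ], C[i, ], g$b_CN, g$a_CACN, psi)
      CA[i + 1, ] <- place_internal(CA[i, ], C[i, ], N[i + 1, ], g$b_NCA, g$a_CNCA, omega)
      C[i + 1, ] <- place_internal(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CAC, g$a_NCAC, phi)
    }
    O[i, ] <- place_internal(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO, psi - 180)
  }
  co <- array(NA_real_, c(n_residues, 4L, 3L, 1L))
  co[, 1, , 1] <- N
  co[, 2, , 1] <- CA
  co[, 3, , 1] <- C
  co[, 4, , 1] <- O
  backbone_trajectory(co, data.frame(chain = chain, resid = seq_len(n_residues),
                                     resname = "ALA"))
}

#' Specification for a synthetic fluctuating trajectory
#'
#' Describes Gaussian backbone fluctuations about a base structure, with
#' optional correlated blocks. Every atom of residue j receives independent
#' isotropic Gaussian noise of standard deviation \code{sigma_j} per
#' coordinate. A correlated block injects, on top of that noise, collective
#' motion shared by its members and scaled by the block's latent weight:
#' (a) a rigid per-frame latent 3-vector displacing all member atoms
#' together (correlates the members' displacement magnitudes) and (b) a
#' per-frame scalar amplitude driving a fixed hydrogen-bond stretch mode on
#' backbone i,i+4 H-bonds internal to the block (acceptor O displaced along
#' its C=O axis, donor N along the N...O axis), which coherently modulates
#' the members' Kabsch-Sander energies. Rigid displacement alone leaves the
#' members' internal H-bond geometry untouched and therefore injects almost
#' no energy correlation; the stretch mode is what makes the block visible
#' to the electrostatic-centrality network.
#'
#' @param n_residues,n_frames trajectory dimensions.
#' @param base_sigma per-coordinate Gaussian amplitude in Angstrom
#'   (default 0.1, a compact-fold fluctuation scale that keeps the 1/d
#'   electrostatics in their quasi-linear regime).
#' @param residue_sigma_overrides named numeric vector (names = residue
#'   numbers) of per-residue sigmas overriding \code{base_sigma}.
#' @param correlated_blocks list of \code{list(residues =, weight =)} with
#'   weight in [0, 1]; blocks must be disjoint.
#' @param latent_scale ratio of latent-amplitude SD to \code{base_sigma}
#'   (default 2).
#' @param ar1_phi lag-1 autocorrelation of the per-atom noise in [0, 1).
#'   Default 0 (frames independent, the regime with analytic ground
#'   truths); positive values give AR(1) noise with the same stationary
#'   per-coordinate SD, for realism checks.
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return object of class \code{fluctuation_spec}.
#' @export
fluctuation_spec <- function(n_residues, n_frames, base_sigma = 0.1,
                             residue_sigma_overrides = NULL,
                             correlated_blocks = list(),
                             latent_scale = 2, ar1_phi = 0, seed = 1L) {
  stopifnot_scalar(base_sigma, "base_sigma")
  if (base_sigma < 0) stop("base_sigma must be >= 0")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  seen <- integer(0)
  for (b in correlated_blocks) {
    if (!all(c("residues", "weight") %in% names(b)))
      stop("each block needs 'residues' and 'weight'")
    if (b$weight < 0 || b$weight > 1) stop("latent weight must be in [0, 1]")
    if (any(b$residues %in% seen)) stop("correlated blocks must be disjoint")
    if (any(b$residues < 1 | b$residues > n_residues))
      stop("block residues out of range")
    seen <- c(seen, b$residues)
  }
  structure(list(n_residues = n_residues, n_frames = n_frames,
                 base_sigma = base_sigma,
                 residue_sigma_overrides = residue_sigma_overrides,
                 correlated_blocks = correlated_blocks,
                 latent_scale = latent_scale, ar1_phi = ar1_phi,
                 seed = seed),
            class = "fluctuation_spec")
}

#' Generate a fluctuating trajectory about a base structure
#'
#' @param base single-frame \code{backbone_trajectory} (the mean structure).
#' @param spec a \code{\link{fluctuation_spec}}.
#' @return a \code{backbone_trajectory} with \code{spec$n_frames} frames.
#' @export
generate_fluctuating_trajectory <- function(base, spec) {
  stopifnot(inherits(spec, "fluctuation_spec"))
  R <- n_residues(base)
  if (R != spec$n_residues)
    stop("base structure has ", R, " residues but spec expects ", spec$n_residues)
  nf <- spec$n_frames
  b0 <- base$coords[, , , 1]
  sig <- rep(spec$base_sigma, R)
  if (!is.null(spec$residue_sigma_overrides)) {
    ov <- spec$residue_sigma_overrides
    sig[as.integer(names(ov))] <- as.numeric(ov)
  }
  # fixed H-bond stretch modes per block, from the base geometry
  blocks <- lapply(spec$correlated_blocks, function(b) {
    memb <- sort(as.integer(b$residues))
    modeO <- matrix(0, R, 3)
    modeN <- matrix(0, R, 3)
    for (r in memb) {
      if ((r + 4L) %in% memb) {
        v <- b0[r, 4, ] - b0[r, 3, ]
        modeO[r, ] <- v / sqrt(sum(v^2))
      }
      if ((r - 4L) %in% memb) {
        v <- b0[r - 4L, 4, ] - b0[r, 1, ]
        modeN[r, ] <- v / sqrt(sum(v^2))
      }
    }
    list(members = memb, weight = b$weight, modeO = modeO, modeN = modeN)
  })
  lat_sd <- spec$latent_scale * spec$base_sigma
  phi <- spec$ar1_phi
  co <- with_seed(spec$seed, {
    out <- array(NA_real_, c(R, 4L, 3L, nf))
    eps <- NULL  # AR(1) noise state, stationary SD = sig
    for (f in seq_len(nf)) {
      innov <- array(rnorm(R * 12L, 0, rep(sig, 12L)), c(R, 4L, 3L))
      eps <- if (is.null(eps) || phi == 0) innov
             else phi * eps + sqrt(1 - phi^2) * innov
      fr <- b0 + eps
      for (bl in blocks) {
        g <- rnorm(3, 0, spec$base_sigma)       # rigid shared latent vector
        a <- rnorm(1, 0, lat_sd)                # shared stretch amplitude
        w <- bl$weight
        for (k in 1:3) {
          fr[bl$members, , k] <- fr[bl$members, , k] + w * g[k]
          fr[, 4, k] <- fr[, 4, k] + w * a * bl$modeO[, k]
          fr[, 1, k] <- fr[, 1, k] + w * a * bl$modeN[, k]
        }
      }
      out[, , , f] <- fr
    }
    out
  })
  backbone_trajectory(co, base$residues, check = FALSE)
}

#' Specification for a synthetic wt/variant HSQC peak-list pair
#'
#' @param n_residues number of assigned residues.
#' @param shift_perturbations named list or data.frame: per-residue
#'   (dH, dN) chemical-shift changes in ppm applied to the variant, e.g.
#'   \code{list(`10` = c(0.1, 0.5))}.
#' @param broadened_set integer residues whose variant intensity is
#'   attenuated.
#' @param attenuation multiplicative intensity factor for broadened
#'   residues (in [0, 1); use < 0.5 to trip the 50-percent rule).
#' @param global_intensity_scale factor applied to all variant intensities
#'   (receiver-gain difference between spectra).
#' @param noise_sd_ppm,noise_sd_intensity Gaussian noise SDs (shift ppm,
#'   relative intensity).
#' @param seed integer seed.
#' @return object of class \code{peaklist_spec}.
#' @export
peaklist_spec <- function(n_residues, shift_perturbations = list(),
                          broadened_set = integer(0), attenuation = 0.2,
                          global_intensity_scale = 1,
                          noise_sd_ppm = 0, noise_sd_intensity = 0,
                          seed = 1L) {
  if (attenuation < 0 || attenuation >= 1) stop("attenuation must be in [0, 1)")
  if (global_intensity_scale <= 0) stop("global_intensity_scale must be > 0")
  pert <- names(shift_perturbations)
  if (length(pert) && any(as.integer(pert) < 1 | as.integer(pert) > n_residues))
    stop("perturbed residues out of range")
  if (length(broadened_set) && any(broadened_set < 1 | broadened_set > n_residues))
    stop("broadened residues out of range")
  structure(list(n_residues = n_residues,
                 shift_perturbations = shift_perturbations,
                 broadened_set = as.integer(broadened_set),
                 attenuation = attenuation,
                 global_intensity_scale = global_intensity_scale,
                 noise_sd_ppm = noise_sd_ppm,
                 noise_sd_intensity = noise_sd_intensity, seed = seed),
            class = "peaklist_spec")
}

#' Generate a wild-type / variant peak-list pair with known ground truth
#'
#' Wild-type amide shifts are drawn uniformly in realistic ranges (1H
#' 6.5-10.5 ppm, 15N 105-135 ppm) with log-normal-ish positive intensities;
#' the variant applies the specified shift perturbations, attenuates the
#' broadened set, scales all intensities by the global factor, and adds
#' Gaussian noise.
#'
#' @param spec a \code{\link{peaklist_spec}}.
#' @return list with elements \code{wt} and \code{variant}, each a
#'   \code{peak_list}.
#' @export
generate_peak_list_pair <- function(spec) {
  stopifnot(inherits(spec, "peaklist_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    resid <- seq_len(n)
    dH <- stats::runif(n, 6.5, 10.5)
    dN <- stats::runif(n, 105, 135)
    height <- exp(rnorm(n, log(1e6), 0.3))
    wt <- peak_list(resid, dH, dN, height, label = "wt")
    dH2 <- dH
    dN2 <- dN
    for (r in names(spec$shift_perturbations)) {
      p <- spec$shift_perturbations[[r]]
      i <- as.integer(r)
      dH2[i] <- dH2[i] + p[1]
      dN2[i] <- dN2[i] + p[2]
    }
    h2 <- height
    h2[spec$broadened_set] <- h2[spec$broadened_set] * spec$attenuation
    h2 <- h2 * spec$global_intensity_scale
    if (spec$noise_sd_ppm > 0) {
      dH2 <- dH2 + rnorm(n, 0, spec$noise_sd_ppm)
      dN2 <- dN2 + rnorm(n, 0, spec$noise_sd_ppm * 5)  # 15N noise on its scale
    }
    if (spec$noise_sd_intensity > 0)
      h2 <- h2 * (1 + rnorm(n, 0, spec$noise_sd_intensity))
    list(wt = wt, variant = peak_list(resid, dH2, dN2, h2, label = "variant"))
  })
}

# default longitudinal-relaxation delay schedule (ms) and its replicates
T1_DELAYS_MS <- c(0, 20, 60, 100, 200, 600, 800, 1200, 1500, 2000, 2500)
T1_DUPLICATES_MS <- c(20, 600)
T2_DELAYS_MS <- c(0, 16.9, 33.9, 67.8, 136, 169, 203)
T2_DUPLICATES_MS <- c(33.9, 136)

#' Specification for a synthetic mono-exponential relaxation decay
#'
#' Defaults reproduce a standard longitudinal (T1) delay schedule of
#' 0-2500 ms with duplicate delays at 20 and 600 ms, so synthetic fits
#' exercise the same experimental design as real series;
#' \code{delay_schedule = T2_DELAYS_MS} gives the transverse analogue.
#'
#' @param true_rate decay rate in 1/s (> 0).
#' @param initial_height height at zero delay (arbitrary units).
#' @param delay_schedule delays in ms (must include 0).
#' @param duplicate_delays delays measured twice (ms); must be a subset of
#'   \code{delay_schedule}.
#' @param noise_fraction relative Gaussian noise SD on each height.
#' @param seed integer seed.
#' @return object of class \code{decay_spec}.
#' @export
decay_spec <- function(true_rate, initial_height = 100,
                       delay_schedule = T1_DELAYS_MS,
                       duplicate_delays = T1_DUPLICATES_MS,
                       noise_fraction = 0, seed = 1L) {
  stopifnot_scalar(true_rate, "true_rate")
  if (true_rate <= 0) stop("true_rate must be > 0")
  if (any(delay_schedule < 0)) stop("delays must be non-negative")
  if (!any(delay_schedule == 0)) stop("delay schedule must include 0")
  if (!all(duplicate_delays %in% delay_schedule))
    stop("duplicate delays must be part of the delay schedule")
  structure(list(true_rate = true_rate, initial_height = initial_height,
                 delay_schedule = delay_schedule,
                 duplicate_delays = duplicate_delays,
                 noise_fraction = noise_fraction, seed = seed),
            class = "decay_spec")
}

#' Generate a relaxation decay series with known rate
#'
#' Heights follow \code{initial_height * exp(-rate * t)} with multiplicative
#' Gaussian noise; duplicate delays appear twice with independent noise.
#'
#' @param spec a \code{\link{decay_spec}}.
#' @return a \code{relaxation_series} (data.frame of delay_ms, height,
#'   replicate flag).
#' @export
generate_decay_series <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  with_seed(spec$seed, {
    delays <- c(spec$delay_schedule, spec$duplicate_delays)
    replicate <- c(rep(FALSE, length(spec$delay_schedule)),
                   rep(TRUE, length(spec$duplicate_delays)))
    mu <- spec$initial_height * exp(-spec$true_rate * delays / 1000)
    h <- mu * (1 + rnorm(length(delays), 0, spec$noise_fraction))
    relaxation_series(delay_ms = delays, height = h, replicate = replicate)
  })
}
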