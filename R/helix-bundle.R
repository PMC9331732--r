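# Synthetic four-fold helical bundle trajectories.
#
# Emulates the geometry the trajectory analysis consumes: ideal
# alpha-helices (2.3 A radius, 1.5 A rise and 100 deg twist per residue)
# arranged with exact C_n symmetry about z, each bent at a PVP-like hinge
# position. One subunit can be bent further ("asymmetric" subunit); its
# extra bend is applied to the segment N-terminal to the hinge, so it
# both increases that subunit's kink angle and displaces its pore-top
# residue, breaking the ring symmetry the way a strained pore would.

.rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

.rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

.ideal_kinked_helix <- function(resno, kink_residue, kink_deg,
                                upper_extra_deg = 0,
                                radius = 2.3, rise = 1.5, twist = 100) {
  j <- seq_along(resno) - 1
  phi <- j * twist * pi / 180
  X <- cbind(radius * cos(phi), radius * sin(phi), rise * j)
  jk <- match(kink_residue, resno)
  if (is.na(jk)) stop("kink residue outside the modeled residue range")
  hinge <- c(0, 0, rise * (jk - 1))
  lower <- resno > kink_residue
  if (kink_deg != 0 && any(lower)) {
    R <- .rot_x(kink_deg * pi / 180)
    X[lower, ] <- sweep(sweep(X[lower, , drop = FALSE], 2, hinge) %*% t(R),
                        2, hinge, "+")
  }
  upper <- resno < kink_residue
  if (upper_extra_deg != 0 && any(upper)) {
    R <- .rot_x(-upper_extra_deg * pi / 180)
    X[upper, ] <- sweep(sweep(X[upper, , drop = FALSE], 2, hinge) %*% t(R),
                        2, hinge, "+")
  }
  X
}

#' Generate a synthetic kinked helical-bundle trajectory
#'
#' Builds `n_frames` snapshots of `n_subunits` ideal alpha-helices
#' (Calpha only, author-style residue numbering spanning the S6 region
#' with the pore-top glycine at 385 and the hinge at 403) arranged with
#' exact C_n symmetry, with independent Gaussian coordinate noise per
#' frame.
#'
#' @param n_subunits Number of subunits (>= 3); chains are labeled A, B, ...
#' @param kink_deg Imposed kink angle at the hinge (degrees, 0 <= kink < 90).
#' @param kink_residue Hinge residue number; default 403.
#' @param asym_subunit Optional subunit index (1-based) receiving an
#'   extra bend.
#' @param asym_extra_deg Extra bend of the asymmetric subunit (degrees).
#' @param n_frames Number of frames.
#' @param coord_noise_A Gaussian coordinate noise sd per frame (Angstrom);
#'   default 0.3, of the order of aligned-Calpha fluctuations in
#'   equilibrated simulations.
#' @param frame_dt_ns Time between frames (ns).
#' @param seed Integer seed.
#' @param first_res,last_res Modeled residue range; must contain 385 and
#'   the hinge.
#' @param bundle_radius_A Distance of each helix axis from the pore axis.
#' @return A `kv_trajectory` (fields `atom`, `coords`, `times_ns`).
#' @export
make_helix_bundle <- function(n_subunits = 4, kink_deg = 25,
                              kink_residue = 403, asym_subunit = NULL,
                              asym_extra_deg = 0, n_frames = 100,
                              coord_noise_A = 0.3, frame_dt_ns = 0.1,
                              seed = 1, first_res = 380, last_res = 420,
                              bundle_radius_A = 10) {
  stopifnot(n_subunits >= 3, kink_deg >= 0, kink_deg < 90, n_frames >= 1,
            coord_noise_A >= 0, frame_dt_ns > 0)
  if (kink_residue <= first_res || kink_residue >= last_res)
    stop("invalid kink residue: must lie strictly inside the residue range")
  resno <- first_res:last_res
  chains <- LETTERS[seq_len(n_subunits)]
  base <- vector("list", n_subunits)
  for (i in seq_len(n_subunits)) {
    extra <- if (!is.null(asym_subunit) && i == asym_subunit)
      asym_extra_deg else 0
    X <- .ideal_kinked_helix(resno, kink_residue, kink_deg, extra)
    X[, 1] <- X[, 1] + bundle_radius_A
    base[[i]] <- X %*% t(.rot_z(2 * pi * (i - 1) / n_subunits))
  }
  base <- do.call(rbind, base)
  resid3 <- ifelse(resno == 385, "GLY",
                   ifelse(resno %in% c(403, 405), "PRO", "ALA"))
  atom <- data.frame(chain = rep(chains, each = length(resno)),
                     resno = rep(resno, n_subunits),
                     resid = rep(resid3, n_subunits),
                     elety = "CA", stringsAsFactors = FALSE)
  set.seed(seed)
  coords <- array(NA_real_, c(n_frames, nrow(base), 3))
  for (f in seq_len(n_frames)) {
    noise <- if (coord_noise_A > 0)
      matrix(stats::rnorm(length(base), sd = coord_noise_A), nrow(base))
    else 0
    coords[f, , ] <- base + noise
  }
  structure(list(atom = atom, coords = coords,
                 times_ns = frame_dt_ns * (seq_len(n_frames) - 1)),
            class = "kv_trajectory")
}

# --- multi-model PDB IO ---------------------------------------------------

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, frame times as
#' `REMARK 100 FRAME <i> TIME_NS <t>` header records.
#'
#' @param traj A `kv_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kv_trajectory"))
  nf <- dim(traj$coords)[1]
  na <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK 100 SYNTHETIC HELICAL BUNDLE TRAJECTORY", con)
  writeLines(sprintf("REMARK 100 FRAME %5d TIME_NS %12.4f",
                     seq_len(nf), traj$times_ns), con)
  a <- traj$atom
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , ]
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(na), a$resid, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Coordinates and topology are parsed with `bio3d`; frame times are
#' taken from `REMARK 100 FRAME ... TIME_NS ...` records when present,
#' otherwise a uniform grid at `dt_ns` is assumed.
#'
#' @param path Multi-model PDB file (MODEL/ENDMDL records).
#' @param dt_ns Fallback frame spacing (ns) when the file carries no
#'   frame-time remarks.
#' @return A `kv_trajectory`.
#' @export
read_trajectory <- function(path, dt_ns = 0.1) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  atom <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                     resid = pdb$atom$resid, elety = pdb$atom$elety,
                     stringsAsFactors = FALSE)
  rem <- grep("^REMARK 100 FRAME", readLines(path, n = 10000), value = TRUE)
  times <- if (length(rem) == nf) {
    as.numeric(sub(".*TIME_NS\\s+", "", rem))
  } else dt_ns * (seq_len(nf) - 1)
  structure(list(atom = atom, coords = coords, times_ns = times),
            class = "kv_trajectory")
}

#' Apply a rigid-body transform to every frame
#'
#' Utility for invariance checks and frame alignment: rotates all
#' coordinates by `R` and then translates by `shift`.
#'
#' @param traj A `kv_trajectory`.
#' @param R 3x3 rotation matrix.
#' @param shift Length-3 translation vector.
#' @return The transformed `kv_trajectory`.
#' @export
transform_trajectory <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(traj, "kv_trajectory"), all(dim(R) == c(3, 3)))
  for (f in seq_len(dim(traj$coords)[1]))
    traj$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(R), 2, shift, "+")
  traj
}
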