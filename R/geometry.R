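# Trajectory geometry of the tetrameric pore domain.
#
# Works on multi-model PDB coordinate sets (one MODEL per frame, frame
# times in REMARK 100 records). The S6 kink angle is the angle between
# the helix axes above and below the PVP/A motif; the symmetry angles
# are measured at each subunit's G385 Calpha toward its two
# pore-adjacent neighbors. Helix axes come from a principal-component
# fit of Calpha positions smoothed over one helical turn, which is
# exact for ideal alpha-helical geometry and robust to coordinate
# noise.

#' A helix segment selector
#'
#' @param chain Chain identifier.
#' @param first,last First and last residue numbers (author numbering);
#'   at least 5 residues.
#' @return An object of class `helix_segment`.
#' @export
helix_segment <- function(chain, first, last) {
  stopifnot(last - first >= 4)
  structure(list(chain = chain, first = first, last = last),
            class = "helix_segment")
}

# Default S6 windows around the P403-V404-P405 motif (author numbering)
.S6_UPPER <- c(389, 401)
.S6_LOWER <- c(405, 417)

#' Extract one frame of a trajectory
#'
#' @param traj A `kv_trajectory`.
#' @param i Frame index.
#' @return List with `atom` (data.frame) and `xyz` (n_atoms x 3 matrix).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "kv_trajectory"), i >= 1, i <= dim(traj$coords)[1])
  list(atom = traj$atom, xyz = traj$coords[i, , ], time_ns = traj$times_ns[i])
}

.frame_ca <- function(frame, chain, resno) {
  sel <- frame$atom$chain == chain & frame$atom$resno %in% resno &
    frame$atom$elety == "CA"
  got <- frame$atom$resno[sel]
  missing <- setdiff(resno, got)
  if (length(missing) > 0)
    stop("missing Calpha atoms: chain ", chain, " residues ",
         paste(missing, collapse = ","))
  xyz <- frame$xyz[sel, , drop = FALSE]
  xyz[order(got), , drop = FALSE]
}

# smoothing kernel cancelling the helical circular component over one turn
.turn_kernel <- function(twist_deg = 100) {
  th <- twist_deg * pi / 180
  M <- rbind(c(1, cos(th)), c(0, sin(th)))
  rhs <- -c(cos(2 * th) + cos(3 * th), sin(2 * th) + sin(3 * th))
  w <- c(solve(M, rhs), 1, 1)
  w / sum(w)
}

#' Helix axis of a segment in one frame
#'
#' Calpha positions are smoothed with a 4-residue kernel whose weights
#' cancel the helical spiral at the canonical 100 deg-per-residue twist;
#' the principal component of the smoothed points is the axis, oriented
#' N-terminal to C-terminal.
#'
#' @param frame A frame from [get_frame()].
#' @param seg A [helix_segment].
#' @param twist_deg Assumed helical twist (degrees per residue).
#' @return List with `axis` (unit 3-vector) and `centroid`.
#' @export
helix_axis <- function(frame, seg, twist_deg = 100) {
  stopifnot(inherits(seg, "helix_segment"))
  X <- .frame_ca(frame, seg$chain, seg$first:seg$last)
  if (nrow(X) < 5) stop("helix axis needs at least 5 Calpha atoms")
  w <- .turn_kernel(twist_deg)
  m <- nrow(X) - 3
  Q <- vapply(1:3, function(k)
    vapply(seq_len(m), function(i) sum(w * X[i:(i + 3), k]), numeric(1)),
    numeric(m))
  p <- stats::prcomp(Q)$rotation[, 1]
  if (sum(p * (X[nrow(X), ] - X[1, ])) < 0) p <- -p
  list(axis = p, centroid = colMeans(X))
}

#' S6 kink angle in one frame
#'
#' Angle between the N->C-oriented helix axes of the segments above and
#' below the PVP/A motif of one chain, in degrees within `[0, 180]`.
#'
#' @param frame A frame from [get_frame()].
#' @param chain Chain identifier.
#' @param upper,lower [helix_segment]s on that chain; must not overlap.
#'   Defaults: residues 389-401 (above) and 405-417 (below), excluding
#'   the 402-404 motif.
#' @return Kink angle in degrees.
#' @export
kink_angle <- function(frame, chain,
                       upper = helix_segment(chain, .S6_UPPER[1], .S6_UPPER[2]),
                       lower = helix_segment(chain, .S6_LOWER[1], .S6_LOWER[2])) {
  if (upper$chain != lower$chain)
    stop("kink segments must lie on the same chain")
  if (max(upper$first, lower$first) <= min(upper$last, lower$last))
    stop("kink segments must not overlap")
  a <- helix_axis(frame, upper)$axis
  b <- helix_axis(frame, lower)$axis
  acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
}

#' Four-fold symmetry angles at a pore-top residue
#'
#' For each subunit, the angle at its chosen residue's Calpha between
#' the vectors to the equivalent Calpha of its two pore-adjacent
#' neighbors. Neighbors are identified geometrically (azimuthal order
#' about the normal of the best-fit plane of the four atoms), not by
#' chain labels. A perfectly four-fold-symmetric bundle gives 90 deg
#' everywhere.
#'
#' @param frame A frame from [get_frame()].
#' @param residue Residue number; default 385 (the G385 position at the
#'   top of S6).
#' @return Named numeric vector (one angle in degrees per chain).
#' @export
symmetry_angles <- function(frame, residue = 385) {
  chains <- unique(frame$atom$chain)
  if (length(chains) < 4) stop("symmetry angles need at least 4 chains")
  P <- t(vapply(chains, function(ch)
    .frame_ca(frame, ch, residue)[1, ], numeric(3)))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  pc <- stats::prcomp(Pc)
  # azimuthal ring order in the best-fit plane
  uv <- Pc %*% pc$rotation[, 1:2]
  ord <- order(atan2(uv[, 2], uv[, 1]))
  n <- length(ord)
  ang <- numeric(n)
  for (j in seq_len(n)) {
    i <- ord[j]
    prev <- ord[ifelse(j == 1, n, j - 1)]
    nxt <- ord[ifelse(j == n, 1, j + 1)]
    v1 <- P[prev, ] - P[i, ]
    v2 <- P[nxt, ] - P[i, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang[i] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  names(ang) <- chains
  ang
}

#' Windowed trajectory statistics
#'
#' Evaluates an observable on the frame nearest each sample time of a
#' regular grid over the final window of the trajectory and returns its
#' mean and SD (n-1 denominator). The conventional reporting window is
#' the last 50 ns sampled every 0.1 ns (501 samples).
#'
#' @param traj A `kv_trajectory`.
#' @param observable Function of one frame returning a numeric scalar or
#'   a (named) numeric vector.
#' @param window_last Window length (ns) measured back from the final
#'   frame time.
#' @param sample_every Sampling interval (ns).
#' @return `data.frame` with `observable`, `mean`, `sd`, `n_samples`.
#' @export
trajectory_stats <- function(traj, observable, window_last = 50,
                             sample_every = 0.1) {
  stopifnot(inherits(traj, "kv_trajectory"))
  times <- traj$times_ns
  span <- max(times) - min(times)
  if (window_last > span + 1e-9)
    stop("window (", window_last, " ns) longer than trajectory span (",
         span, " ns)")
  grid <- seq(max(times) - window_last, max(times), by = sample_every)
  idx <- vapply(grid, function(tt) which.min(abs(times - tt)), integer(1))
  vals <- lapply(idx, function(i) observable(get_frame(traj, i)))
  V <- do.call(rbind, lapply(vals, function(v) matrix(v, nrow = 1)))
  nm <- names(vals[[1]])
  if (is.null(nm)) nm <- if (ncol(V) == 1) "observable" else
    paste0("obs", seq_len(ncol(V)))
  data.frame(observable = nm,
             mean = colMeans(V),
             sd = apply(V, 2, stats::sd),
             n_samples = length(grid),
             row.names = NULL)
}
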