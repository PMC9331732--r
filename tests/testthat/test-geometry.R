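# Trajectory geometry: axis estimation, kink and symmetry angles,
# windowed statistics, PDB round-trips.

one_frame_bundle <- function(...) {
  get_frame(make_helix_bundle(n_frames = 1, coord_noise_A = 0, ...), 1)
}

test_that("helix axis is exact on ideal helices and equivariant under
           rotation", {
  fr <- one_frame_bundle(kink_deg = 0)
  seg <- helix_segment("A", 389, 401)
  ax <- helix_axis(fr, seg)$axis
  # chain A of a straight bundle is built along z
  expect_lt(acos(abs(sum(ax * c(0, 0, 1)))) * 180 / pi, 0.01)
  set.seed(2)
  R <- random_rotation()
  fr2 <- fr
  fr2$xyz <- fr$xyz %*% t(R)
  ax2 <- helix_axis(fr2, seg)$axis
  expect_lt(acos(pmin(sum(ax2 * (R %*% ax)), 1)) * 180 / pi, 1e-6)
})

test_that("kink angle: straight helices read 0, imposed kinks recover
           within 0.5 degrees noise-free", {
  fr0 <- one_frame_bundle(kink_deg = 0)
  expect_lt(kink_angle(fr0, "A"), 0.5)
  for (kd in c(10, 25, 40)) {
    fr <- one_frame_bundle(kink_deg = kd)
    for (ch in c("A", "B", "C", "D"))
      expect_lt(abs(kink_angle(fr, ch) - kd), 0.5)
  }
})

test_that("kink angle is invariant under rigid-body motion to 1e-6 deg", {
  fr <- one_frame_bundle(kink_deg = 25)
  base <- kink_angle(fr, "B")
  set.seed(4)
  for (i in 1:5) {
    R <- random_rotation()
    fr2 <- fr
    fr2$xyz <- sweep(fr$xyz %*% t(R), 2, runif(3, -50, 50), "+")
    expect_lt(abs(kink_angle(fr2, "B") - base), 1e-6)
  }
})

test_that("kink segments must be disjoint and on one chain", {
  fr <- one_frame_bundle()
  expect_error(kink_angle(fr, "A", helix_segment("A", 389, 406),
                          helix_segment("A", 405, 417)), "overlap")
  expect_error(kink_angle(fr, "A", helix_segment("A", 389, 401),
                          helix_segment("B", 405, 417)), "same chain")
})

test_that("C4 bundle symmetry angles are 90 degrees each and react to an
           asymmetric subunit", {
  fr <- one_frame_bundle(kink_deg = 25)
  sym <- symmetry_angles(fr, 385)
  expect_equal(unname(sym), rep(90, 4), tolerance = 1e-6)
  spread <- vapply(c(5, 15), function(extra) {
    fra <- one_frame_bundle(kink_deg = 25, asym_subunit = 2,
                            asym_extra_deg = extra)
    s <- symmetry_angles(fra, 385)
    max(s) - min(s)
  }, numeric(1))
  expect_gt(spread[1], 0.1)
  expect_gt(spread[2], spread[1])  # monotone in the perturbation
})

test_that("symmetry-angle sum is 360 degrees for the planar ring", {
  fr <- one_frame_bundle(kink_deg = 25, asym_subunit = 3,
                         asym_extra_deg = 10)
  expect_equal(sum(symmetry_angles(fr, 385)), 360, tolerance = 0.5)
})

test_that("noisy bundles: trajectory-mean kink recovers the imposed angle
           within 2 degrees at 0.3 A coordinate noise", {
  traj <- make_helix_bundle(kink_deg = 25, n_frames = 120,
                            coord_noise_A = 0.3, frame_dt_ns = 0.1,
                            seed = 8)
  st <- trajectory_stats(traj, function(fr) kink_angle(fr, "A"),
                         window_last = 10, sample_every = 0.1)
  expect_lt(abs(st$mean - 25), 2)
  expect_gt(st$sd, 0)
})

test_that("windowed statistics: 50 ns at 0.1 ns gives 501 samples; SD of a
           constant observable is 0", {
  traj <- make_helix_bundle(kink_deg = 20, n_frames = 701,
                            coord_noise_A = 0, frame_dt_ns = 0.1)
  st <- trajectory_stats(traj, function(fr) kink_angle(fr, "A"),
                         window_last = 50, sample_every = 0.1)
  expect_equal(st$n_samples, 501)
  expect_equal(st$sd, 0, tolerance = 1e-9)
  expect_lt(abs(st$mean - 20), 0.5)
  expect_error(trajectory_stats(traj, function(fr) 1, window_last = 100),
               "longer than")
})

test_that("multi-model PDB round-trip preserves coordinates to PDB
           precision and frame times", {
  traj <- make_helix_bundle(kink_deg = 25, n_frames = 100,
                            coord_noise_A = 0.1, frame_dt_ns = 0.1, seed = 3)
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3 + 1e-9)
  expect_equal(back$times_ns, seq(0, 9.9, by = 0.1))
  expect_identical(back$atom$chain, traj$atom$chain)
  expect_identical(back$atom$resno, traj$atom$resno)
  unlink(tmp)
})

test_that("single-model files load as one frame; missing files and missing
           Calpha atoms give named errors", {
  traj <- make_helix_bundle(n_frames = 1, coord_noise_A = 0)
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(dim(back$coords)[1], 1)
  expect_error(read_trajectory(tempfile()), "no such trajectory")
  # drop one analyzed residue
  keep <- !(traj$atom$chain == "A" & traj$atom$resno == 395)
  traj2 <- list(atom = traj$atom[keep, ],
                coords = traj$coords[, keep, , drop = FALSE],
                times_ns = traj$times_ns)
  class(traj2) <- "kv_trajectory"
  expect_error(kink_angle(get_frame(traj2, 1), "A"), "395")
})

test_that("bundle generator validates its inputs", {
  expect_error(make_helix_bundle(n_subunits = 2), "n_subunits")
  expect_error(make_helix_bundle(kink_deg = 95))
  expect_error(make_helix_bundle(kink_residue = 500), "kink residue")
})
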