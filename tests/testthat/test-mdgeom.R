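test_that("classify_frame applies the threshold logic", {
  crit <- geometric_criteria()
  # N-O below 5.0: in-oxyanion regardless of OG-C
  expect_equal(classify_frame(toy_class_frame(4.2, 9)), "in_oxyanion")
  # bound but not pre-reactive
  expect_equal(classify_frame(toy_class_frame(6.0, 5.0)), "near_active_site")
  # outside both
  expect_equal(classify_frame(toy_class_frame(8.0, 6.0)), "other")
  # boundary: tie at exactly 5.0 A N-O goes to near-active-site
  expect_equal(classify_frame(toy_class_frame(5.0, 4.0)), "near_active_site")
  # OG-C at exactly 5.5 is outside (strict upper bound)
  expect_equal(classify_frame(toy_class_frame(6.0, 5.5)), "other")
  # missing atoms are named
  fr <- toy_class_frame(4, 4)
  expect_error(classify_frame(fr[fr$atom != "OG", ]), "ser_og")
  # disjointness is enforced in the criteria constructor
  expect_error(geometric_criteria(d_oxyanion_in = 4.5), "disjoint")
})

test_that("classification partitions every frame exactly once", {
  set.seed(13)
  labs <- replicate(200, classify_frame(toy_class_frame(runif(1, 2, 10),
                                                        runif(1, 2, 8))))
  expect_true(all(labs %in% c("in_oxyanion", "near_active_site", "other")))
})

test_that("state_fractions counts and sums to one", {
  traj <- c(replicate(45, toy_class_frame(4.0, 4.0), simplify = FALSE),
            replicate(55, toy_class_frame(9.0, 7.0), simplify = FALSE))
  fr <- state_fractions(traj)
  expect_equal(unclass(fr)[["in_oxyanion"]], 0.45)
  expect_equal(sum(unclass(fr)), 1)
  expect_equal(attr(fr, "n_frames"), 100L)
  one <- state_fractions(list(toy_class_frame(4, 4)))
  expect_equal(unname(sort(unclass(one), decreasing = TRUE)[1]), 1)
  expect_error(state_fractions(list()), "empty")
})

test_that("hbond_geometry distances, angles, and out-of-plane", {
  # collinear donor-H-acceptor: angle 180
  g <- hbond_geometry(donor = c(0, 0, 0), hydrogen = c(1, 0, 0),
                      acceptor = c(3, 0, 0))
  expect_equal(g$angle, 180, tolerance = 1e-9)
  expect_equal(g$distance, 2, tolerance = 1e-12)
  # acceptor in the amide plane: out-of-plane 0
  plane <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # z = 0 plane
  g2 <- hbond_geometry(donor = c(2, 2, 0), hydrogen = c(1.4, 1.2, 0),
                       acceptor = c(0.5, 0.5, 0), plane_atoms = plane)
  expect_equal(g2$out_of_plane, 0, tolerance = 1e-9)
  # H directly above the acceptor along the normal: out-of-plane 90
  g3 <- hbond_geometry(donor = c(0, 0, 2), hydrogen = c(0, 0, 1),
                       acceptor = c(0, 0, 0), plane_atoms = plane)
  expect_equal(g3$out_of_plane, 90, tolerance = 1e-9)
  # below the plane: sign flips
  g4 <- hbond_geometry(donor = c(0, 0, -2), hydrogen = c(0, 0, -1),
                       acceptor = c(0, 0, 0), plane_atoms = plane)
  expect_equal(g4$out_of_plane, -90, tolerance = 1e-9)
  expect_error(hbond_geometry(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              plane_atoms = rbind(c(0, 0, 0), c(1, 0, 0),
                                                  c(2, 0, 0))),
               "collinear")
})

test_that("salt_bridge_occupancy counts sub-cutoff frames", {
  all_close <- replicate(20, toy_sb_frame(2.8), simplify = FALSE)
  all_far <- replicate(20, toy_sb_frame(8.0), simplify = FALSE)
  expect_equal(as.numeric(salt_bridge_occupancy(all_close, 148, 233)), 1)
  expect_equal(as.numeric(salt_bridge_occupancy(all_far, 148, 233)), 0)
  mixed <- c(all_close[1:9], all_far[1:11])
  expect_equal(as.numeric(salt_bridge_occupancy(mixed, 148, 233)), 0.45)
  expect_error(salt_bridge_occupancy(all_close, 99, 233), "residue 99")
})

test_that("dihedral sign convention, mirror symmetry, and constructed twist", {
  # planar trans arrangement
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1)),
               180, tolerance = 1e-9)
  # cis
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)),
               0, tolerance = 1e-9)
  # constructed twist: p4 rotated +60 degrees about the p2-p3 (z) axis
  th <- 60 * pi / 180
  p4 <- c(cos(th), sin(th), 1)
  d60 <- dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), p4)
  expect_equal(abs(d60), 60, tolerance = 1e-9)
  # mirror image negates the dihedral
  mir <- function(p) c(p[1], -p[2], p[3])
  expect_equal(dihedral(mir(c(1, 0, 0)), mir(c(0, 0, 0)), mir(c(0, 0, 1)),
                        mir(p4)),
               -d60, tolerance = 1e-9)
})

test_that("phi_psi reads backbone atoms and errors at termini", {
  # three-residue stretch with synthetic but valid geometry
  fr <- md_frame(
    resno = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
    resname = rep("ALA", 9),
    atom = rep(c("N", "CA", "C"), 3),
    x = c(0.0, 1.4, 2.0, 3.3, 4.7, 5.2, 6.5, 7.9, 8.4),
    y = c(0.0, 0.4, 1.7, 1.9, 1.2, 2.4, 2.6, 2.0, 3.2),
    z = c(0.0, 0.9, 0.1, 0.5, 1.3, 2.2, 2.0, 2.9, 3.8))
  ang <- phi_psi(fr, 2)
  expect_true(all(is.finite(ang)))
  expect_true(all(ang > -180 & ang <= 180))
  expect_error(phi_psi(fr, 1), "C0")  # no preceding residue
})

test_that("geometric measures are invariant under rigid motion", {
  R <- rotation_xyz(0.4, -1.1, 2.2)
  tr <- c(5, -3, 7)
  fr <- toy_class_frame(4.4, 5.1)
  fr2 <- transform_frame(fr, R, tr)
  expect_equal(classify_frame(fr2), classify_frame(fr))
  sb1 <- toy_sb_frame(3.1); sb2 <- transform_frame(sb1, R, tr)
  expect_equal(as.numeric(salt_bridge_occupancy(list(sb2), 148, 233)),
               as.numeric(salt_bridge_occupancy(list(sb1), 148, 233)))
  # dihedral magnitude preserved under proper rotation
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0.5, 0.866, 1))
  pr <- lapply(p, function(q) as.numeric(R %*% q + tr))
  expect_equal(dihedral(pr[[1]], pr[[2]], pr[[3]], pr[[4]]),
               dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), tolerance = 1e-9)
})

test_that("water_rdf is ~1 for Poisson points and peaks at a shell", {
  frames <- gen_water_frames(n_water = 5000, box = c(40, 40, 40),
                             n_frames = 3, seed = 8)
  rdf <- water_rdf(frames, ref_sel = list(resno = 1, atom = "REF"),
                   r_max = 12, bin_width = 1.0)
  mid <- rdf$r > 5.5
  # tolerance fixed by simulation: max mid-range deviation over 30 seeds
  # at this density / bin width was 0.18
  expect_lt(max(abs(rdf$g[mid] - 1)), 0.25)
  expect_lt(mean(abs(rdf$g[mid] - 1)), 0.1)
  # single shell of waters at r0 = 5
  r0 <- 5
  dirs <- petkit:::with_seed(9, petkit:::runit(400))
  shell <- md_frame(resno = c(1L, seq_len(400) + 1L),
                    resname = c("REF", rep("HOH", 400)),
                    atom = c("REF", rep("O", 400)),
                    x = c(20, 20 + r0 * dirs[, 1]),
                    y = c(20, 20 + r0 * dirs[, 2]),
                    z = c(20, 20 + r0 * dirs[, 3]), box = c(40, 40, 40))
  rdf2 <- water_rdf(list(shell), ref_sel = list(resno = 1, atom = "REF"),
                    r_max = 10, bin_width = 0.5)
  expect_equal(rdf2$r[which.max(rdf2$g)], r0 + 0.25, tolerance = 0.5)
  expect_error(water_rdf(list(shell), list(resno = 1, atom = "REF"),
                         water_resname = "WAT"),
               "no water")
})

test_that("kabsch_superpose: identity, rigid invariance, jitter expectation", {
  s <- toy_structure(n = 30)
  expect_equal(kabsch_superpose(s, s)$rmsd, 0, tolerance = 1e-12)
  # rigidly moved copy superposes to zero
  moved <- transform_frame(s, rotation_xyz(0.3, 1.2, -0.8), c(10, -4, 2))
  ks <- kabsch_superpose(s, moved)
  expect_equal(ks$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(ks$rotation), 1, tolerance = 1e-9)
  # transform() maps mobile onto reference
  back <- ks$transform(as.matrix(moved[, c("x", "y", "z")]))
  expect_equal(max(abs(back - as.matrix(s[, c("x", "y", "z")]))), 0,
               tolerance = 1e-9)
  # jittered copy: RMSD ~ sd * sqrt(3) (within Monte-Carlo tolerance)
  big <- toy_structure(n = 400, seed = 77)
  pert <- gen_perturbed_structure(big, jitter_sd = 0.2, seed = 78)
  expect_equal(kabsch_superpose(big, pert)$rmsd, 0.2 * sqrt(3),
               tolerance = 0.1)
  expect_error(kabsch_superpose(s[1:2, ], s[1:2, ]), "at least 3")
})

test_that("kabsch equals brute-force rotation search on toy systems", {
  # independent oracle: minimize RMSD over Euler angles from a coarse grid
  brute_rmsd <- function(ref, mob) {
    P <- as.matrix(mob[, c("x", "y", "z")])
    Q <- as.matrix(ref[, c("x", "y", "z")])
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    f <- function(a) sqrt(mean(rowSums((Pc %*% t(rotation_xyz(a[1], a[2], a[3])) - Qc)^2)))
    grid <- expand.grid(a = seq(-pi, pi, length.out = 7),
                        b = seq(-pi / 2, pi / 2, length.out = 5),
                        c = seq(-pi, pi, length.out = 7))
    vals <- apply(grid, 1, f)
    start <- as.numeric(grid[which.min(vals), ])
    stats::optim(start, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }
  set.seed(55)
  for (k in 1:3) {
    ref <- toy_structure(n = 5, seed = 200 + k)
    mob <- gen_perturbed_structure(ref, jitter_sd = 0.3, seed = 300 + k)
    expect_equal(kabsch_superpose(ref, mob)$rmsd, brute_rmsd(ref, mob),
                 tolerance = 1e-3)
  }
})
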