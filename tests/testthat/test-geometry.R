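# Hand-built topology: basic residues with a single side-chain nitrogen and
# lipids with one phosphate oxygen, for salt-bridge unit tests.
sb_system <- function(n_frames, n_xyz, o_xyz, resnames = "ARG",
                      n_names = "NE") {
  nr <- length(n_names)
  nl <- nrow(o_xyz) / n_frames
  atoms <- rbind(
    do.call(rbind, lapply(seq_len(nr), function(i) {
      protein_atom_row(i, n_names[i], resnames[min(i, length(resnames))], i,
                       element = "N")
    })),
    data.frame(atom_id = nr + seq_len(nl), atom_name = "O11", element = "O",
               resname = "POPA", resnum = seq_len(nl), chain = "L")
  )
  co <- array(NA_real_, c(nr + nl, 3, n_frames))
  for (f in seq_len(n_frames)) {
    co[seq_len(nr), , f] <- n_xyz
    co[nr + seq_len(nl), , f] <- o_xyz[(f - 1) * nl + seq_len(nl), ,
                                       drop = FALSE]
  }
  toy_trajectory(atoms, co)
}

test_that("salt-bridge events are maximal runs under the N...O cutoff", {
  o <- matrix(rep(c(0, 0, 3.5), 5), ncol = 3, byrow = TRUE)
  traj <- sb_system(5, matrix(c(0, 0, 0), 1), o)
  ev <- salt_bridges(traj)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 5L)
  expect_equal(ev$t_i_ps, 0)
  expect_equal(ev$t_f_ps, 40)
  expect_equal(ev$n_atom, "NE")
  expect_equal(ev$o_atom, "O11")

  # degenerate zero cutoff finds nothing
  expect_equal(nrow(salt_bridges(traj, d_sb = 0)), 0L)

  # no basic residues: warning + empty
  atoms <- rbind(protein_atom_row(1, "CA", "GLY", 1), lipid_bead_rows(2, 1))
  t2 <- toy_trajectory(atoms, cbind(c(0, 0), c(0, 0), c(0, 3)))
  expect_warning(ev2 <- salt_bridges(t2), "basic")
  expect_equal(nrow(ev2), 0L)
})

test_that("two residues sharing one PA give two fully overlapping events", {
  n_xyz <- rbind(c(-2, 0, 0), c(2, 0, 0))
  o <- matrix(rep(c(0, 0, 1.5), 100), ncol = 3, byrow = TRUE)
  traj <- sb_system(100, n_xyz, o, n_names = c("NE", "NE"))
  ev <- salt_bridges(traj)
  expect_equal(nrow(ev), 2L)
  expect_equal(unique(ev$lipid_id), "POPA:L:1")
  expect_equal(ev$n_frames, c(100L, 100L))

  mv <- multivalent_episodes(ev)
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$n_frames, 100L)
  expect_equal(mv$n_residues, 2L)
})

test_that("salt bridges agree with a brute-force distance scan", {
  set.seed(17)
  n_xyz <- cbind(runif(3, -5, 5), runif(3, -5, 5), runif(3, -2, 2))
  o <- cbind(runif(40, -6, 6), runif(40, -6, 6), runif(40, -3, 3))
  traj <- sb_system(10, n_xyz, o, n_names = c("NE", "NZ", "NE"),
                    resnames = c("ARG", "LYS", "ARG"))
  ev <- salt_bridges(traj, d_sb = 4)
  # oracle: per frame, per (residue, lipid), explicit min distance
  active <- array(FALSE, c(3, 4, 10))
  for (f in 1:10) {
    xyz <- matrix(traj$coords[, , f], ncol = 3)
    for (r in 1:3) {
      for (l in 1:4) {
        d <- sqrt(sum((xyz[r, ] - xyz[3 + l, ])^2))
        active[r, l, f] <- d <= 4
      }
    }
  }
  # total active frames must match summed event lengths
  expect_equal(sum(active), sum(ev$n_frames))
})

test_that("multivalent interval algebra intersects per-lipid events", {
  dt <- 10
  ev <- tibble::tibble(
    chain = "A", resnum = c(391L, 398L), resname = "ARG",
    lipid_id = "POPA:L:1", species = "POPA",
    n_atom = "NE", o_atom = "O11",
    t_i_ps = c(0, 200), t_f_ps = c(490, 800),
    n_frames = c(50L, 61L)
  )
  attr(ev, "dt") <- dt
  mv <- multivalent_episodes(ev)
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$t_start_ps, 200)
  expect_equal(mv$t_end_ps, 490)
  expect_equal(mv$n_frames, 30L)
  expect_true(grepl("391", mv$residues) && grepl("398", mv$residues))

  # disjoint events yield nothing
  ev2 <- ev
  ev2$t_i_ps <- c(0, 500); ev2$t_f_ps <- c(490, 800)
  attr(ev2, "dt") <- dt
  expect_equal(nrow(multivalent_episodes(ev2)), 0L)

  # a scripted three-residue groove reports a partner set of three
  ev3 <- tibble::tibble(
    chain = "A", resnum = c(391L, 398L, 399L), resname = "ARG",
    lipid_id = "POPA:L:2", species = "POPA", n_atom = "NE", o_atom = "O11",
    t_i_ps = 0, t_f_ps = 90, n_frames = 10L
  )
  attr(ev3, "dt") <- dt
  mv3 <- multivalent_episodes(ev3)
  expect_equal(mv3$n_residues, 3L)

  # every multivalent interval lies inside each contributing event
  expect_true(mv$t_start_ps >= max(pmin(ev$t_i_ps, ev$t_f_ps)[1], ev$t_i_ps[2]))
  expect_true(mv$t_end_ps <= min(ev$t_f_ps))
})

test_that("shared-lipid episodes track region handoffs in order", {
  # regions A = residue 1, B = residue 2; schedule A -> A+B -> B
  arr <- array(FALSE, c(2, 1, 9))
  arr[1, 1, 1:5] <- TRUE
  arr[2, 1, 4:9] <- TRUE
  s <- manual_series(arr)
  ep <- shared_lipid_regions(s, regions = list(A = 1L, B = 2L))
  expect_equal(nrow(ep), 3L)
  expect_equal(ep$regions, c("A", "A,B", "B"))
  expect_equal(ep$n_frames, c(3L, 2L, 4L))
  # windows partition the lipid's in-contact frames exactly
  expect_equal(sum(ep$n_frames), sum(apply(arr, 3, any)))

  # single-region lipid: one window
  arr2 <- array(FALSE, c(2, 1, 6)); arr2[1, 1, ] <- TRUE
  ep2 <- shared_lipid_regions(manual_series(arr2),
                              regions = list(A = 1L, B = 2L))
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$regions, "A")

  # lipid never in contact: no episode
  ep3 <- shared_lipid_regions(manual_series(array(FALSE, c(2, 1, 6))),
                              regions = list(A = 1L, B = 2L))
  expect_equal(nrow(ep3), 0L)
})

test_that("helix tilt is measured from the membrane normal", {
  n_ca <- 20
  ca_x <- ideal_helix_ca(n = n_ca, axis = c(1, 0, 0))
  atoms <- do.call(rbind, lapply(seq_len(n_ca), function(i) {
    protein_atom_row(i, "CA", "ALA", i)
  }))
  t_x <- toy_trajectory(atoms, ca_x)
  th_x <- helix_orientation(t_x, helix_resnums = seq_len(n_ca))$theta_deg
  expect_lt(abs(th_x - 90), 1)

  ca_z <- ideal_helix_ca(n = n_ca, axis = c(0, 0, 1))
  th_z <- helix_orientation(toy_trajectory(atoms, ca_z),
                            helix_resnums = seq_len(n_ca))$theta_deg
  expect_lt(abs(th_z - 0), 1)

  # rotating an axis-aligned frame about y shifts theta by exactly the angle
  ca_line <- cbind(0, 0, 1.5 * seq_len(n_ca))   # degenerate: a straight axis
  th_line <- helix_orientation(toy_trajectory(atoms, ca_line),
                               helix_resnums = seq_len(n_ca))$theta_deg
  expect_equal(th_line, 0, tolerance = 1e-8)
  ca_rot <- ca_line %*% t(rotation_about_y(30))
  th_rot <- helix_orientation(toy_trajectory(atoms, ca_rot),
                              helix_resnums = seq_len(n_ca))$theta_deg
  expect_equal(th_rot - th_line, 30, tolerance = 1e-6)

  # theta is invariant under rotation about z and translation
  rz <- matrix(c(cos(0.7), -sin(0.7), 0, sin(0.7), cos(0.7), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  th_rz <- helix_orientation(toy_trajectory(atoms, ca_x %*% t(rz) + 5),
                             helix_resnums = seq_len(n_ca))$theta_deg
  expect_equal(th_rz, th_x, tolerance = 1e-8)

  expect_error(helix_orientation(t_x, helix_resnums = 1:3), ">= 4")
})

test_that("spine collinearity is the RMS deviation from the best-fit line", {
  # four residues, one heavy side-chain atom each
  mk <- function(centroids) {
    n <- nrow(centroids)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(protein_atom_row(2 * i - 1, "CA", "PHE", i),
            protein_atom_row(2 * i, "CG", "PHE", i))
    }))
    co <- matrix(NA_real_, 2 * n, 3)
    co[seq(1, 2 * n, 2), ] <- centroids + 10   # backbone, ignored
    co[seq(2, 2 * n, 2), ] <- centroids
    toy_trajectory(atoms, co)
  }
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_lt(mk(line) |> spine_collinearity(spine_resnums = 1:4) |>
              (\(d) d$rms_dev)(), 1e-10)

  # one point displaced off a straight line: closed-form RMS
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1.5, 2, 0))
  dev <- spine_collinearity(mk(pts), spine_resnums = 1:4)$rms_dev
  fit <- prcomp(pts)
  resid <- pts - (fit$x[, 1] %*% t(fit$rotation[, 1]) +
                    matrix(colMeans(pts), 4, 3, byrow = TRUE))
  expect_equal(dev, sqrt(mean(rowSums(resid^2))), tolerance = 1e-10)

  # five collinear residues stay at zero
  line5 <- cbind(1:5, 1:5, 1:5)
  expect_lt(spine_collinearity(mk(line5), spine_resnums = 1:5)$rms_dev, 1e-10)

  # glycine has no side chain
  g_atoms <- rbind(protein_atom_row(1, "CA", "GLY", 1),
                   protein_atom_row(2, "CA", "PHE", 2),
                   protein_atom_row(3, "CG", "PHE", 2),
                   protein_atom_row(4, "CA", "PHE", 3),
                   protein_atom_row(5, "CG", "PHE", 3),
                   protein_atom_row(6, "CA", "PHE", 4),
                   protein_atom_row(7, "CG", "PHE", 4))
  gt <- toy_trajectory(g_atoms, matrix(runif(21), 7, 3))
  expect_error(spine_collinearity(gt, spine_resnums = 1:4), "[Gg]lycine|side-chain")
})

test_that("inter-chain minimum distances flag only genuine proximity", {
  two_chains <- function(offset) {
    atoms <- rbind(protein_atom_row(1, "CA", "ARG", 1, chain = "A"),
                   protein_atom_row(2, "CB", "ARG", 1, chain = "A"),
                   protein_atom_row(3, "CA", "ARG", 1, chain = "B"),
                   protein_atom_row(4, "CB", "ARG", 1, chain = "B"))
    co <- rbind(c(0, 0, 0), c(1, 0, 0), c(offset, 0, 0), c(offset + 1, 0, 0))
    toy_trajectory(atoms, co, box = c(200, 200, 200))
  }
  far <- interchain_independence(two_chains(60))
  expect_false(any(far$flagged))
  expect_equal(far$min_dist, 59)

  near <- interchain_independence(two_chains(0.5))
  expect_true(all(near$flagged))

  # oracle agreement on a random 2 x 5-atom toy
  set.seed(3)
  atoms <- do.call(rbind, lapply(1:10, function(i) {
    protein_atom_row(i, "CA", "ALA", i, chain = if (i <= 5) "A" else "B")
  }))
  co <- matrix(runif(30, -20, 20), 10, 3)
  trj <- toy_trajectory(atoms, co, box = c(200, 200, 200))
  got <- interchain_independence(trj)$min_dist
  oracle <- min(sqrt(outer(rowSums(co[1:5, ]^2), rowSums(co[6:10, ]^2), "+") -
                       2 * co[1:5, ] %*% t(co[6:10, ])))
  expect_equal(got, oracle, tolerance = 1e-10)

  expect_error(interchain_independence(two_chains(60), chains = "A"), "2")
})
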