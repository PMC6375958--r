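# Builders for in-plane lipid fields around a single reference bead.
field_traj <- function(positions_by_frame, L = 100, ref_z = 20, lip_z = 18) {
  nl <- nrow(positions_by_frame[[1]])
  atoms <- rbind(protein_atom_row(1, "CA", "GLY", 1),
                 lipid_bead_rows(1 + seq_len(nl), seq_len(nl)))
  nf <- length(positions_by_frame)
  co <- array(NA_real_, c(nl + 1, 3, nf))
  for (f in seq_len(nf)) {
    co[1, , f] <- c(0, 0, ref_z)
    co[1 + seq_len(nl), 1:2, f] <- positions_by_frame[[f]]
    co[1 + seq_len(nl), 3, f] <- lip_z
  }
  toy_trajectory(atoms, co, box = c(L, L, 80))
}

uniform_frames <- function(nl, nf, L = 100) {
  lapply(seq_len(nf), function(f) cbind(runif(nl, -L / 2, L / 2),
                                        runif(nl, -L / 2, L / 2)))
}

test_that("a uniform lipid field gives g = 1 within 3-sigma Poisson bands", {
  set.seed(55)
  traj <- field_traj(uniform_frames(nl = 1500, nf = 80))
  prof <- rdf2d(traj, ref_atoms = 1, species = "POPA", leaflet = "both",
                r_max = 12, dr = 0.5)
  rho <- 1500 / 100^2
  n_exp <- 80 * rho * 2 * pi * prof$r * 0.5
  expect_true(all(abs(prof$g - 1) <= 3 / sqrt(n_exp)))
})

test_that("a lipid pinned at 4 Angstrom occupies exactly one bin", {
  frames <- lapply(1:5, function(f) cbind(4.0, 0))
  prof <- rdf2d(field_traj(frames), ref_atoms = 1, species = "POPA",
                leaflet = "both", r_max = 8, dr = 0.5)
  occupied <- which(prof$g > 0)
  expect_length(occupied, 1L)
  expect_lt(abs(prof$r[occupied] - 4.0), 0.5)
})

test_that("the RDF equals a hand-normalised brute-force pair count", {
  set.seed(77)
  pos <- cbind(runif(10, -40, 40), runif(10, -40, 40))
  traj <- field_traj(list(pos))
  dr <- 1; r_max <- 12; L <- 100
  prof <- rdf2d(traj, ref_atoms = 1, species = "POPA", leaflet = "both",
                r_max = r_max, dr = dr)
  # oracle: explicit distances, explicit ideal-density normalisation
  d <- sqrt(rowSums(sweep(pos, 2, c(0, 0))^2))
  counts <- sapply(seq_len(r_max / dr), function(b) {
    sum(d >= (b - 1) * dr & d < b * dr)
  })
  rho <- 10 / L^2
  centers <- (seq_len(r_max / dr) - 0.5) * dr
  g_oracle <- counts / (rho * 2 * pi * centers * dr)
  expect_equal(prof$g, g_oracle, tolerance = 1e-12)
})

test_that("integrating rho * g * 2 pi r dr recovers the mean neighbour count", {
  set.seed(88)
  traj <- field_traj(uniform_frames(nl = 200, nf = 10))
  dr <- 0.4; r_max <- 15
  prof <- rdf2d(traj, ref_atoms = 1, species = "POPA", leaflet = "both",
                r_max = r_max, dr = dr)
  rho <- attr(prof, "mean_density")
  integral <- sum(rho * prof$g * 2 * pi * prof$r * dr)
  # direct mean count of lipids within r_max of the reference
  xyz <- traj$coords
  counts <- sapply(seq_len(traj$n_frames), function(f) {
    dx <- xyz[-1, 1, f]; dy <- xyz[-1, 2, f]
    sum(sqrt(dx^2 + dy^2) < r_max)
  })
  expect_equal(integral, mean(counts), tolerance = 1e-10)
})

test_that("the RDF is invariant to rigid in-plane translation", {
  set.seed(13)
  frames <- uniform_frames(nl = 100, nf = 5)
  t1 <- field_traj(frames)
  t2 <- field_traj(lapply(frames, function(p) sweep(p, 2, c(-31.4, 8.8), "+")))
  t2$coords[1, 1:2, ] <- t2$coords[1, 1:2, ] + c(-31.4, 8.8)
  p1 <- rdf2d(t1, 1, leaflet = "both", r_max = 12, dr = 0.5)
  p2 <- rdf2d(t2, 1, leaflet = "both", r_max = 12, dr = 0.5)
  expect_equal(p1$g, p2$g, tolerance = 1e-12)
})

test_that("time-block profiles agree on stationary fields and flag drift", {
  set.seed(91)
  traj <- field_traj(uniform_frames(nl = 3000, nf = 400))
  blocks <- lapply(0:3, function(k) c(k * 1000, k * 1000 + 990))
  conv <- rdf_convergence(traj, 1, leaflet = "both", r_max = 10, dr = 2,
                          blocks = blocks)
  expect_true(all(conv$metric$max_abs_dev < 0.2))

  whole <- rdf_convergence(traj, 1, leaflet = "both", r_max = 10, dr = 2,
                           blocks = list(c(0, 1e9)))
  expect_equal(whole$metric$max_abs_dev, 0)

  # non-stationary: lipids pulled toward the reference in the late half
  drift <- lapply(1:80, function(f) {
    p <- cbind(runif(400, -50, 50), runif(400, -50, 50))
    if (f > 40) p <- p * 0.25
    p
  })
  dtraj <- field_traj(drift)
  dconv <- rdf_convergence(dtraj, 1, leaflet = "both", r_max = 10, dr = 1,
                           blocks = list(c(0, 390), c(400, 790)))
  expect_gt(max(dconv$metric$max_abs_dev), 0.2)
  expect_error(rdf_convergence(traj, 1, blocks = list(c(10, 10))), "block")
})

test_that("global species fractions come from the topology composition", {
  spec <- synth_spec(n_popc = 183, n_popa = 25, box = c(120, 120, 76),
                     n_frames = 2,
                     peptides = synth_peptide("RKTR", chain = "A",
                                              start_resnum = 398,
                                              spacing = 8),
                     seed = 6)
  sim <- synth_generate(spec)
  enr <- enrichment(sim$trajectory, region_resnums = 398:401)
  expect_equal(enr$global_fraction, 50 / 416, tolerance = 1e-12)
  expect_equal(round(enr$global_fraction, 3), 0.120)
})

test_that("a well-mixed fixture shows no enrichment beyond binomial noise", {
  pep <- synth_peptide("RKTR", chain = "A", start_resnum = 398, spacing = 8)
  spec <- synth_spec(n_popc = 44, n_popa = 6, box = c(70, 70, 76),
                     n_frames = 400, sigma = 6, peptides = pep, seed = 123)
  sim <- synth_generate(spec)
  enr <- enrichment(sim$trajectory, region_resnums = 398:401)
  # near lipids are a near-binomial sample of the leaflet composition
  n_eff <- enr$mean_near * enr$n_frames
  p0 <- enr$global_fraction
  se <- sqrt(p0 * (1 - p0) / n_eff)
  expect_false(enr$undefined)
  expect_lt(abs(enr$local_fraction - p0), 1.96 * se + 0.02)
})

test_that("sticky PA sites produce local enrichment above the global fraction", {
  pep <- synth_peptide("RKTR", chain = "A", start_resnum = 398, spacing = 8)
  rules <- lapply(1:4, function(i) {
    list(chain = "A", resnum = 397L + i, lipid = 44L + i,
         intervals = rbind(c(1, 300)))
  })
  spec <- synth_spec(n_popc = 44, n_popa = 6, box = c(70, 70, 76),
                     n_frames = 300, peptides = pep, binding = rules,
                     seed = 5)
  sim <- synth_generate(spec)
  enr <- enrichment(sim$trajectory, region_resnums = 398:401)
  expect_gt(enr$local_fraction, enr$global_fraction)

  # a region nothing ever approaches is flagged undefined
  pep2 <- dplyr::bind_rows(pep, synth_peptide("G", chain = "B",
                                              start_resnum = 900,
                                              center = c(30, 30),
                                              leaflet = "lower"))
  spec2 <- synth_spec(n_popc = 4, n_popa = 2, box = c(70, 70, 76),
                      n_frames = 3, sigma = 0, peptides = pep2,
                      binding = lapply(1:6, function(l) {
                        list(chain = "A", resnum = 398L, lipid = l,
                             intervals = rbind(c(1, 3))
                        )
                      })[1], seed = 8)
  sim2 <- synth_generate(spec2)
  enr2 <- enrichment(sim2$trajectory, region_resnums = 900, chain = "B")
  expect_true(enr2$undefined)
  expect_true(is.na(enr2$local_fraction))
})
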