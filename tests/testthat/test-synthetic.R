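test_that("generation is deterministic and fixtures round-trip on disk", {
  spec <- synth_spec(n_popc = 8, n_popa = 4, box = c(70, 70, 76),
                     n_frames = 12,
                     peptides = synth_peptide("RKT", chain = "A",
                                              start_resnum = 398, spacing = 8),
                     binding = list(list(chain = "A", resnum = 398, lipid = 9,
                                         intervals = rbind(c(3, 9)))),
                     seed = 77)
  sim1 <- synth_generate(spec)
  sim2 <- synth_generate(spec)
  expect_identical(sim1$trajectory$coords, sim2$trajectory$coords)

  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(sim1, d1)
  write_fixture(sim2, d2)
  expect_identical(readLines(file.path(d1, "traj.mtraj")),
                   readLines(file.path(d2, "traj.mtraj")))

  back <- read_fixture(d1)
  expect_lt(max(abs(back$trajectory$coords - sim1$trajectory$coords)), 1e-5)
  expect_equal(back$manifest$seed, 77)
  expect_equal(back$manifest$schedule$start_frame, 3)
  expect_match(back$manifest$rng, "lcg32")
})

test_that("the manifest RNG recurrence replays free-lipid positions", {
  spec <- synth_spec(n_popc = 3, n_popa = 1, box = c(70, 70, 76),
                     n_frames = 10, sigma = 0.4, peptides = NULL, seed = 31)
  sim <- synth_generate(spec)
  # independent replay of lipid 2 from the documented recurrence
  M <- 2^32
  s <- (31 + 2654435761 * 2) %% M
  for (k in 1:2) s <- (1664525 * s + 1013904223) %% M
  draw <- function() {
    s <<- (1664525 * s + 1013904223) %% M
    (s + 0.5) / M
  }
  x <- draw() * 70 - 35
  y <- draw() * 70 - 35
  lip_row <- which(sim$topology$atoms$resnum == 2 &
                     sim$topology$atoms$chain == "L")
  expect_equal(sim$trajectory$coords[lip_row, 1:2, 1], c(x, y))
  for (f in 2:10) {
    u1 <- draw(); u2 <- draw()
    r <- 0.4 * sqrt(-2 * log(u1))
    x <- x + r * cos(2 * pi * u2); y <- y + r * sin(2 * pi * u2)
    x <- x - 70 * round(x / 70);   y <- y - 70 * round(y / 70)
    expect_equal(sim$trajectory$coords[lip_row, 1:2, f], c(x, y))
  }
})

test_that("scripted nanosecond-scale dwell schedules round-trip exactly", {
  pep <- synth_peptide("R", chain = "A", start_resnum = 398, spacing = 8)
  spec <- synth_spec(n_popc = 3, n_popa = 3, box = c(60, 60, 76),
                     n_frames = 50100, peptides = pep,
                     binding = list(list(chain = "A", resnum = 398, lipid = 4,
                                         intervals = rbind(c(1000, 5000),
                                                           c(6000, 18000),
                                                           c(20000, 50000)))),
                     seed = 7)
  sim <- synth_generate(spec)
  ev <- dwell_events(contact_series(sim$trajectory), residues = "all",
                     species = "POPA")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$t_res_ps, c(40e3, 120e3, 300e3))   # 40, 120, 300 ns
  expect_equal(ev$t_i_ps, c(999, 5999, 19999) * 10)
  expect_false(any(ev$censored))
})

test_that("degenerate specs behave sensibly", {
  # zero lipids: a valid trajectory whose lipid analyses error cleanly
  spec0 <- synth_spec(n_popc = 0, n_popa = 0, box = c(70, 70, 76),
                      n_frames = 3,
                      peptides = synth_peptide("RK", chain = "A",
                                               start_resnum = 1, spacing = 8),
                      seed = 1)
  sim0 <- synth_generate(spec0)
  expect_equal(sim0$trajectory$n_frames, 3L)
  expect_error(contact_series(sim0$trajectory), "headgroup")
  expect_error(assign_leaflets(sim0$trajectory), "lipid")

  # overlapping scripted intervals are rejected
  expect_error(
    synth_spec(n_popc = 2, n_popa = 1, box = c(60, 60, 76), n_frames = 20,
               peptides = synth_peptide("R", chain = "A", start_resnum = 1),
               binding = list(list(chain = "A", resnum = 1, lipid = 3,
                                   intervals = rbind(c(1, 10), c(5, 15))))),
    "Overlapping")

  # a rule lipid must live in the residue's leaflet
  expect_error(synth_generate(
    synth_spec(n_popc = 2, n_popa = 2, box = c(60, 60, 76), n_frames = 5,
               peptides = synth_peptide("R", chain = "A", start_resnum = 1),
               binding = list(list(chain = "A", resnum = 1, lipid = 7,
                                   intervals = rbind(c(1, 3)))))),
    "leaflet")

  # box too small for the lipid count
  expect_error(synth_spec(n_popc = 100, n_popa = 0, box = c(50, 50, 76),
                          n_frames = 2), "area per lipid")
})

test_that("an unbiased fixture matches the geometric chance rate", {
  pep <- synth_peptide("RKTRAK", chain = "A", start_resnum = 1, spacing = 9)
  spec <- synth_spec(n_popc = 36, n_popa = 6, box = c(70, 70, 76),
                     n_frames = 800, sigma = 6, peptides = pep, seed = 2718)
  sim <- synth_generate(spec)
  p <- contact_probability(contact_series(sim$trajectory))
  # empirical chance rate: probe points sprinkled on the same frames
  set.seed(1)
  n_probe <- 300
  px <- runif(n_probe, -35, 35); py <- runif(n_probe, -35, 35)
  side_z <- 20   # side-bead height used by the generator
  hits <- 0L; tries <- 0L
  lip_rows <- which(sim$topology$atoms$chain == "L" &
                      sim$topology$atoms$resnum <= 42)  # upper leaflet
  for (f in seq(1, 800, by = 40)) {
    xyz <- sim$trajectory$coords[, , f]
    for (q in seq_len(n_probe)) {
      dx <- xyz[lip_rows, 1] - px[q]; dx <- dx - 70 * round(dx / 70)
      dy <- xyz[lip_rows, 2] - py[q]; dy <- dy - 70 * round(dy / 70)
      dz <- xyz[lip_rows, 3] - side_z
      hits <- hits + any(dx^2 + dy^2 + dz^2 <= 16)
      tries <- tries + 1L
    }
  }
  p_chance <- hits / tries
  # every residue's occupancy within the binomial 99% interval of chance
  half <- 2.576 * sqrt(p_chance * (1 - p_chance) / 800)
  expect_true(all(abs(p$p_contact - p_chance) <= half + 0.01))
})

test_that("stochastic unbinding probability is recovered from mean dwell", {
  pep <- synth_peptide("RRR", chain = "A", start_resnum = 1, spacing = 9)
  rules <- lapply(1:3, function(i) {
    list(chain = "A", resnum = i, lipid = 9L + i, p_bind = 0.2,
         p_unbind = 0.02)
  })
  spec <- synth_spec(n_popc = 9, n_popa = 3, box = c(70, 70, 76),
                     n_frames = 4000, peptides = pep, binding = rules,
                     seed = 11)
  sim <- synth_generate(spec)
  ev <- dwell_events(contact_series(sim$trajectory), residues = "all",
                     species = "POPA")
  keep <- ev[!ev$censored, ]
  # p recovered as dt / (mean dwell + dt)
  p_hat <- 10 / (mean(keep$t_res_ps) + 10)
  se <- 0.02 / sqrt(nrow(keep))   # delta-method scale
  expect_lt(abs(p_hat - 0.02), 4 * se)
})
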