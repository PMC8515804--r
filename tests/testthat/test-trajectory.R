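# Ensemble profiling: RMSD, windows, RMSF, distributions, snapshots,
# contacts, occupancy.

test_that("rmsd_series removes rigid motion and matches the quaternion oracle", {
  set.seed(21)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  # frame 2: pure translation; frame 3: rotation; frame 4: one atom displaced
  rot <- random_rotation_matrix()
  disp <- base
  disp[4, ] <- disp[4, ] + c(0.9, 0, 0)
  x <- toy_ensemble(list(base,
                         base + matrix(c(5, 0, 0), 10, 3, byrow = TRUE),
                         base %*% t(rot),
                         disp))
  r <- rmsd_series(x, reference_frame = 1)
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_equal(r[2], 0, tolerance = 1e-9)
  expect_equal(r[3], 0, tolerance = 1e-9)
  expect_lte(r[4], 0.9 / sqrt(10) + 1e-9)
  expect_equal(r[4], oracle_quaternion_rmsd(base, disp), tolerance = 1e-7)

  ident <- toy_ensemble(list(base, base, base))
  expect_equal(rmsd_series(ident), rep(0, 3), tolerance = 1e-9)
})

test_that("rmsd after fit agrees with the quaternion oracle on random pairs", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    a <- matrix(rnorm(3 * n, sd = 3), n, 3)
    b <- a + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    x <- toy_ensemble(list(a, b))
    expect_equal(rmsd_series(x)[2], oracle_quaternion_rmsd(a, b),
                 tolerance = 1e-6)
  }
})

test_that("rmsd series is invariant under a global rigid transform", {
  set.seed(23)
  frames <- lapply(1:6, function(i) matrix(rnorm(24, sd = 3), 8, 3))
  x <- toy_ensemble(frames)
  r0 <- rmsd_series(x)
  x2 <- transform_structure(x, random_rotation_matrix(), rnorm(3, sd = 30))
  expect_equal(rmsd_series(x2), r0, tolerance = 1e-9)
})

test_that("sliding windows reproduce direct enumeration", {
  # constant series
  w <- sliding_window_stats(rep(2.5, 20), window = 5)
  expect_true(all(w$mean == 2.5 & w$min == 2.5 & w$max == 2.5))
  # window 1, one replicate: identity
  v <- c(3, 1, 4, 1, 5)
  w1 <- sliding_window_stats(v, window = 1)
  expect_equal(w1$mean, v)
  expect_equal(w1$min, v)
  expect_equal(w1$max, v)
  # three replicate ramps vs exhaustive enumeration
  reps <- rbind(seq(0, 19), seq(5, 24), seq(-3, 16))
  w3 <- sliding_window_stats(reps, window = 4)
  for (k in seq_len(nrow(w3))) {
    block <- reps[, k:(k + 3)]
    expect_equal(w3$mean[k], mean(block))
    expect_equal(w3$min[k], min(block))
    expect_equal(w3$max[k], max(block))
  }
  expect_true(all(w3$min <= w3$mean & w3$mean <= w3$max))
  expect_error(sliding_window_stats(v, window = 6), "exceeds")
  expect_error(sliding_window_stats(v, window = 0), ">= 1")
})

test_that("rmsf is zero for a static ensemble and d for a symmetric two-state", {
  set.seed(31)
  base <- matrix(rnorm(15, sd = 5), 5, 3)
  x <- toy_ensemble(rep(list(base), 8))
  r <- rmsf_per_residue(x, "all", fit = FALSE)
  expect_equal(r$rmsf, rep(0, 5), tolerance = 1e-12)

  # residue 3 oscillates +/- d along x about its mean; others fixed
  d <- 0.7
  up <- base; up[3, 1] <- up[3, 1] + d
  dn <- base; dn[3, 1] <- dn[3, 1] - d
  x2 <- toy_ensemble(rep(list(up, dn), 10))
  r2 <- rmsf_per_residue(x2, "all", fit = FALSE)
  expect_equal(r2$rmsf[r2$resno == 3], d, tolerance = 1e-12)
  expect_equal(r2$rmsf[r2$resno != 3], rep(0, 4), tolerance = 1e-12)
})

test_that("rmsf of iid Gaussian noise approaches sigma * sqrt(3)", {
  set.seed(32)
  sigma <- 0.2
  base <- matrix(rnorm(9, sd = 5), 3, 3)
  frames <- lapply(1:4000, function(i) base + matrix(rnorm(9, sd = sigma),
                                                     3, 3))
  x <- toy_ensemble(frames)
  r <- rmsf_per_residue(x, "all", fit = FALSE)
  expect_equal(r$rmsf, rep(sigma * sqrt(3), 3), tolerance = 0.05)
})

test_that("side-chain policy selects base atoms of nucleotides", {
  s <- read_structure(hairpin_path("GAAA"))
  x <- anionpi:::as_nucleic_structure(s$atoms, rbind(s$xyz, s$xyz))
  r <- rmsf_per_residue(x, "side_chain", fit = FALSE)
  # all atoms selected are base atoms: count matches template sizes (G=11,
  # A=10, C=8, U=8) for sequence C C G A A A U U
  expect_equal(r$n_atoms, c(8, 8, 11, 10, 10, 10, 8, 8))
  expect_equal(r$rmsf, rep(0, 8), tolerance = 1e-12)
})

test_that("descriptor distribution conserves counts and finds the mode", {
  ser <- data.frame(R = rep(3.05, 7), A = rep(88, 7))
  h <- descriptor_distribution(ser)
  expect_equal(sum(h$counts), 7)
  expect_equal(h$n_total, 7)
  expect_equal(sum(h$counts > 0), 1)
  expect_lt(abs(h$mode["R"] - 3.05), 0.1)
  expect_lt(abs(h$mode["A"] - 88), 5)

  set.seed(41)
  ser2 <- data.frame(R = runif(500, 2, 5), A = runif(500, 40, 140))
  h2 <- descriptor_distribution(ser2)
  expect_equal(sum(h2$counts), 500)
  # marginals equal independently computed 1-D histograms
  r_marg <- rowSums(h2$counts)
  a_marg <- colSums(h2$counts)
  r_ora <- hist(ser2$R, breaks = h2$r_edges, plot = FALSE, right = FALSE)
  a_ora <- hist(ser2$A, breaks = h2$a_edges, plot = FALSE, right = FALSE)
  expect_equal(r_marg, r_ora$counts, ignore_attr = TRUE)
  expect_equal(a_marg, a_ora$counts, ignore_attr = TRUE)
})

test_that("descriptor distribution correlation reflects the generator", {
  ts <- simulate_two_state_ensemble(2000, seed = 19)
  ser <- anion_pi_series(ts$structure, ts$assignment)
  h <- descriptor_distribution(ser)
  # far state has broader angular scatter: |A - 90| grows with R
  expect_gt(cor(ser$R, abs(ser$A - 90)), 0.2)
  expect_equal(h$n_total, 2000)
})

test_that("snapshot selection picks peak and tail frames deterministically", {
  ser <- data.frame(frame = 1:10, R = seq(2, 4.7, length.out = 10),
                    A = rep(90, 10))
  expect_equal(select_snapshots(ser, 2, "low_tail"), c(1, 2))
  expect_equal(select_snapshots(ser, 2, "high_tail"), c(9, 10))
  const <- data.frame(frame = 1:6, R = rep(3, 6), A = rep(90, 6))
  expect_equal(select_snapshots(const, 3, "peak"), c(1, 2, 3))
  expect_error(select_snapshots(const, 7), "exceeds")

  set.seed(51)
  g <- data.frame(frame = 1:500, R = rnorm(500, 3, 0.25), A = 90)
  peak <- select_snapshots(g, 5, "peak")
  expect_true(all(abs(g$R[peak] - mean(g$R)) < sd(g$R)))
})

test_that("native contacts score 1 on the reference and 0 after separation", {
  set.seed(61)
  a <- matrix(rnorm(15, sd = 2), 5, 3)
  b <- a + matrix(rnorm(15, sd = 1), 5, 3)   # interleaved partner
  far_b <- b + matrix(c(100, 0, 0), 5, 3, byrow = TRUE)
  coords <- list(rbind(a, b), rbind(a, far_b))
  x <- toy_ensemble(coords, chain = rep(c("A", "B"), each = 5),
                    resno = rep(1:5, 2))
  nc <- native_contacts(x, "A", "B", cutoff = 4.5)
  expect_equal(nc$fraction[1], 1)
  expect_equal(nc$fraction[2], 0)
})

test_that("native contacts agree with exhaustive enumeration and are symmetric", {
  set.seed(62)
  for (i in 1:30) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- matrix(rnorm(3 * na, sd = 3), na, 3)
    b <- matrix(rnorm(3 * nb, sd = 3), nb, 3)
    pert <- rbind(a, b) + matrix(rnorm(3 * (na + nb), sd = 1.2), na + nb, 3)
    x <- toy_ensemble(list(rbind(a, b), pert),
                      chain = rep(c("A", "B"), c(na, nb)),
                      resno = c(1:na, 1:nb))
    ref_pairs <- 0; kept <- 0
    for (p in 1:na) for (q in 1:nb) {
      if (sqrt(sum((a[p, ] - b[q, ])^2)) <= 4.5) {
        ref_pairs <- ref_pairs + 1
        if (sqrt(sum((pert[p, ] - pert[na + q, ])^2)) <= 4.5) kept <- kept + 1
      }
    }
    if (ref_pairs == 0) {
      expect_error(native_contacts(x, "A", "B"), "no native contacts")
      next
    }
    nc <- native_contacts(x, "A", "B")
    expect_equal(nc$n_pairs, ref_pairs)
    expect_equal(nc$fraction[2], kept / ref_pairs)
    # symmetric in partner labels
    nc_sym <- native_contacts(x, "B", "A")
    expect_equal(nc_sym$fraction, nc$fraction)
  }
})

test_that("native contact fraction is monotone under uniform inflation", {
  set.seed(63)
  a <- matrix(rnorm(18, sd = 2), 6, 3)
  b <- a + matrix(rnorm(18, sd = 0.8), 6, 3)
  scales <- c(1, 1.2, 1.5, 2, 3, 5)
  coords <- lapply(scales, function(s) rbind(a, b) * s)
  x <- toy_ensemble(coords, chain = rep(c("A", "B"), each = 6),
                    resno = rep(1:6, 2))
  nc <- native_contacts(x, "A", "B")
  expect_true(all(diff(nc$fraction) <= 0))
})

test_that("occupancy grids count static and alternating ions exactly", {
  pos1 <- c(2.2, 3.3, 4.4)
  x <- toy_ensemble(rep(list(rbind(pos1)), 7), elety = "K", resid = "K")
  g <- occupancy_grid(x, selection = 1, spacing = 1)
  expect_equal(sum(g$counts), 7)
  expect_equal(max(g$counts), 7)
  expect_equal(sum(g$counts > 0), 1)
  expect_equal(sum(g$density) * g$spacing^3, 1)  # counts / n_frames sums to 1

  pos2 <- pos1 + c(3, 0, 0)
  x2 <- toy_ensemble(rep(list(rbind(pos1), rbind(pos2)), 5), elety = "K",
                     resid = "K")
  g2 <- occupancy_grid(x2, selection = 1, spacing = 1)
  expect_equal(sort(g2$counts[g2$counts > 0]), c(5, 5))

  set.seed(71)
  cloud <- lapply(1:20, function(i) matrix(rnorm(12, sd = 4), 4, 3))
  x3 <- toy_ensemble(cloud, elety = paste0("O", 1:4))
  g3 <- occupancy_grid(x3, selection = 1:4, spacing = 1.5)
  expect_equal(sum(g3$counts) + g3$n_outside, 20 * 4)
  expect_equal(g3$n_outside, 0)   # auto-sized grid covers everything
  expect_error(occupancy_grid(x3, selection = integer(0)), "empty")
})

test_that("occupancy grids write valid OpenDX", {
  x <- toy_ensemble(rep(list(rbind(c(0.5, 0.5, 0.5))), 3), elety = "MG",
                    resid = "MG")
  g <- occupancy_grid(x, selection = 1, spacing = 1)
  f <- tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "gridpositions counts")
  expect_match(lines[2], "^origin")
  items <- as.integer(sub(".*items (\\d+) data.*", "\\1", lines[7]))
  expect_equal(items, prod(dim(g$counts)))
})
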