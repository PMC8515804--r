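# Dihedral extraction and the binned +1-pseudo-count entropy statistic.

test_that("dihedral angle follows the cis/trans conventions", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 0, tolerance = 1e-9)
  # trans maps onto -180, the low end of the principal range
  expect_equal(dihedral_angle(p1, p2, p3, c(2, -1, 0)), -180,
               tolerance = 1e-9)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 0, 0)), "collinear")
})

test_that("random tetrads match the plane-normal oracle", {
  set.seed(81)
  n_ok <- 0
  while (n_ok < 120) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 2))
    val <- tryCatch(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
                    error = function(e) NULL)
    if (is.null(val)) next
    n_ok <- n_ok + 1
    expect_equal(val, oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-7)
    expect_gte(val, -180)
    expect_lt(val, 180)
  }
})

test_that("backbone dihedrals extract all seven angles on interior residues", {
  s <- read_structure(hairpin_path("GAAA"))
  tors <- backbone_dihedrals(s, "A", 4)
  expect_setequal(names(tors), c("alpha", "beta", "gamma", "delta",
                                 "epsilon", "zeta", "chi"))
  for (t in tors) {
    expect_true(all(t$values >= -180 & t$values < 180))
    expect_length(t$values, s$n_frames)
  }
  # the 5'-terminal residue has no phosphate: alpha/beta are omitted with a
  # warning, the rest still come out
  expect_warning(t1 <- backbone_dihedrals(s, "A", 1), "omitted")
  expect_false("alpha" %in% names(t1))
  expect_true("chi" %in% names(t1))
})

test_that("uniform bin counts give exactly log(36)", {
  vals <- rep(seq(-175, 175, by = 10), each = 100)   # 100 per bin, n = 3600
  h <- binned_entropy(vals)
  expect_equal(as.numeric(h), log(36), tolerance = 1e-12)
  # in bits when asked
  h2 <- binned_entropy(vals, log_base = 2)
  expect_equal(as.numeric(h2), log2(36), tolerance = 1e-12)
  # signed convention is the negation
  expect_equal(as.numeric(binned_entropy(vals, signed = TRUE)), -log(36),
               tolerance = 1e-12)
})

test_that("a single occupied bin at n = 36 matches the closed form", {
  # p_hot = 37/72, 35 bins at 1/72 under the +1 pseudo-count rule
  closed <- -(37 / 72 * log(37 / 72) + 35 * (1 / 72) * log(1 / 72))
  h <- binned_entropy(rep(3, 36))
  expect_equal(as.numeric(h), closed, tolerance = 1e-12)
  expect_equal(as.numeric(h), 2.421056, tolerance = 1e-6)
  expect_equal(as.numeric(h), oracle_entropy(rep(3, 36)), tolerance = 1e-12)
})

test_that("entropy agrees with the independent binning oracle on random data", {
  set.seed(91)
  for (i in 1:50) {
    v <- runif(sample(10:500, 1), -180, 180)
    expect_equal(as.numeric(binned_entropy(v)), oracle_entropy(v),
                 tolerance = 1e-12)
  }
})

test_that("concentrating mass into fewer bins never increases H", {
  # all two-bin allocations of n = 10 observations
  for (k in 0:10) {
    h_split <- binned_entropy(c(rep(-175, k), rep(5, 10 - k)))
    h_onebin <- binned_entropy(rep(5, 10))
    expect_gte(as.numeric(h_split) + 1e-12, as.numeric(h_onebin))
  }
})

test_that("H is invariant under exact 10-degree cyclic shifts", {
  set.seed(92)
  v <- runif(400, -180, 180)
  h0 <- as.numeric(binned_entropy(v))
  for (shift in c(10, 50, 120, 350)) {
    vs <- ((v + shift + 180) %% 360) - 180
    expect_equal(as.numeric(binned_entropy(vs)), h0, tolerance = 1e-12)
  }
})

test_that("H bounds, degenerate inputs and bin-width validation", {
  expect_error(binned_entropy(numeric(0)), "empty")
  expect_error(binned_entropy(runif(10), bin_width = 7), "divide 360")
  set.seed(93)
  for (i in 1:20) {
    h <- as.numeric(binned_entropy(runif(sample(1:100, 1), -180, 180)))
    expect_gte(h, 0)
    expect_lte(h, log(36) + 1e-12)
  }
})

test_that("pseudo-count bias vanishes on large uniform samples", {
  s <- sample_dihedrals(1e5, "uniform", seed = 5)
  expect_lt(abs(as.numeric(binned_entropy(s)) - log(36)), 0.01)
})

test_that("H decreases monotonically with von Mises concentration", {
  kappas <- c(0.2, 1, 5, 25, 100)
  h_mean <- vapply(kappas, function(k) {
    mean(vapply(1:8, function(seed) {
      as.numeric(binned_entropy(sample_dihedrals(2000, "von_mises", mu = 0,
                                                 kappa = k, seed = seed)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(h_mean) < 0))
})

test_that("entropy deltas compare reports keywise", {
  s <- read_structure(hairpin_path("GAAA"))
  x <- anionpi:::as_nucleic_structure(s$atoms, rbind(s$xyz, s$xyz, s$xyz))
  res <- data.frame(chain = "A", resno = 4:5)
  rep_a <- entropy_report(x, res)
  expect_true(all(c("chain", "resno", "angle", "n", "H") %in% names(rep_a)))
  d0 <- entropy_delta(rep_a, rep_a)
  expect_equal(d0$delta, rep(0, nrow(d0)))

  # uniform vs single-bin samples: delta equals the two closed forms
  mk <- function(vals) data.frame(chain = "A", resno = 1, angle = "chi",
                                  n = length(vals),
                                  H = as.numeric(binned_entropy(vals)))
  uni <- mk(rep(seq(-175, 175, 10), each = 1))   # 36 obs, uniform
  one <- mk(rep(0, 36))
  d <- entropy_delta(one, uni)
  expect_equal(d$delta, log(36) - 2.421056, tolerance = 1e-6)
  expect_error(entropy_delta(rep_a,
                             data.frame(chain = "Z", resno = 1, angle = "chi",
                                        n = 1, H = 0)),
               "no shared")
})

test_that("wide von Mises samples carry more entropy than narrow ones", {
  pos <- vapply(1:20, function(seed) {
    wide <- sample_dihedrals(1e4, "von_mises", mu = 30, kappa = 0.5,
                             seed = seed)
    narrow <- sample_dihedrals(1e4, "von_mises", mu = 30, kappa = 50,
                               seed = seed + 1000)
    as.numeric(binned_entropy(wide)) > as.numeric(binned_entropy(narrow))
  }, logical(1))
  expect_true(all(pos))
})
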