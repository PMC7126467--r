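test_that("topology invariants hold over a parameter sweep", {
  set.seed(51)
  for (k in 1:300) {
    topo <- sample_topology(simulation_params(
      length_range = c(40L, 90L), n_strand_range = c(2L, 5L)))
    s <- topo$strands
    expect_true(all(s[, "length"] >= 3 & s[, "length"] <= 10))
    ends <- s[, "start"] + s[, "length"] - 1L
    expect_true(all(s[, "start"] >= 0) && all(ends < topo$length))
    ord <- order(s[, "start"])
    if (nrow(s) > 1) {
      expect_true(all(s[ord[-1], "start"] - ends[ord[-nrow(s)]] - 1L >= 2))
    }
    deg <- table(c(topo$pairings$a, topo$pairings$b))
    expect_true(all(deg <= 2))
  }
})

test_that("degenerate and infeasible topology settings behave", {
  set.seed(52)
  topo <- sample_topology(simulation_params(length_range = c(30L, 30L),
                                            n_strand_range = c(0L, 0L)))
  expect_identical(nrow(topo$strands), 0L)
  expect_identical(nrow(topo$pairings), 0L)
  expect_identical(nrow(topology_to_labels(topo)$pairs), 0L)
  expect_error(sample_topology(simulation_params(
    length_range = c(12L, 12L), n_strand_range = c(6L, 6L))),
    "feasible")
})

test_that("topology sampling is deterministic under a fixed seed", {
  p <- simulation_params()
  set.seed(53); a <- sample_topology(p)
  set.seed(53); b <- sample_topology(p)
  expect_identical(a, b)
})

test_that("labels follow the stated pairing geometry", {
  # antiparallel hairpin: strand A at residues 2-5, strand B at 8-11,
  # full register -> pairs {(2,11), (3,10), (4,9), (5,8)}
  topo <- sheet_topology(14, rbind(c(2, 4), c(8, 4)),
                         data.frame(a = 1, b = 2,
                                    orientation = "antiparallel",
                                    register = 3))
  pl <- topology_to_labels(topo)
  expect_identical(unname(pl$pairs),
                   rbind(c(2L, 11L), c(3L, 10L), c(4L, 9L), c(5L, 8L)))
  # parallel pairing with aligned segments at 0 and 20, overlap 3
  # register is in strand-local coordinates (B pos = A pos + r), so
  # r = 0 aligns the two segment starts at residues 0 and 20
  topo2 <- sheet_topology(30, rbind(c(0, 3), c(20, 3)),
                          data.frame(a = 1, b = 2,
                                     orientation = "parallel",
                                     register = 0))
  expect_identical(unname(topology_to_labels(topo2)$pairs),
                   rbind(c(0L, 20L), c(1L, 21L), c(2L, 22L)))
})

test_that("sheet_topology enforces its invariants", {
  expect_error(sheet_topology(20, rbind(c(0, 2)), NULL), "\\[3, 10\\]")
  expect_error(sheet_topology(20, rbind(c(0, 4), c(5, 4)), NULL),
               "loop residues")
  expect_error(sheet_topology(10, rbind(c(5, 8)), NULL), "outside")
  s <- rbind(c(0, 4), c(6, 4), c(12, 4))
  expect_error(sheet_topology(20, s,
                              data.frame(a = 1, b = 1,
                                         orientation = "parallel",
                                         register = 0)),
               "itself")
})

test_that("noiseless contact maps exactly invert to the labels", {
  for (seed in 1:20) {
    set.seed(seed)
    topo <- sample_topology(noiseless_params(50L))
    labels <- topology_to_labels(topo)
    set.seed(seed + 1000)
    cm <- simulate_contact_map(labels, topo$length, noiseless_params(50L))
    got <- which(cm$values >= 0.5 & upper.tri(cm$values) &
                   separation_mask(topo$length), arr.ind = TRUE) - 1L
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_identical(unname(got), unname(labels$pairs))
  }
})

test_that("false-positive density matches its binomial expectation", {
  # no labels: every off-band upper-triangle zero cell is a candidate
  L <- 100L
  labels <- pairing_labels(L, NULL)
  p <- simulation_params(length_range = c(L, L), fp_density = 0.02,
                         miss_rate = 0, blur_sigma = 0)
  n_cand <- sum(upper.tri(matrix(0, L, L)) & separation_mask(L))
  set.seed(54)
  counts <- replicate(20, {
    cm <- simulate_contact_map(labels, L, p)
    sum(cm$values[upper.tri(cm$values)] > 0 & separation_mask(L)[
      upper.tri(cm$values)])
  })
  expected <- 0.02 * n_cand
  sigma <- sqrt(20 * 0.02 * 0.98 * n_cand) / 20
  expect_lt(abs(mean(counts) - expected), 3 * sigma * sqrt(20))
  # planted values lie in [0.3, 1]
  cm <- simulate_contact_map(labels, L, p)
  vals <- cm$values[separation_mask(L) & cm$values > 0]
  expect_true(all(vals >= 0.3 & vals <= 1))
  expect_true(isSymmetric(cm$values))
})

test_that("profile flips and jitter behave as documented", {
  set.seed(55)
  topo <- sample_topology(simulation_params(length_range = c(80L, 80L)))
  # jitter off, no errors: argmax is strand exactly on strand residues
  p0 <- simulation_params(length_range = c(80L, 80L), ss_error_rate = 0)
  prof <- simulate_profile(topo, p0, jitter = FALSE)
  in_strand <- rep(FALSE, 80)
  for (s in seq_len(nrow(topo$strands))) {
    in_strand[topo$strands[s, 1] + seq_len(topo$strands[s, 2])] <- TRUE
  }
  argmax <- apply(prof$ss3, 1, which.max)
  expect_identical(argmax == 2, in_strand)
  expect_equal(rowSums(prof$ss3), rep(1, 80), tolerance = 1e-9)
  # flip frequency over many residues within 3 sigma of ss_error_rate
  pf <- simulation_params(length_range = c(80L, 80L), ss_error_rate = 0.15)
  set.seed(56)
  n_flip <- sum(replicate(150, {
    pr <- simulate_profile(topo, pf, jitter = FALSE)
    sum((apply(pr$ss3, 1, which.max) == 2) != in_strand)
  }))
  n_tot <- 150 * 80
  expect_lt(abs(n_flip / n_tot - 0.15), 3 * sqrt(0.15 * 0.85 / n_tot))
  # jittered rows still sum to one
  prj <- simulate_profile(topo, pf, jitter = TRUE)
  expect_equal(rowSums(prj$ss3), rep(1, 80), tolerance = 1e-9)
  expect_true(prj$n_homologs >= 10 && prj$n_homologs <= 10000)
})

test_that("generate_dataset is complete, deterministic and in range", {
  ds <- generate_dataset(3, simulation_params(), seed = 57)
  expect_identical(length(ds), 3L)
  expect_identical(ds[[1]]$id, "synthetic_0001")
  for (pr in ds) {
    expect_s3_class(pr$map_a, "contact_map")
    expect_s3_class(pr$map_b, "contact_map")
    expect_s3_class(pr$ridge_a, "ridge_map")
    expect_s3_class(pr$profile, "sequence_profile")
    expect_s3_class(pr$labels, "pairing_labels")
    expect_true(pr$labels$length >= 50 && pr$labels$length <= 120)
    # the two maps are independently corrupted, not copies
    expect_false(identical(pr$map_a$values, pr$map_b$values))
  }
  ds2 <- generate_dataset(3, simulation_params(), seed = 57)
  expect_identical(ds, ds2)
  expect_error(generate_dataset(0), "positive")
  # positive fraction among valid pairs is sane over seeds
  fracs <- vapply(1:5, function(s) {
    d <- generate_dataset(2, simulation_params(), seed = s)
    mean(vapply(d, function(pr) {
      L <- pr$labels$length
      nrow(pr$labels$pairs) / (sum(separation_mask(L)) / 2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(fracs > 0.001 & fracs < 0.2))
})
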