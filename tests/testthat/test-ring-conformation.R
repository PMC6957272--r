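test_that("generated rings return their requested diagonals exactly", {
  for (pair in list(c(30, 30), c(40.7, 30.7), c(52, 22), c(34, 30))) {
    m <- compute_l1_l2(build_ring(simulate_ring(pair[1], pair[2])))
    expect_equal(m$L1, pair[1], tolerance = 1e-9)
    expect_equal(m$L2, pair[2], tolerance = 1e-9)
    expect_equal(m$asymmetry, pair[1] - pair[2], tolerance = 1e-9)
  }
})

test_that("diagonal metrics are invariant under rigid motion of the ring", {
  set.seed(11)
  atoms <- simulate_ring(40.7, 30.7)
  m0 <- compute_l1_l2(build_ring(atoms))
  for (i in 1:5) {
    moved <- transform_atoms(atoms, random_rotation(), rnorm(3, 0, 50))
    m1 <- compute_l1_l2(build_ring(moved))
    expect_equal(m1$L1, m0$L1, tolerance = 1e-9)
    expect_equal(m1$L2, m0$L2, tolerance = 1e-9)
  }
})

test_that("near-equal diagonals collapse to a single four-fold value", {
  # construction guarantees exact equality; asymmetry must be exactly 0
  m <- compute_l1_l2(build_ring(simulate_ring(30, 30)))
  expect_identical(m$L1, m$L2)
  expect_equal(m$asymmetry, 0)
})

test_that("intra-dimer distances honour construction and match enumeration", {
  r_even <- build_ring(simulate_ring(30, 30, dimer_d36 = rep(10, 4)))
  expect_equal(intra_dimer_distances(r_even), rep(10, 4), tolerance = 1e-9)

  r_alt <- build_ring(simulate_ring(40.7, 30.7, dimer_d36 = c(8, 14, 8, 14)))
  expect_equal(intra_dimer_distances(r_alt), c(8, 14, 8, 14), tolerance = 1e-9)

  # enumeration oracle over the declared dimer pairing
  set.seed(5)
  ring <- build_ring(simulate_ring(37, 28, dimer_d36 = runif(4, 7, 15)))
  got <- intra_dimer_distances(ring)
  m <- marker_coords(ring, 36)
  oracle <- sapply(0:3, function(k) {
    sqrt(sum((m[2 * k + 1, ] - m[2 * k + 2, ])^2))
  })
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("square classification is thresholded, symmetric and validated", {
  calls <- classify_conformation(
    tibble::tibble(L1 = c(30.0, 40.7, 25, 30.7), L2 = c(30.0, 30.7, 25, 40.7)))
  expect_equal(calls$label, c("square", "non-square", "square", "non-square"))
  expect_error(classify_conformation(tibble::tibble(L1 = 1, L2 = 1),
                                     threshold = -1),
               class = "rck_usage_error")
  expect_error(classify_conformation(tibble::tibble(a = 1)),
               class = "rck_usage_error")
})

test_that("conformation clustering is deterministic and monotone in cutoff", {
  one <- cluster_conformations(tibble::tibble(name = "x", L1 = 30, L2 = 30))
  expect_equal(one$group, 1L)

  dup <- cluster_conformations(tibble::tibble(
    name = c("a", "b", "c"), L1 = c(52, 52, 30), L2 = c(22, 22, 30)))
  expect_equal(dup$group[1], dup$group[2])
  expect_false(dup$group[1] == dup$group[3])

  items <- published_nonsquare_pairs()
  n_groups <- sapply(c(0.5, 2, 3.7, 3.8, 5, 10, 40), function(h) {
    max(cluster_conformations(items, cutoff = h)$group)
  })
  expect_true(all(diff(n_groups) <= 0))
  # label assignment ignores row order
  perm <- items[c(5, 1, 9, 3, 10, 2, 8, 4, 6, 7), ]
  g1 <- cluster_conformations(items)
  g2 <- cluster_conformations(perm)
  key1 <- split(g1$name, g1$group)
  key2 <- split(g2$name, g2$group)
  expect_setequal(
    unname(sapply(key1, function(v) paste(sort(v), collapse = ","))),
    unname(sapply(key2, function(v) paste(sort(v), collapse = ","))))
})

test_that("Kabsch superposition has rigid invariances and symmetry", {
  set.seed(3)
  A <- matrix(rnorm(150, sd = 10), ncol = 3)
  expect_equal(superpose_rmsd(A, A), 0, tolerance = 1e-9)
  moved <- A %*% t(random_rotation()) +
    matrix(rnorm(3, 0, 20), nrow(A), 3, byrow = TRUE)
  expect_lt(superpose_rmsd(A, moved), 1e-6)
  B <- A + matrix(rnorm(150, sd = 1), ncol = 3)
  expect_equal(superpose_rmsd(A, B), superpose_rmsd(B, A), tolerance = 1e-9)
  expect_error(superpose_rmsd(A, B[1:10, ]), class = "rck_usage_error")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose_rmsd(line, line + 1), class = "rck_numerical_error")
})

test_that("Kabsch RMSD agrees with bio3d and a rotation-search oracle", {
  set.seed(8)
  for (i in 1:5) {
    A <- matrix(rnorm(60, sd = 5), ncol = 3)
    B <- A %*% t(random_rotation()) + matrix(rnorm(60, sd = 0.7), ncol = 3)
    ours <- superpose_rmsd(A, B)
    # independent library route
    fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
    ref <- bio3d::rmsd(as.numeric(t(B)), fit)   # bio3d rounds to 3 decimals
    expect_lt(abs(ours - ref), 1.1e-3)
    # brute-force rotation search
    expect_equal(ours, oracle_superpose_rmsd(A, B, n_grid = 500),
                 tolerance = 1e-3)
  }
})

test_that("whole-ring C-alpha RMSD drops unmodelled residues pairwise", {
  set.seed(9)
  a1 <- simulate_ring(30, 30)
  a2 <- a1
  xyz <- as.matrix(a2[, c("x", "y", "z")]) + matrix(rnorm(nrow(a2) * 3, 0, 0.3),
                                                    ncol = 3)
  a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
  full <- ring_ca_rmsd(build_ring(a1), build_ring(a2))
  expect_equal(full$n_atoms, 40L)
  expect_gt(full$rmsd, 0)
  # drop residue 34 of one chain in one ring: pairwise exclusion
  a2_gap <- a2[!(a2$chain == "C" & a2$resno == 34), ]
  gap <- ring_ca_rmsd(build_ring(a1), build_ring(a2_gap))
  expect_equal(gap$n_atoms, 39L)
})

test_that("hinge angle follows its documented convention", {
  ring <- build_ring(simulate_ring(30, 30, dimer_d36 = rep(8, 4)))
  got <- hinge_angle(ring, dimer = c(1, 2))
  # independent arccos evaluation from raw coordinates
  m36 <- marker_coords(ring, 36)
  vertex <- (m36[1, ] + m36[2, ]) / 2
  cent <- function(i) {
    sub <- ring$atoms[ring$atoms$chain == ring$subunits[i], ]
    c(mean(sub$x), mean(sub$y), mean(sub$z))
  }
  v1 <- cent(1) - vertex; v2 <- cent(2) - vertex
  expected <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(got, expected, tolerance = 1e-9)
  expect_gte(got, 0); expect_lte(got, 180)
})

test_that("collinear hinge markers give a straight angle", {
  # two single-residue stubs placed so both centroids and the vertex align
  mk_chain <- function(ch, xs) {
    tibble::tibble(type = "ATOM", elety = "CA", alt = "", resid = "ALA",
                   chain = ch, resno = c(34L, 35L, 36L, 37L, 38L), insert = "",
                   x = xs, y = 0, z = 0, o = 1, b = 30, elesy = "C")
  }
  ring <- build_ring(simulate_ring(30, 30))
  # overwrite dimer subunits 1-2 with collinear coordinates
  atoms <- ring$atoms
  s1 <- ring$subunits[1]; s2 <- ring$subunits[2]
  atoms[atoms$chain == s1, c("x", "y", "z")] <-
    mk_chain(s1, seq(-10, -6))[, c("x", "y", "z")]
  atoms[atoms$chain == s2, c("x", "y", "z")] <-
    mk_chain(s2, seq(6, 10))[, c("x", "y", "z")]
  ring$atoms <- atoms
  expect_equal(hinge_angle(ring, dimer = c(1, 2)), 180, tolerance = 1e-6)
})
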