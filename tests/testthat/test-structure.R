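test_that("PDB reading and writing preserve structure content", {
  s <- read_pdb(tiny_pdb())
  expect_equal(nrow(s$residues), 3L)
  expect_equal(sum(!is.na(s$residues$ca)), 3L)
  expect_equal(nrow(s$atoms), 5L)

  # multi-model file honoured
  two <- make_two_domain_structure(seed = 5)
  ens <- make_ensemble(two, 0.3, n_frames = 2, seed = 6)
  f <- tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  models <- read_pdb(f, model = "all")
  expect_length(models, 2L)
  expect_equal(nrow(models[[1]]$residues), nrow(models[[2]]$residues))

  # round-trip within PDB format precision (3 decimals)
  g <- tempfile(fileext = ".pdb")
  write_pdb(two, g)
  back <- read_pdb(g)
  expect_equal(calpha_coords(back), calpha_coords(two), tolerance = 1e-3)

  expect_error(read_pdb(tempfile()), "cannot parse|No such|exist")
})

test_that("Kirchhoff matrices satisfy closed forms and graph-Laplacian identities", {
  pair <- chain_structure(2, spacing = 5)
  enm2 <- build_gnm(pair, cutoff = 10)
  expect_equal(unname(enm2$kirchhoff), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
  expect_equal(enm2$eigenvalues, c(0, 2), tolerance = 1e-9)

  # path-graph closed form: eigenvalues 4 sin^2(pi k / 2n)
  n <- 50
  chain <- chain_structure(n, spacing = 3.8)
  enm <- build_gnm(chain, cutoff = 5)   # only adjacent beads within cutoff
  want <- sort(4 * sin(pi * (seq_len(n) - 1) / (2 * n))^2)
  expect_equal(enm$eigenvalues, want, tolerance = 1e-8)

  # properties on random structures: symmetric, row sums 0, eigenvalues >= 0
  for (seed in 1:5) {
    set.seed(seed)
    s <- coords_structure(matrix(runif(3 * 40, 0, 30), ncol = 3))
    e <- suppressWarnings(build_gnm(s, cutoff = 10))
    expect_equal(max(abs(e$kirchhoff - t(e$kirchhoff))), 0)
    expect_lt(max(abs(rowSums(e$kirchhoff))), 1e-9)
    expect_gt(min(e$eigenvalues), -1e-9)
    expect_lt(max(abs(crossprod(e$eigenvectors) - diag(nrow(e$kirchhoff)))), 1e-6)
  }
})

test_that("zero-mode count equals the number of connected components", {
  # two clusters far beyond the cutoff: 2 components
  m <- rbind(cbind(runif(10, 0, 5), runif(10, 0, 5), runif(10, 0, 5)),
             cbind(runif(10, 100, 105), runif(10, 0, 5), runif(10, 0, 5)))
  s <- coords_structure(m)
  expect_warning(e <- build_gnm(s, cutoff = 10), "disconnected")
  # graph-traversal oracle on the same contact graph
  adj <- as.matrix(dist(m)) <= 10
  seen <- rep(FALSE, nrow(m)); comps <- 0
  for (i in seq_len(nrow(m))) {
    if (seen[i]) next
    comps <- comps + 1
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] & !seen))
    }
  }
  expect_equal(e$n_zero_modes, comps)
})

test_that("slow modes carry the expected shape and hinge calls sit at sign changes", {
  pair <- chain_structure(2, spacing = 5)
  m1 <- gnm_mode(build_gnm(pair, cutoff = 10), 1)
  expect_equal(unname(m1), c(1, -1) / sqrt(2), tolerance = 1e-9)

  chain <- chain_structure(30)
  enm <- build_gnm(chain, cutoff = 5)
  v1 <- gnm_mode(enm, 1); v2 <- gnm_mode(enm, 2)
  expect_lt(abs(sum(v1 * v2)), 1e-6)
  flips <- which(diff(sign(v1)) != 0)
  expect_length(flips, 1L)
  expect_lt(abs(flips - 15), 3)  # single crossing near the chain midpoint
  expect_error(gnm_mode(enm, 40), "mode index")

  h <- find_hinges(c(1, 1, -1, -1), tolerance = 0)
  expect_equal(h$resno, 3L)
  expect_equal(nrow(find_hinges(c(1, 2, 1, 2), tolerance = 0)), 0L)
})

test_that("Shrake-Rupley areas hit the analytic sphere and are rigid-motion invariant", {
  one <- coords_structure(matrix(c(0, 0, 0), 1))
  a1 <- sasa(one)
  expect_lt(abs(a1$area - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.02)

  # two coincident atoms occlude to a single atom's area
  twin <- protein_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), resid = "GLY", elety = "CA", element = "C",
    x = 0, y = 0, z = 0))
  expect_lt(abs(sum(sasa(twin)$area) - a1$area) / a1$area, 0.02)

  # rotation + translation invariance
  s <- make_two_domain_structure(n_per_domain = 12, seed = 2)
  base <- sum(sasa(s, n_sphere_points = 240)$area)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  at <- s$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R + 11.5
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  moved <- sum(sasa(protein_structure(at), n_sphere_points = 240)$area)
  expect_lt(abs(moved - base) / base, 1e-6)

  # buried rule and unknown elements
  expect_false(a1$buried)
  unk <- coords_structure(matrix(0, 1, 3), element = "ZZ")
  expect_error(sasa(unk), "ZZ")
})

test_that("interface and distance-to-set calculations equal brute-force oracles", {
  a <- coords_structure(matrix(c(0, 0, 0), 1))
  b_in <- coords_structure(matrix(c(9.9, 0, 0), 1))
  b_out <- coords_structure(matrix(c(10.1, 0, 0), 1))
  expect_equal(nrow(interface_residues(a, b_in)), 1L)
  expect_equal(nrow(interface_residues(a, b_out)), 0L)

  s <- make_two_domain_structure(n_per_domain = 20, seed = 3)
  expect_equal(nrow(interface_residues(s, s)), nrow(s$residues))

  set.seed(12)
  A <- coords_structure(matrix(runif(3 * 200, 0, 60), ncol = 3))
  B <- coords_structure(matrix(runif(3 * 200, 30, 90), ncol = 3))
  got <- interface_residues(A, B, cutoff = 10)
  ca <- as.matrix(A$atoms[, c("x", "y", "z")])
  cb <- as.matrix(B$atoms[, c("x", "y", "z")])
  mind <- sapply(seq_len(nrow(ca)), function(i) {
    sqrt(min(colSums((t(cb) - ca[i, ])^2)))
  })
  expect_equal(got$resno, which(mind <= 10))
  expect_equal(got$min_distance, mind[mind <= 10])

  d <- distance_to_residue_set(A, c(5L, 50L))
  want <- sapply(seq_len(nrow(ca)), function(i) {
    sqrt(min(sum((ca[i, ] - ca[5, ])^2), sum((ca[i, ] - ca[50, ])^2)))
  })
  expect_equal(d$distance, want)
  expect_equal(d$distance[c(5, 50)], c(0, 0))
  expect_error(distance_to_residue_set(A, 999L), "not in structure")
})
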