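# Residue graph construction: PDB parsing, side-chain-centroid
# pseudo-positions, cutoff adjacency, and the two spatial edge features.

test_that("parse_structure reads residues in order, dedups altlocs, drops H", {
  pdb <- write_fixture_pdb()
  st <- parse_structure(pdb, "A")
  expect_s3_class(st, "protein_structure")
  expect_equal(nrow(st$residues), 3L)
  expect_equal(st$residues$res_name, c("ALA", "GLY", "SER"))
  expect_equal(st$residues$resno, 1:3)

  # altloc: exactly one CB survives for residue 1, the higher-occupancy A copy
  cb <- st$atoms[st$atoms$res_index == 1 & st$atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 2.000)

  # hydrogen removal against a line-counting oracle over ATOM records:
  # non-H ATOM lines, minus the one duplicated altloc copy
  lines <- readLines(pdb)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  n_heavy <- sum(substr(atom_lines, 77, 78) != " H")
  expect_equal(nrow(st$atoms), n_heavy - 1L)
  expect_false(any(grepl("^H", st$atoms$atom)))
})

test_that("parse_structure reports missing chains and unreadable files", {
  pdb <- write_fixture_pdb()
  expect_error(parse_structure(pdb, "B"), "chain not found")
  expect_error(parse_structure(tempfile(), "A"), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(parse_structure(bad, "A"))
})

test_that("pseudo-positions average side-chain atoms with C-alpha fallback", {
  pdb <- write_fixture_pdb()
  st <- parse_structure(pdb, "A")
  pp <- pseudo_positions(st)
  # ALA: single surviving CB
  expect_equal(pp[1, ], c(2.0, 1.0, 1.5))
  # GLY: no side chain -> CA
  expect_equal(pp[2, ], c(4.2, 2.6, -0.8))
  # SER: mean of CB and OG
  expect_equal(pp[3, ], c((8.0 + 9.3) / 2, (1.6 + 1.2) / 2, (-2.9 - 3.1) / 2))

  # brute-force oracle on a synthetic chain
  st2 <- synth_structure(5, seed = 3)
  pp2 <- pseudo_positions(st2)
  for (i in 1:5) {
    a <- st2$atoms[st2$atoms$res_index == i, ]
    sc <- a[a$is_sidechain, ]
    ref <- if (nrow(sc) > 0) colMeans(sc[, c("x", "y", "z")]) else
      unlist(a[a$atom == "CA", c("x", "y", "z")])
    expect_equal(unname(pp2[i, ]), unname(as.numeric(ref)))
  }
})

test_that("mean of a two-point side chain is the midpoint; no atoms errors", {
  st <- structure(list(
    id = "toy_A", chain_id = "A",
    residues = tibble::tibble(seq_index = 1L, resno = 1L, res_name = "SER"),
    atoms = tibble::tibble(res_index = c(1L, 1L, 1L),
                           atom = c("CA", "CB", "OG"),
                           element = c("C", "C", "O"),
                           x = c(9, 0, 2), y = c(9, 0, 0), z = c(9, 0, 0),
                           b_factor = 10, is_sidechain = c(FALSE, TRUE, TRUE))),
    class = "protein_structure")
  expect_equal(unname(pseudo_positions(st)[1, ]), c(1, 0, 0))
  st$atoms <- st$atoms[0, ]
  expect_error(pseudo_positions(st), "no atoms")
})

test_that("center_coordinates has zero column means", {
  expect_equal(center_coordinates(rbind(c(1, 0, 0), c(-1, 0, 0))),
               rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(center_coordinates(matrix(c(5, 5, 5), 1)), matrix(0, 1, 3))
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rnorm(30, sd = 10), 10, 3)
    expect_lt(sqrt(sum(colMeans(center_coordinates(x))^2)), 1e-9)
  }
})

test_that("adjacency at the cutoff matches the all-pairs oracle", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  e <- build_adjacency(two, 14)
  expect_true(any(e[, 1] == 1 & e[, 2] == 2))
  two_far <- rbind(c(0, 0, 0), c(15, 0, 0))
  e2 <- build_adjacency(two_far, 14)
  expect_false(any(e2[, 1] != e2[, 2]))  # only self-loops remain
  expect_true(all(e2[, 1] == e2[, 2]))   # and they are present

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:50, 1)
    x <- matrix(rnorm(3 * n, sd = 8), n, 3)
    e <- build_adjacency(x, 14)
    # O(N^2) brute force, self-loops included
    oracle <- do.call(rbind, lapply(seq_len(n), function(i) {
      js <- which(sqrt(colSums((t(x) - x[i, ])^2)) <= 14)
      cbind(i, js)
    }))
    expect_equal(nrow(e), nrow(oracle))
    expect_setequal(paste(e[, 1], e[, 2]), paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("edge features: normalised distance and centroid-angle cosine", {
  coords <- rbind(c(-5, 0, 0), c(5, 0, 0))
  edges <- build_adjacency(coords, 14)
  ef <- edge_features(coords, edges, 14)
  ij <- which(edges[, 1] == 1 & edges[, 2] == 2)
  expect_equal(unname(ef[ij, ]), c(10 / 14, -1))
  self <- which(edges[, 1] == edges[, 2])
  expect_true(all(abs(ef[self, 1]) < 1e-12))
  expect_true(all(ef[self, 2] == 1))

  # node exactly at the centroid: cosine defined as 0
  coords3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  c3 <- center_coordinates(coords3)
  e3 <- build_adjacency(c3, 14)
  ef3 <- edge_features(c3, e3, 14)
  k <- which(e3[, 1] == 1 & e3[, 2] == 2)
  expect_equal(unname(ef3[k, 2]), 0)

  # brute-force oracle on a random 10-node graph
  set.seed(7)
  x <- center_coordinates(matrix(rnorm(30, sd = 6), 10, 3))
  ed <- build_adjacency(x, 14)
  ef <- edge_features(x, ed, 14)
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1]; j <- ed[k, 2]
    if (i == j) next
    expect_equal(unname(ef[k, 1]), sqrt(sum((x[i, ] - x[j, ])^2)) / 14)
    expect_equal(unname(ef[k, 2]),
                 sum(x[i, ] * x[j, ]) / (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2))))
  }
})

test_that("edge features are symmetric and invariant to rigid motions", {
  set.seed(8)
  x <- matrix(rnorm(36, sd = 6), 12, 3)
  cx <- center_coordinates(x)
  edges <- build_adjacency(cx, 14)
  ef <- edge_features(cx, edges, 14)

  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  for (k in unique(key)) {
    rows <- which(key == k)
    expect_equal(ef[rows[1], ], ef[rows[length(rows)], ])
  }

  t_shift <- matrix(rep(c(100, -50, 3), each = 12), 12, 3)
  ef_t <- edge_features(center_coordinates(x + t_shift),
                        build_adjacency(center_coordinates(x + t_shift), 14), 14)
  expect_lt(max(abs(ef - ef_t)), 1e-9)

  R <- random_rotation()
  xr <- x %*% t(R)
  ef_r <- edge_features(center_coordinates(xr),
                        build_adjacency(center_coordinates(xr), 14), 14)
  expect_lt(max(abs(ef - ef_r)), 1e-6)
})

test_that("protein graphs assemble, validate and serialise to JSON", {
  g <- random_graph(n = 10, seed = 5)
  expect_s3_class(g, "protein_graph")
  expect_equal(ncol(g$node_features), 62L)
  expect_true(all(g$edges[g$edges[, 1] == g$edges[, 2], 1] == seq_len(10)))
  expect_error(build_protein_graph(synth_structure(5, seed = 1),
                                   matrix(0, 4, 62)), "residue count")
  path <- tempfile(fileext = ".json")
  write_graph_json(g, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_nodes, 10L)
  expect_equal(parsed$n_edges, nrow(g$edges))
  expect_equal(length(parsed$node_features), 10L)
})
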