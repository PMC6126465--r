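test_that("face diagonals match hand computation and scale homogeneously", {
  expect_equal(unname(face_diagonals(unit_cell(100, 100, 100, 90, 90, 90))),
               rep(sqrt(2) * 100, 3), tolerance = 1e-9)
  d <- face_diagonals(unit_cell(102, 100, 100, 90, 90, 90))
  expect_equal(unname(d[c("ab", "ac")]), rep(sqrt(102^2 + 100^2), 2),
               tolerance = 1e-9)
  expect_equal(unname(d["bc"]), sqrt(2) * 100, tolerance = 1e-9)
  base <- face_diagonals(unit_cell(31, 47, 63, 80, 95, 110))
  scaled <- face_diagonals(unit_cell(31 * 1.7, 47 * 1.7, 63 * 1.7, 80, 95, 110))
  expect_equal(unname(scaled), unname(base) * 1.7, tolerance = 1e-9)
  # the longer diagonal is returned on oblique faces
  d2 <- face_diagonals(unit_cell(10, 10, 10, 90, 90, 60))
  expect_equal(unname(d2["ab"]), sqrt(100 + 100 + 2 * 100 * cos(pi / 3)),
               tolerance = 1e-9)
})

test_that("cluster metrics match the derived two-cell case and are symmetric", {
  cells <- list(unit_cell(100, 100, 100, 90, 90, 90),
                unit_cell(102, 100, 100, 90, 90, 90))
  m <- cluster_metrics(cells)
  expect_equal(unname(m["alcv"]), sqrt(102^2 + 100^2) - sqrt(2) * 100,
               tolerance = 1e-6)
  expect_equal(unname(m["alcv"]), 1.421, tolerance = 1e-3)
  expect_equal(unname(m["lcv"]), 1.005, tolerance = 1e-3)
  expect_equal(cluster_metrics(rev(cells)), m)
  ident <- replicate(4, unit_cell(50, 60, 70, 90, 90, 90), simplify = FALSE)
  expect_equal(unname(cluster_metrics(ident)), c(0, 0))
  expect_equal(unname(cluster_metrics(ident[1])), c(0, 0))
})

test_that("cluster metrics agree with the brute-force oracle on random sets", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    cells <- replicate(n, unit_cell(runif(1, 20, 120), runif(1, 20, 120),
                                    runif(1, 20, 120), runif(1, 70, 110),
                                    runif(1, 70, 110), runif(1, 70, 110)),
                       simplify = FALSE)
    got <- cluster_metrics(cells)
    want <- oracle_metrics(cells)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("dendrogram has n-1 annotated nodes with monotone heights and LCVs", {
  set.seed(7)
  cells <- replicate(63, unit_cell(40 + rnorm(1, 0, 0.1), 50, 60, 90, 90, 90),
                     simplify = FALSE)
  d <- build_dendrogram(cells)
  expect_equal(nrow(d$nodes), 62)
  expect_equal(d$nodes$node_id, 64:125)
  # ultrametric: children merge no higher than parents
  for (i in seq_len(nrow(d$nodes))) {
    for (ch in c(d$nodes$child1[i], d$nodes$child2[i])) {
      if (ch > d$n_leaves) {
        j <- match(ch, d$nodes$node_id)
        expect_lte(d$nodes$height[j], d$nodes$height[i] + 1e-12)
        expect_lte(d$nodes$lcv[j], d$nodes$lcv[i] + 1e-12)
        expect_lte(d$nodes$alcv[j], d$nodes$alcv[i] + 1e-12)
      }
    }
  }
  # members of each node are the union of its children's members
  for (i in seq_len(nrow(d$nodes))) {
    mem <- unlist(lapply(c(d$nodes$child1[i], d$nodes$child2[i]), function(ch) {
      if (ch <= d$n_leaves) ch else d$nodes$members[[match(ch, d$nodes$node_id)]]
    }))
    expect_setequal(d$nodes$members[[i]], mem)
  }
  # lcv = 0 iff alcv = 0
  expect_equal(d$nodes$lcv == 0, d$nodes$alcv == 0)
})

test_that("a two-dataset tree merges at the standardised Euclidean distance", {
  cells <- list(unit_cell(40, 50, 60, 90, 90, 90),
                unit_cell(42, 50, 61, 90, 90, 90))
  d <- build_dendrogram(cells)
  expect_equal(nrow(d$nodes), 1)
  # after per-component standardisation both differing components contribute
  # |z1 - z2| = 2/sqrt(2) * sqrt(2) ... compute directly:
  M <- rbind(c(40, 50, 60, 90, 90, 90), c(42, 50, 61, 90, 90, 90))
  Z <- apply(M, 2, function(col) if (sd(col) == 0) c(0, 0) else scale(col)[, 1])
  expect_equal(d$nodes$height, sqrt(sum((Z[1, ] - Z[2, ])^2)), tolerance = 1e-9)
})

test_that("clustering separates two planted cell groups exactly", {
  set.seed(11)
  mk <- function(shift) unit_cell(40 + shift + rnorm(1, 0, 0.05),
                                  50 + shift + rnorm(1, 0, 0.05),
                                  60 + shift + rnorm(1, 0, 0.05), 90, 90, 90)
  cells <- c(replicate(6, mk(0), simplify = FALSE),
             replicate(6, mk(2), simplify = FALSE))
  d <- build_dendrogram(cells)
  root <- d$nodes[nrow(d$nodes), ]
  kid_members <- function(ch) {
    if (ch <= d$n_leaves) ch else d$nodes$members[[match(ch, d$nodes$node_id)]]
  }
  split <- lapply(c(root$child1, root$child2), kid_members)
  expect_true(setequal(split[[1]], 1:6) || setequal(split[[1]], 7:12))
  # determinism: identical input gives the identical tree
  d2 <- build_dendrogram(cells)
  expect_identical(d$nodes$node_id, d2$nodes$node_id)
  expect_identical(d$nodes$members, d2$nodes$members)
})

test_that("cut_tree selects by height or aLCV with sane edge cases", {
  set.seed(3)
  cells <- replicate(8, unit_cell(40 + rnorm(1, 0, 0.3), 50, 60, 90, 90, 90),
                     simplify = FALSE)
  d <- build_dendrogram(cells)
  all_nodes <- cut_tree(d, "height", max(d$nodes$height) + 1)
  expect_equal(nrow(all_nodes), 7)
  expect_equal(all_nodes$node_id, sort(all_nodes$node_id))
  expect_equal(nrow(cut_tree(d, "height", min(d$nodes$height) / 2)), 0)
  thr <- stats::median(d$nodes$alcv)
  sel <- cut_tree(d, "alcv", thr)
  expect_true(all(sel$alcv <= thr))
  expect_true(all(d$nodes$alcv[!d$nodes$node_id %in% sel$node_id] > thr))
})

test_that("outlier flagging peels exactly the planted outliers", {
  set.seed(19)
  core <- replicate(20, unit_cell(40 + rnorm(1, 0, 0.05), 50 + rnorm(1, 0, 0.05),
                                  60 + rnorm(1, 0, 0.05), 90, 90, 90),
                    simplify = FALSE)
  rogue <- replicate(4, unit_cell(65 + rnorm(1, 0, 0.05), 75, 85, 90, 90, 90),
                     simplify = FALSE)
  d <- build_dendrogram(c(core, rogue))
  expect_equal(flag_outliers(d), 21:24)
  # one dataset 50 % larger than the rest
  d2 <- build_dendrogram(c(core, list(unit_cell(60, 75, 90, 90, 90, 90))))
  expect_equal(flag_outliers(d2), 21L)
  # already isomorphous: nothing flagged
  expect_length(flag_outliers(build_dendrogram(core)), 0)
})

test_that("CLUSTERS.txt rows re-parse to the node table", {
  set.seed(5)
  cells <- replicate(6, unit_cell(40 + rnorm(1, 0, 0.2), 50, 60, 90, 90, 90),
                     simplify = FALSE)
  d <- build_dendrogram(cells)
  f <- withr::local_tempfile()
  write_clusters_file(d, f)
  back <- isomerge:::read_clusters_file(f)
  expect_equal(nrow(back), nrow(d$nodes))
  expect_equal(back$node_id, d$nodes$node_id)
  expect_equal(back$height, d$nodes$height, tolerance = 1e-3)
  for (i in seq_len(nrow(back))) {
    expect_setequal(back$members[[i]], d$nodes$members[[i]])
  }
  # a two-leaf tree gives exactly one row
  d2 <- build_dendrogram(cells[1:2])
  write_clusters_file(d2, f)
  expect_length(readLines(f), 2)  # header + one node
})
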