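test_that("icosphere counts, unit vertices and Euler characteristic hold for orders 0..4", {
  for (k in 0:4) {
    ico <- get_ico(k)
    V <- nrow(ico$vertices); F_ <- nrow(ico$faces)
    E <- nrow(cortexdiff:::unique_edges(ico$faces))
    expect_identical(V, ico_vertex_count(k))
    expect_identical(F_, ico_face_count(k))
    expect_identical(E, ico_edge_count(k))
    expect_identical(V - E + F_, 2L)
    expect_lt(max(abs(sqrt(rowSums(ico$vertices^2)) - 1)), 1e-12)
    expect_identical(sum(ico$valence == 5L), 12L)
    expect_true(all(ico$valence %in% c(5L, 6L)))
  }
})

test_that("order-6 icosphere has 40962 vertices", {
  expect_identical(ico_vertex_count(6L), 40962L)
  ico6 <- get_ico(6)
  expect_identical(nrow(ico6$vertices), 40962L)
})

test_that("vertex ordering satisfies the prefix property across orders", {
  for (k in 1:4) {
    fine <- get_ico(k)
    coarse <- get_ico(k - 1)
    nvc <- nrow(coarse$vertices)
    expect_equal(fine$vertices[seq_len(nvc), ], coarse$vertices,
                 tolerance = 0)
  }
})

test_that("invalid orders are refused", {
  expect_error(ico_sphere(-1), "non-negative")
  expect_error(ico_sphere(9), "memory guard")
  expect_error(ico_sphere(2.5), "non-negative")
})

test_that("neighbor table matches brute-force face adjacency as a cyclic set", {
  ico <- get_ico(2)
  adj <- face_adjacency(ico$faces, nrow(ico$vertices))
  for (i in seq_len(nrow(ico$vertices))) {
    ring <- ico$neighbor_table[i, seq_len(ico$valence[i])]
    expect_setequal(ring, adj[[i]])
    expect_false(i %in% ring)
    expect_identical(anyDuplicated(ring), 0L)
    # consecutive ring entries must themselves be adjacent (cyclic order)
    for (s in seq_along(ring)) {
      nxt <- ring[if (s == length(ring)) 1 else s + 1]
      expect_true(nxt %in% adj[[ring[s]]])
    }
  }
})

test_that("pentagon padding repeats the center vertex in slot six", {
  ico <- get_ico(2)
  pent <- which(ico$valence == 5L)
  expect_length(pent, 12L)
  expect_identical(ico$neighbor_table[cbind(pent, 6L)], pent)
})

test_that("neighbor relation is symmetric ignoring pad slots", {
  ico <- get_ico(3)
  for (i in seq_len(nrow(ico$vertices))) {
    for (j in ico$neighbor_table[i, seq_len(ico$valence[i])]) {
      expect_true(i %in% ico$neighbor_table[j, seq_len(ico$valence[j])])
    }
  }
})

test_that("pool keeps the order prefix and unpool zero-pads", {
  x <- matrix(rnorm(642 * 3), 642, 3)
  p <- ico_pool(x)
  expect_identical(dim(p), c(162L, 3L))
  expect_equal(p, x[1:162, ], tolerance = 0)
  u <- ico_unpool(p)
  expect_identical(dim(u), c(642L, 3L))
  expect_equal(u[1:162, ], p, tolerance = 0)
  expect_true(all(u[163:642, ] == 0))
  expect_equal(colSums(u), colSums(p))       # padding conserves sums
  expect_equal(ico_pool(ico_unpool(x)), x)   # adjoint pair round-trips
})

test_that("pooling a constant map stays constant and shape errors are caught", {
  expect_equal(unique(as.vector(ico_pool(rep(3.5, 162)))), 3.5)
  expect_error(ico_pool(matrix(0, 100, 1)), "not an icosphere")
  expect_error(ico_pool(matrix(0, 12, 1)), "below order 0")
})

test_that("barycentric resampling is exact on identical meshes and for linear fields", {
  src <- get_ico(3)
  vals <- cbind(rnorm(642), rnorm(642))
  same <- resample_to_icosphere(vals, src$vertices, src$faces, src)
  expect_lt(max(abs(same - vals)), 1e-10)

  # constant map stays constant
  const <- resample_to_icosphere(rep(2, 642), src$vertices, src$faces,
                                 get_ico(4))
  expect_lt(max(abs(const - 2)), 1e-10)

  # linear-in-coordinates field: barycentric beats nearest-neighbor
  a <- c(0.3, -1.2, 0.7)
  f <- src$vertices %*% a
  dst <- get_ico(4)
  truth <- dst$vertices %*% a
  bar <- resample_to_icosphere(f, src$vertices, src$faces, dst)
  nn <- resample_to_icosphere(f, src$vertices, src$faces, dst,
                              method = "nearest")
  expect_lt(max(abs(bar - truth)), max(abs(nn - truth)))
})

test_that("nearest resampling preserves label values exactly", {
  src <- get_ico(2)
  labs <- matrix(as.numeric(sample(0:4, 162, TRUE)))
  out <- resample_to_icosphere(labs, src$vertices, src$faces, get_ico(3),
                               method = "nearest")
  expect_true(all(out %in% labs))
})

test_that("parcellation partitions the sphere into non-empty deterministic ROIs", {
  ico <- get_ico(3)
  p1 <- make_parcellation(ico, 34, seed = 7)
  p2 <- make_parcellation(ico, 34, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_length(p1$labels, 642L)
  counts <- table(factor(p1$labels, levels = 0:33))
  expect_true(all(counts > 0))
  expect_identical(sum(counts), 642L)

  single <- make_parcellation(ico, 1, seed = 1)
  expect_true(all(single$labels == 0L))
  expect_error(make_parcellation(ico, 0), "between 1")
  expect_error(make_parcellation(ico, 10000), "between 1")
})
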