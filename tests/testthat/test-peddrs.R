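test_that("iteration evaluation follows the residual and cosine definitions", {
  A <- diag(2)
  expect_equal(evaluate_l2(A, 1:2, c(0, 1), c(0, 1)), 0)
  expect_equal(evaluate_l2(A, 1:2, c(0, 0), c(3, 4)), 5)
  expect_equal(evaluate_l2(A, 1:2, c(1, 0), c(0, 1)), sqrt(2))
  expect_error(evaluate_l2(A, integer(0), numeric(0), c(1, 1)), "nonempty")

  expect_equal(evaluate_cos(A, 1:2, c(2, 2), c(1, 1)), 1)
  expect_equal(evaluate_cos(A, 1:2, c(1, 0), c(0, 1)), 0)
  expect_equal(evaluate_cos(A, 1:2, c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(evaluate_cos(A, 1:2, c(0, 0), c(1, 0)), 0)
})

test_that("probability weights mix inverse-residual and cosine shares", {
  expect_equal(probability_weights(2, 0.7), 1)
  expect_equal(probability_weights(c(1, 1), c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(probability_weights(c(1, 3), c(0.9, 0.3)), c(0.75, 0.25))
  # all-zero cosines fall back to a uniform cosine share
  expect_equal(probability_weights(c(1, 1), c(0, 0)), c(0.5, 0.5))
  w <- probability_weights(runif(7, 0.1, 5), runif(7))
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
})

test_that("probabilistic distribution clamps and normalizes", {
  expect_equal(probabilistic_distribution(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_equal(probabilistic_distribution(5), 1)
  expect_equal(probabilistic_distribution(c(-1, 2)), c(0, 1))
  expect_null(probabilistic_distribution(c(0, 0)))
})

test_that("ROI centre and covariance match hand evaluations", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(roi_center(coords, c(0.5, 0.5)), c(1, 0, 0))
  expect_equal(roi_center(rbind(c(3, 1, 2)), 1), c(3, 1, 2))
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  expect_equal(roi_center(tri, c(0.25, 0.5, 0.25)), c(0.5, 0.5, 0))

  m <- roi_covariance(coords, c(0.5, 0.5))
  expect_equal(m[1, 1], 2)
  expect_equal(m[-1], rep(0, 8), ignore_attr = TRUE)
  expect_equal(roi_covariance(rbind(c(1, 2, 3)), 1), matrix(0, 3, 3))

  set.seed(8)
  for (i in 1:20) {
    pts <- matrix(rnorm(30), 10, 3)
    p <- runif(10); p <- p / sum(p)
    ev <- eigen(roi_covariance(pts, p), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-12)
  }
})

test_that("ROI box takes the eigenframe with floored half-lengths", {
  box <- roi_box(diag(c(2, 0.5, 1)), c(0, 0, 0), size = 1, floor = 0.1)
  expect_equal(sort(box$half_lengths), c(0.5, 1, 2))
  expect_equal(abs(box$axes), diag(3)[, order(-c(2, 0.5, 1))],
               tolerance = 1e-12, ignore_attr = TRUE)
  box2 <- roi_box(diag(c(2, 0.5, 1)), c(0, 0, 0), size = 2, floor = 0.1)
  expect_equal(box2$half_lengths, 2 * box$half_lengths)
  box0 <- roi_box(matrix(0, 3, 3), c(1, 1, 1), size = 1, floor = 0.75)
  expect_equal(box0$half_lengths, rep(0.75, 3))
  expect_error(roi_box(matrix(1:9, 3), c(0, 0, 0)), "symmetric")
})

test_that("nodes_in_box agrees with a brute-force containment oracle", {
  nodes <- rbind(c(0, 0, 0), c(5, 5, 5))
  box <- roi_box(diag(3) * 0.5, c(0, 0, 0), floor = 0.1)
  expect_equal(nodes_in_box(nodes, box), 1L)

  # a point at 90% of a half-length along a rotated axis is inside
  th <- pi / 7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  boxr <- structure(list(center = c(1, 2, 3), axes = rot,
                         half_lengths = c(2, 1, 1)), class = "roi_box")
  p_in <- c(1, 2, 3) + 0.9 * 2 * rot[, 1]
  expect_equal(nodes_in_box(rbind(p_in), boxr), 1L)

  set.seed(9)
  nodes <- matrix(rnorm(1500, sd = 2), 500, 3)
  for (i in 1:100) {
    box <- roi_box(random_spd3() / 2, rnorm(3), size = sample(c(0.5, 1, 2), 1),
                   floor = 0.3)
    expect_identical(sort(nodes_in_box(nodes, box)),
                     brute_force_in_box(nodes, box))
  }
})

test_that("nodes_in_box sorts by distance with index tie-breaks", {
  nodes <- rbind(c(2, 0, 0), c(1, 0, 0), c(0, 2, 0), c(-1, 0, 0))
  box <- roi_box(matrix(0, 3, 3), c(0, 0, 0), floor = 2.5)
  expect_equal(nodes_in_box(nodes, box), c(2L, 4L, 1L, 3L))
})

test_that("attenuation coefficient follows the schedule closed form", {
  expect_equal(attenuation_coefficient(4), 1)
  expect_equal(attenuation_coefficient(4 * 2^49, l_max = 50), 2)
  expect_equal(attenuation_coefficient(12831), 1.1791, tolerance = 5e-4)
  expect_equal(attenuation_coefficient(2), 1)   # below num_f: no shrink
})

test_that("size update compares ROI supply to the look-ahead budget", {
  beta <- 1.2
  cut <- 100
  expect_equal(update_size(cut / beta^2, cut, beta), 1)   # q = 1 inclusive
  expect_equal(update_size(3 * cut / beta^2, cut, beta), 2)
  expect_equal(update_size(0.4 * cut / beta^2, cut, beta), 0.5)
})

test_that("index refresh concatenates ROI first, dedups, truncates", {
  out <- refresh_index(x = c(6, 5, 4, 3, 2, 1), index_sp = 1:6,
                       index_sp_roi = c(4, 5), cut_num = 6, beta = 2)
  expect_equal(out$cut_num, 3L)
  expect_equal(out$index_sp, c(4L, 5L, 1L))

  out2 <- refresh_index(c(6, 5, 4, 3, 2, 1), 1:6, integer(0), 6, 2)
  expect_equal(out2$index_sp, 1:3)

  out3 <- refresh_index(c(3, 2, 1), 1:3, integer(0), 3, 1)
  expect_equal(out3$cut_num, 3L)
  expect_equal(out3$index_sp, 1:3)
})

test_that("Gaussian filtering retains the one-sigma intersection", {
  expect_equal(gaussian_filter_iterations(c(1, 1, 1), c(0.9, 0.9, 0.9)), 1:3)
  expect_equal(gaussian_filter_iterations(5, 0.5), 1L)

  e <- c(1, 1, 1, 10)
  keep <- gaussian_filter_iterations(e, rep(0.8, 4))
  expect_identical(keep, which(abs(e - mean(e)) <= sd(e)))
  expect_false(4L %in% keep)
})

test_that("fusion is a convex combination concentrating retained mass", {
  recs <- list(
    list(index_sp = c(1L, 3L), x = c(2, 2), e_l2 = 1, e_cos = 0.9),
    list(index_sp = c(2L, 3L), x = c(1, 3), e_l2 = 1, e_cos = 0.9))
  one <- final_distribution(recs, 1L, 4)
  expect_equal(one$x_final, c(0.5, 0, 0.5, 0))
  # equal scores and equal masses -> arithmetic mean of the embeddings
  both <- final_distribution(recs, 1:2, 4)
  expect_equal(both$weights, c(0.5, 0.5))
  expect_equal(both$x_final, c(0.25, 0.125, 0.5 + 0.125, 0) / 1)
  expect_equal(sum(both$x_final), 1)
  expect_true(all(both$x_final >= 0))
})

test_that("noiseless single-node source is recovered exactly with OMP", {
  fix <- small_system()
  sm <- fix$sysmat
  j <- which.min(rowSums(sweep(fix$mesh$nodes[sm$col_nodes, ], 2,
                               c(4, 4, 4))^2))
  B <- as.numeric(sm$A %*% replace(numeric(ncol(sm$A)), j, 1))
  res <- run_peddrs(sm, B, fix$mesh, solver_spec("omp", k = 1))
  reg <- reconstructed_region(res$x_final, fix$mesh)
  node <- sm$col_nodes[j]
  expect_equal(reg$nodes, node)
  expect_equal(location_error(reg$center, fix$mesh$nodes[node, ]), 0)
})

test_that("cut_num trace equals the analytic ceiling schedule", {
  fix <- small_system()
  sm <- fix$sysmat
  set.seed(10)
  x_true <- replace(numeric(ncol(sm$A)), sample(ncol(sm$A), 3), 1)
  B <- simulate_surface_flux(sm, x_true, 0.05, seed = 3)
  res <- run_peddrs(sm, B, fix$mesh, solver_spec("tikhonov"))
  c0 <- ncol(sm$A)
  beta <- attenuation_coefficient(c0)
  sched <- Reduce(function(c, i) ceiling(c / beta), seq_len(49),
                  accumulate = TRUE, init = c0)
  expect_equal(res$audit$cut_num, sched[seq_len(nrow(res$audit))])
  expect_equal(res$beta, beta)
})

test_that("the loop terminates within l_max with valid invariants everywhere", {
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(abs(rnorm(30 * 60)), 30, 60)
    coords <- matrix(runif(180, 0, 10), 60, 3)
    B <- abs(rnorm(30))
    res <- run_peddrs(A, B, solver = solver_spec("tikhonov"),
                      coords = coords, floor = 1, l_max = 20)
    expect_lte(nrow(res$audit), 20)
    expect_true(all(diff(res$audit$cut_num) <= 0))
    expect_equal(sum(res$x_final), 1, tolerance = 1e-12)
    expect_true(all(res$x_final >= 0))
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    # audit weights are the final refresh over all completed iterations
    w <- probability_weights(res$audit$e_l2, res$audit$e_cos)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})
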