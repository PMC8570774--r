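test_that("diffusion coefficient and boundary factor follow their closed forms", {
  expect_equal(diffusion_coefficient(list(mu_a = 0, mu_s_prime = 1 / 3, g = 0.9)), 1)
  muscle <- tissue_optics()["Muscle", ]
  expect_equal(diffusion_coefficient(muscle), 1 / (3 * 0.526), tolerance = 1e-12)
  # doubling mu_a + mu_s' halves D
  expect_equal(diffusion_coefficient(list(mu_a = 0.032, mu_s_prime = 1.020, g = 0.9)),
               diffusion_coefficient(muscle) / 2, tolerance = 1e-12)
  # raw interpretation reduces by (1 - g) first
  expect_equal(diffusion_coefficient(list(mu_a = 0.1, mu_s_prime = 10, g = 0.9),
                                     "raw"),
               1 / (3 * 1.1), tolerance = 1e-12)
  expect_error(diffusion_coefficient(list(mu_a = -1, mu_s_prime = 1, g = 0.9)))

  expect_equal(boundary_factor(0), 1)
  expect_equal(boundary_factor(1 / 3), 2)
  expect_equal(boundary_factor(0.431), 2.515, tolerance = 1e-3)
  expect_error(boundary_factor(1), "rf")
})

test_that("assembled system is symmetric and annihilates constants in the interior", {
  fix <- small_system()
  K <- fix$fem$K
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)

  # with mu_a = 0 only the Robin surface term acts on constants, so
  # interior rows of K * 1 vanish and the total equals area / (2F)
  optics0 <- data.frame(mu_a = 1e-300, mu_s_prime = 0.5, g = 0.9,
                        row.names = "Muscle")
  mesh <- build_structured_tet_mesh(c(4, 4, 4), 1)
  fem0 <- assemble_fem(mesh, optics = optics0)
  k1 <- as.numeric(fem0$K %*% rep(1, nrow(mesh$nodes)))
  interior <- setdiff(seq_len(nrow(mesh$nodes)), fem0$boundary_nodes)
  expect_lt(max(abs(k1[interior])), 1e-12)
  expect_equal(sum(k1), 6 * 16 / (2 * fem0$F), tolerance = 1e-10)
})

test_that("K is positive definite for every reference tissue", {
  mesh <- build_structured_tet_mesh(c(4, 4, 4), 1)
  for (tissue in rownames(tissue_optics())) {
    m <- mesh
    m$region <- rep(tissue, nrow(m$tets))
    fem <- assemble_fem(m)
    ev <- eigen(as.matrix(fem$K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("sparse solve agrees with a dense factorization", {
  mesh <- build_structured_tet_mesh(c(3, 3, 3), 1)   # 64 nodes
  fem <- assemble_fem(mesh)
  set.seed(7)
  s <- runif(nrow(mesh$nodes))
  phi_sparse <- solve_fem(fem, s)
  phi_dense <- solve(as.matrix(fem$K), as.matrix(fem$M) %*% s)
  expect_lt(sqrt(sum((phi_sparse - phi_dense)^2)) / sqrt(sum(phi_dense^2)),
            1e-8)
})

test_that("FEM converges at second order on a manufactured solution", {
  errs <- c(mms_error(2), mms_error(1), mms_error(0.5))
  expect_true(all(diff(errs) < 0))
  slope <- coef(lm(log2(errs) ~ log2(c(2, 1, 0.5))))[[2]]
  expect_gte(slope, 1.7)
})

test_that("the Green operator is reciprocal and near-nonnegative", {
  mesh <- build_structured_tet_mesh(c(4, 4, 4), 1)
  fem <- assemble_fem(mesh)
  # candidates include the boundary so A contains boundary-boundary blocks
  sysmat <- build_system_matrix(fem, candidate_nodes = seq_len(nrow(mesh$nodes)))
  bnd <- sysmat$row_nodes
  Ab <- sysmat$A[, match(bnd, sysmat$col_nodes)]
  expect_lt(max(abs(Ab - t(Ab))) / max(abs(Ab)), 1e-10)
  expect_gt(min(sysmat$A), -1e-10 * max(sysmat$A))
})

test_that("a mock identity system yields a selection matrix", {
  fem_mock <- list(K = Matrix::Diagonal(6), boundary_nodes = c(1L, 2L))
  sm <- build_system_matrix(fem_mock, candidate_nodes = 3:6)
  expect_equal(dim(sm$A), c(2L, 4L))
  expect_true(all(sm$A == 0))
  sm2 <- build_system_matrix(fem_mock, candidate_nodes = 1:3)
  expect_equal(sm2$A, cbind(diag(2), 0), ignore_attr = TRUE)
})

test_that("surface flux simulation is seeded, clamped and calibrated", {
  A <- diag(1000)
  x <- rep(1, 1000)
  expect_equal(simulate_surface_flux(A, x, 0), rep(1, 1000))
  b1 <- simulate_surface_flux(A, x, 0.05, seed = 11)
  b2 <- simulate_surface_flux(A, x, 0.05, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0))
  rel_rms <- sqrt(mean((b1 - 1)^2))
  expect_gt(rel_rms, 0.04)
  expect_lt(rel_rms, 0.06)
  expect_error(simulate_surface_flux(A, x, -0.1), "noise_level")
})
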