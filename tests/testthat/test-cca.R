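# Toy community table used throughout: 6 sites x 4 species, uneven margins.
toy_Y <- matrix(c(10, 2, 0, 1,
                  8, 3, 1, 0,
                  4, 6, 2, 1,
                  2, 7, 4, 2,
                  1, 5, 8, 3,
                  0, 2, 9, 6), nrow = 6, byrow = TRUE,
                dimnames = list(paste0("s", 1:6), paste0("sp", 1:4)))
toy_x <- cbind(act = c(0.1, 0.3, 0.9, 1.4, 2.2, 2.8))
toy_z <- cbind(year = c(1, 2, 1, 2, 1, 2))

test_that("constrained eigenvalues match the dense projection-matrix oracle", {
  fit <- pcca(toy_Y, toy_x)
  want <- oracle_pcca(toy_Y, toy_x)
  expect_equal(fit$constrained_inertia, want$constrained, tolerance = 1e-8)
  expect_equal(fit$total_inertia, want$total, tolerance = 1e-10)
  expect_equal(sort(fit$constrained_eig, decreasing = TRUE),
               sort(want$constrained_eig, decreasing = TRUE), tolerance = 1e-8)

  # 4-site x 3-species table with a binary constraint
  Y2 <- matrix(c(5, 1, 0, 4, 2, 1, 1, 3, 2, 0, 2, 5), nrow = 4, byrow = TRUE)
  X2 <- cbind(grp = c(0, 0, 1, 1))
  f2 <- pcca(Y2, X2)
  w2 <- oracle_pcca(Y2, X2)
  expect_equal(f2$constrained_eig, w2$constrained_eig, tolerance = 1e-8)

  # partial model: conditioning changes the decomposition consistently
  fp <- pcca(toy_Y, toy_x, toy_z)
  wp <- oracle_pcca(toy_Y, toy_x, toy_z)
  expect_equal(fp$constrained_inertia, wp$constrained, tolerance = 1e-8)
  expect_equal(fp$conditioned_inertia, wp$conditioned, tolerance = 1e-8)
  expect_equal(fp$residual_inertia, wp$residual, tolerance = 1e-8)
})

test_that("inertia decomposition conserves the total exactly", {
  for (Z in list(NULL, toy_z)) {
    fit <- pcca(toy_Y, toy_x, Z)
    expect_lt(abs(fit$conditioned_inertia + fit$constrained_inertia +
                    fit$residual_inertia - fit$total_inertia), 1e-8)
    expect_true(all(fit$constrained_eig >= 0))
    expect_true(all(fit$residual_eig >= 0))
  }
})

test_that("degenerate constraints degrade to zero constrained inertia", {
  # constant column: no constraint information, residual axes = plain CA
  expect_warning(f0 <- pcca(toy_Y, cbind(rep(1, 6))), "aliased")
  expect_equal(f0$constrained_inertia, 0)
  ca_eig <- oracle_pcca(toy_Y, diag(6))$constrained_eig  # full-rank CA eigens
  expect_equal(sort(f0$residual_eig, decreasing = TRUE), sort(ca_eig, decreasing = TRUE),
               tolerance = 1e-8)
  # Z = X partials everything out
  expect_warning(fz <- pcca(toy_Y, toy_x, toy_x), "aliased")
  expect_equal(fz$constrained_inertia, 0, tolerance = 1e-12)
})

test_that("full-rank site indicators explain the total inertia", {
  X <- stats::model.matrix(~ factor(1:6))[, -1]
  fit <- pcca(toy_Y, X)
  expect_equal(fit$constrained_inertia, fit$total_inertia, tolerance = 1e-10)
  expect_equal(fit$residual_inertia, 0, tolerance = 1e-10)
})

test_that("results agree with the reference implementation (vegan)", {
  skip_if_not_installed("vegan")
  ref <- vegan::cca(toy_Y ~ toy_x)
  fit <- pcca(toy_Y, toy_x)
  expect_equal(unname(fit$constrained_eig), unname(ref$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
  df <- data.frame(act = toy_x[, 1], year = toy_z[, 1])
  refp <- vegan::cca(toy_Y ~ act + Condition(year), data = df)
  fp <- pcca(toy_Y, toy_x, toy_z)
  expect_equal(unname(fp$constrained_eig), unname(refp$CCA$eig), tolerance = 1e-8)
  expect_equal(fp$conditioned_inertia, refp$pCCA$tot.chi, tolerance = 1e-8)
  # pseudo-F as computed by anova.cca
  an <- vegan::anova.cca(refp, permutations = 99)
  expect_equal(fp$pseudo_f, an$F[1], tolerance = 1e-8)
})

test_that("permutation test is deterministic, valid at the extremes", {
  # strong signal: observed F above every permutation -> minimum p
  res <- pcca_permutation(toy_Y, toy_x, n_perm = 199, seed = 42)
  expect_equal(res$p_value, pcca_permutation(toy_Y, toy_x, n_perm = 199,
                                             seed = 42)$p_value)
  expect_gte(res$p_value, 1 / 200)
  expect_error(pcca_permutation(toy_Y, toy_x, n_perm = 10), "at least 99")
  expect_error(pcca_permutation(toy_Y[1:2, ], toy_x[1:2, , drop = FALSE],
                                n_perm = 99), "too few rows")
})

test_that("year check wraps pcca and flags degenerate year input", {
  ls <- generate_landscape(landscape_config(n_properties = 4), seed = 2)
  tr <- simulate_visitation(ls, visitation_params(), seed = 2)
  # year loading 0, noise 0 -> constrained inertia ~ 0
  s0 <- generate_tree_surveys(ls, tr, species_response(year_loading = 0,
                                                       noise_sd = 0), seed = 3)
  yc <- cca_year_check(s0, n_perm = 99, seed = 1)
  expect_lt(yc$fit$constrained_inertia, 1e-10)
  # strong year loading -> minimum attainable p
  s1 <- generate_tree_surveys(ls, tr, species_response(year_loading = 2,
                                                       noise_sd = 0.01), seed = 3)
  yc1 <- cca_year_check(s1, n_perm = 99, seed = 1)
  expect_equal(yc1$test$p_value, 1 / 100)
  # wrapper equivalence with a direct call
  parts <- parkactivity:::split_survey_table(s1)
  direct <- pcca(parts$Y, cbind(year = as.numeric(parts$meta$year)))
  expect_equal(yc1$fit$constrained_inertia, direct$constrained_inertia)
  expect_equal(yc1$fit$pseudo_f, direct$pseudo_f)
  # single year rejected
  s_one <- s0[s0$year == s0$year[1], ]
  expect_error(cca_year_check(s_one), "2 distinct")
})

test_that("species score signs follow generating loadings (orientation fixed)", {
  ls <- generate_landscape(landscape_config(n_properties = 10), seed = 6)
  tr <- simulate_visitation(ls, visitation_params(), seed = 6)
  eff <- species_response(noise_sd = 0.02)
  s <- generate_tree_surveys(ls, tr, eff, seed = 7)
  parts <- parkactivity:::split_survey_table(s)
  z <- attr(s, "activity_z")
  X <- cbind(act = z[parts$meta$site_id])
  fit <- pcca(parts$Y, X, cbind(year = as.numeric(parts$meta$year)))
  signs <- sign(fit$species_scores[, 1])
  expect_equal(unname(signs), unname(sign(attr(s, "loadings"))))
})
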