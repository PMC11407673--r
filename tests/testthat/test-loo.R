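# PSIS-LOO, model weights, candidate set, and backward elimination.

test_that("constant pointwise log-likelihood gives elpd_i equal to it exactly", {
  ll <- matrix(rep(c(-1.3, -0.7, -2.1), each = 500), nrow = 3, byrow = TRUE)
  out <- loo_elpd(ll)
  expect_equal(out$pointwise$elpd_i, c(-1.3, -0.7, -2.1))
  expect_equal(out$elpd, sum(c(-1.3, -0.7, -2.1)))
})

test_that("duplicating every site doubles the total elpd", {
  set.seed(51)
  ll <- matrix(rnorm(40 * 800, -1, 0.3), 40, 800)
  e1 <- loo_elpd(ll)$elpd
  e2 <- loo_elpd(rbind(ll, ll))$elpd
  expect_equal(e2, 2 * e1, tolerance = 1e-10)
})

test_that("model weights behave at the symmetric and single-model limits", {
  study <- small_study(n_stations = 40, seed = 52)
  fit <- quick_fit(occu_spec("tree_cover", character(0), FALSE), study,
                   n_iter = 800)
  single <- compare_models(list(only = fit))
  expect_equal(single$weight, 1)
  expect_equal(single$delta_elpd, 0)

  twin <- compare_models(list(a = fit, b = fit))
  expect_equal(twin$weight, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(twin$weight), 1)

  stacked <- compare_models(list(a = fit, b = fit), method = "stacking")
  expect_equal(sum(stacked$weight), 1, tolerance = 1e-6)
})

test_that("comparison is invariant to the order models are supplied in", {
  study <- small_study(n_stations = 50, seed = 53)
  f1 <- quick_fit(occu_spec("tree_cover", "effort", FALSE), study,
                  n_iter = 800)
  f2 <- quick_fit(occu_spec(character(0), "effort", FALSE), study,
                  n_iter = 800)
  c12 <- compare_models(list(m1 = f1, m2 = f2))
  c21 <- compare_models(list(m2 = f2, m1 = f1))
  expect_equal(c12$elpd[match("m1", c12$model)],
               c21$elpd[match("m1", c21$model)])
  expect_equal(c12$weight[match("m2", c12$model)],
               c21$weight[match("m2", c21$model)], tolerance = 1e-2)
  expect_equal(attr(c12, "best"), attr(c21, "best"))
})

test_that("mismatched site sets are refused", {
  study <- small_study(n_stations = 30, seed = 54)
  f1 <- quick_fit(occu_spec(), study, n_iter = 400)
  study2 <- small_study(n_stations = 25, seed = 55)
  f2 <- quick_fit(occu_spec(), study2, n_iter = 400)
  expect_error(compare_models(list(a = f1, b = f2)), "different site sets")
})

test_that("the smaller generating model is not out-predicted by a larger one", {
  wins <- 0L
  for (r in 1:10) {
    study <- small_study(n_stations = 100, seed = 60 + r,
                         beta = c(tree_cover = 0.7))
    small <- quick_fit(occu_spec("tree_cover", "effort", FALSE), study,
                       n_iter = 1000, seed = r)
    large <- quick_fit(occu_spec(c("tree_cover", "dist_road",
                                   "dist_settlement"), "effort", FALSE),
                       study, n_iter = 1000, seed = r)
    l_s <- loo_elpd(small); l_l <- loo_elpd(large)
    if (l_s$elpd >= l_l$elpd - 2 * l_l$se) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("backward elimination drops the null term and keeps the real effect", {
  study <- small_study(n_stations = 120, seed = 71,
                       beta = c(tree_cover = 2, dist_road = 0))
  out <- backward_eliminate(
    occu_spec(c("tree_cover", "dist_road"), "effort", FALSE),
    study$history, study$std_cov, margin = 2,
    fit_args = list(n_chains = 2, n_iter = 1200, n_adapt = 250, seed = 3))
  expect_equal(out$trail$removed_term[2], "dist_road")
  expect_true("tree_cover" %in% out$spec$psi_terms)
  expect_false("dist_road" %in% out$spec$psi_terms)
})

test_that("on null data elimination reaches the intercept-only model", {
  study <- small_study(n_stations = 80, seed = 72,
                       beta = c(tree_cover = 0, dist_road = 0))
  out <- backward_eliminate(
    occu_spec(c("tree_cover", "dist_road"), "effort", FALSE),
    study$history, study$std_cov, margin = 2,
    fit_args = list(n_chains = 2, n_iter = 1000, n_adapt = 250, seed = 4))
  expect_length(out$spec$psi_terms, 0)
  expect_true(all(out$trail$accepted))
})

test_that("an empty starting model is returned unchanged", {
  study <- small_study(n_stations = 10, seed = 73)
  sp <- occu_spec(character(0), "effort", FALSE)
  out <- backward_eliminate(sp, study$history, study$std_cov)
  expect_identical(out$spec, sp)
  expect_equal(nrow(out$trail), 0L)
})

test_that("the candidate set matches the analysis' hypothesis structure", {
  cand <- candidate_model_set()
  expect_gte(length(cand), 6L)
  nulls <- vapply(cand, function(s)
    length(s$psi_terms) == 0 && length(s$p_terms) == 0, logical(1))
  expect_equal(sum(nulls), 1L)
  expect_false(any(c("dist_road", "dist_settlement") %in%
                     cand$environmental$psi_terms))
  expect_setequal(cand$anthropogenic$psi_terms,
                  c("dist_road", "dist_settlement"))
  with_effort <- vapply(cand, function(s) "effort" %in% s$p_terms, logical(1))
  expect_true(all(with_effort[!nulls]))
  expect_true(cand$global_re$random_station_intercept)
  expect_false(cand$global_fixed$random_station_intercept)
})
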