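curve_0_10k <- make_curve("identity", range = c(0, 10000), resolution = 5)

dated_au <- function(id, ages, errors = 50, depth = NULL) {
  errors <- rep_len(errors, length(ages))
  analysis_unit(id, dates = lapply(seq_along(ages), function(i)
    geochron_date(ages[i], errors[i], lab_id = paste0(id, "-", i))),
    depth = depth)
}

test_that("infer_order uses depths (deeper = older) and degrades on ties", {
  cu <- collection_unit("C", list(dated_au("A", 3000, depth = 1.5),
                                  dated_au("B", 2500, depth = 1.0),
                                  dated_au("C", 2000, depth = 0.5)))
  ord <- infer_order(cu)
  expect_true(ord$ordered)
  expect_equal(ord$order, c(1L, 2L, 3L))   # deepest (oldest) first

  cu2 <- collection_unit("C", list(dated_au("A", 3000), dated_au("B", 2500)))
  expect_false(infer_order(cu2)$ordered)

  cu3 <- collection_unit("C", list(dated_au("A", 3000, depth = 1.0),
                                   dated_au("B", 2500, depth = 1.0)))
  expect_warning(ord3 <- infer_order(cu3), "duplicate depths")
  expect_false(ord3$ordered)

  cu4 <- collection_unit("C", list(dated_au("A", 2000), dated_au("B", 3000)),
                         declared_order = c("B", "A"))
  ord4 <- infer_order(cu4)
  expect_true(ord4$ordered)
  expect_equal(ord4$order, c(2L, 1L))      # B declared older
})

test_that("build_collection_model creates one phase per dated unit", {
  cu <- collection_unit("C", list(
    dated_au("A", c(5000, 5200)),
    dated_au("B", c(7000, 7300)),
    analysis_unit("U")))                    # undated: excluded from the model
  m <- build_collection_model(cu, curve_0_10k)
  expect_s3_class(m, "sequence_spec")
  expect_length(m$phases, 2L)
  expect_false(m$ordered)
  expect_length(m$phases[[1]]$event_densities, 2L)

  # mixed radiocarbon + calendar-scale dates in one phase
  mixed <- collection_unit("C", list(analysis_unit("M", dates = list(
    geochron_date(5000, 50), geochron_date(6000, 300, kind = "calendar")))))
  mm <- build_collection_model(mixed, curve_0_10k)
  expect_length(mm$phases[[1]]$event_densities, 2L)

  undated_only <- collection_unit("C", list(analysis_unit("U")))
  expect_error(build_collection_model(undated_only, curve_0_10k),
               "no dated analysis units")
})

test_that("log_posterior_density matches hand computation and enforces constraints", {
  dens <- lapply(c(5000, 5200), function(a)
    calibrate_radiocarbon(geochron_date(a, 50), curve_0_10k))
  m <- sequence_spec(list(phase_spec("A", dens)), span_prior_exponent = 0)

  # event outside its boundaries
  expect_identical(log_posterior_density(m, list(list(t = c(5000, 5600),
                                                      alpha = 5500, beta = 4900))),
                   -Inf)
  # boundary outside the curve range
  expect_identical(log_posterior_density(m, list(list(t = c(5000, 5200),
                                                      alpha = 10050, beta = 4900))),
                   -Inf)
  # hand-computed: sum(log grid mass) + (s - n) log(alpha - beta)
  st <- list(list(t = c(5000, 5200), alpha = 5500, beta = 4800))
  p1 <- dens[[1]]$p[dens[[1]]$grid == 5000]
  p2 <- dens[[2]]$p[dens[[2]]$grid == 5200]
  by_hand <- log(p1) + log(p2) + (0 - 2) * log(5500 - 4800)
  expect_equal(log_posterior_density(m, st), by_hand)

  # the "n-1" span prior option changes only the span exponent
  m2 <- sequence_spec(list(phase_spec("A", dens)), span_prior_exponent = "n-1")
  expect_equal(log_posterior_density(m2, st),
               log(p1) + log(p2) + (1 - 2) * log(700))

  # ordered two-phase monotonicity violation
  dens2 <- list(calibrate_radiocarbon(geochron_date(7000, 50), curve_0_10k))
  mo <- sequence_spec(list(phase_spec("Y", dens), phase_spec("O", dens2)),
                      ordered = TRUE, order = c(2L, 1L))
  bad <- list(list(t = c(5000, 5200), alpha = 7400, beta = 4800),
              list(t = 7000, alpha = 7100, beta = 6900))
  expect_identical(log_posterior_density(mo, bad), -Inf)  # beta_O < alpha_Y
})

test_that("sampler respects containment, ordering, and seed determinism", {
  dens <- lapply(c(5000, 5200), function(a)
    calibrate_radiocarbon(geochron_date(a, 50), curve_0_10k))
  m <- sequence_spec(list(phase_spec("A", dens)))
  s <- sample_posterior(m, n_iter = 4000, burn_in = 1000, thin = 2,
                        chains = 2, seed = 11)
  a <- s$draws[["alpha[1]"]]; b <- s$draws[["beta[1]"]]
  t1 <- s$draws[["t[1,1]"]]; t2 <- s$draws[["t[1,2]"]]
  pr <- s$draws[["pred[1]"]]
  # per-draw containment, exhaustively
  expect_true(all(b <= t1 & t1 <= a))
  expect_true(all(b <= t2 & t2 <= a))
  expect_true(all(b <= pr & pr <= a))
  # quantile-wise stochastic dominance alpha >= events >= beta
  for (q in seq(0.05, 0.95, by = 0.1)) {
    qa <- quantile(a, q); qb <- quantile(b, q)
    expect_gte(qa, quantile(t1, q)); expect_gte(qa, quantile(t2, q))
    expect_lte(qb, quantile(t1, q)); expect_lte(qb, quantile(t2, q))
  }
  # seed determinism
  s2 <- sample_posterior(m, n_iter = 4000, burn_in = 1000, thin = 2,
                         chains = 2, seed = 11)
  expect_identical(s$draws, s2$draws)
  s3 <- sample_posterior(m, n_iter = 4000, burn_in = 1000, thin = 2,
                         chains = 2, seed = 12)
  expect_false(identical(s$draws, s3$draws))
})

test_that("ordered two-phase models keep every draw monotone", {
  m <- sequence_spec(
    list(phase_spec("young", list(calibrate_radiocarbon(
           geochron_date(4000, 60), curve_0_10k))),
         phase_spec("old", list(calibrate_radiocarbon(
           geochron_date(7000, 60), curve_0_10k)))),
    ordered = TRUE, order = c(2L, 1L))
  s <- sample_posterior(m, n_iter = 4000, burn_in = 1000, thin = 2,
                        chains = 2, seed = 3)
  # phase 2 ("old") is first in the sequence: beta_old >= alpha_young always
  expect_true(all(s$draws[["beta[2]"]] >= s$draws[["alpha[1]"]]))
})

test_that("single-date event posterior reproduces the calibrated density (KS < 0.05)", {
  dens <- calibrate_radiocarbon(geochron_date(5000, 50), curve_0_10k)
  m <- sequence_spec(list(phase_spec("A", list(dens))))
  s <- sample_posterior(m, n_iter = 12000, burn_in = 2000, thin = 2,
                        chains = 2, seed = 5)
  draws <- as.vector(s$draws[["t[1,1]"]])
  expect_gte(length(draws), 10000)
  expect_lt(ks_to_density(draws, dens), 0.05)
})

test_that("1-phase medians agree with the brute-force grid oracle", {
  cv <- make_curve("identity", range = c(3000, 7000), resolution = 5)
  dens <- lapply(c(4800, 5100), function(a)
    calibrate_radiocarbon(geochron_date(a, 60), cv))
  orc <- oracle_one_phase(dens)
  m <- sequence_spec(list(phase_spec("A", dens)))
  s <- sample_posterior(m, n_iter = 20000, burn_in = 4000, thin = 2,
                        chains = 2, seed = 21)
  for (nm in c("alpha[1]", "beta[1]", "t[1,1]", "t[1,2]", "pred[1]")) {
    d <- s$draws[[nm]]
    target <- switch(nm, `alpha[1]` = orc$alpha, `beta[1]` = orc$beta,
                     `t[1,1]` = orc$events[1], `t[1,2]` = orc$events[2],
                     `pred[1]` = orc$pred)
    tol <- max(10, 2 * mcse_median(d))
    expect_within(median(d), target, tol)
  }
})

test_that("convergence diagnostics behave on degenerate and iid chains", {
  fake <- function(m) structure(
    list(draws = list(x = m), chains = ncol(m),
         phases = data.frame(phase = 1L, analysis_unit_ref = "A", n_dates = 1L),
         n_kept = nrow(m)),
    class = "posterior_samples")

  set.seed(99)
  iid <- rnorm(4000)
  ident <- fake(cbind(iid[1:2000], iid[1:2000]))   # two identical chains
  d1 <- convergence_diagnostics(ident)
  expect_within(d1$rhat, 1, 0.01)
  expect_false(attr(d1, "flag"))

  const <- fake(cbind(rep(1, 500), rep(2, 500)))   # constant, different values
  d2 <- convergence_diagnostics(const)
  expect_gt(d2$rhat, 1.1)
  expect_true(attr(d2, "flag"))

  gauss <- fake(matrix(rnorm(8000), ncol = 2))     # iid draws
  d3 <- convergence_diagnostics(gauss)
  expect_within(d3$ess, 8000, 0.2 * 8000)
})

test_that("sampler input contracts are enforced", {
  dens <- calibrate_radiocarbon(geochron_date(5000, 50), curve_0_10k)
  m <- sequence_spec(list(phase_spec("A", list(dens))))
  expect_error(sample_posterior(m, n_iter = 100, burn_in = 200, chains = 2,
                                seed = 1), "exceed")
  expect_error(sample_posterior(m, chains = 1, seed = 1), "2 chains")
  expect_error(sample_posterior(m, n_iter = 500, burn_in = 100, chains = 2),
               "seed")
  expect_error(phase_spec("A", list()), "at least one event density")
  expect_error(sequence_spec(list(phase_spec("A", list(dens))), ordered = TRUE,
                             order = c(1L, 2L)), "permutation")
})
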