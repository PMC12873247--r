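#' Synthetic calibration curves and collections with known ground truth
#'
#' The generator emulates the statistical structure the chronology pipeline
#' assumes: a calibration curve of known functional form, phases whose true
#' boundaries and event ages are recorded, observed radiocarbon ages drawn
#' as curve(true age) plus Gaussian laboratory error, optional stratigraphic
#' ordering, and undated analysis units placed to exercise every
#' stratigraphic inference rule.  Defaults (lab errors 30-150 14C yr drawn
#' log-uniformly, phase spans 200-2,000 yr) resemble the Holocene-dominated
#' collections the pipeline targets while keeping desk-scale runtimes.
#'
#' @name synthetic_data
NULL

#' Make a synthetic calibration curve
#'
#' @param kind `"identity"` (mu = theta), `"linear"` (mu = a + b*theta,
#'   b > 0) or `"wiggly"` (linear plus bounded sinusoidal wiggles).
#' @param range calendar age range, within [0, 55000] cal BP.
#' @param resolution grid step in years.
#' @param a,b intercept and slope for linear/wiggly kinds.
#' @param amplitude,period wiggle amplitude (14C yr) and period (yr).
#' @param sigma curve one-sigma: a constant, or a function of the grid age.
#' @return A [cal_curve].
#' @export
make_curve <- function(kind = c("identity", "linear", "wiggly"),
                       range = c(0, 55000), resolution = 1,
                       a = 0, b = 1, amplitude = 50, period = 500,
                       sigma = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(range[1] >= 0, range[2] <= 55000, range[2] > range[1])
  grid <- seq(range[1], range[2], by = resolution)
  mu <- switch(kind,
    identity = grid,
    linear = {
      if (b <= 0) stop("linear curve requires a positive slope")
      a + b * grid
    },
    wiggly = {
      if (b <= 0) stop("wiggly curve requires a positive underlying slope")
      a + b * grid + amplitude * sin(2 * pi * grid / period)
    })
  sig <- if (is.function(sigma)) sigma(grid) else rep(sigma, length(grid))
  sig <- pmax(sig, 1e-8)  # strictly positive even for "noise-free" curves
  cal_curve(grid, mu, sig, name = paste0("synthetic-", kind))
}

curve_mu_at <- function(curve, age) {
  stats::approx(curve$grid, curve$mu, xout = age, rule = 2)$y
}

#' Simulate a collection unit with known truth
#'
#' Per dated unit a true phase window is drawn (span log-uniform within
#' `span_range`), true event ages uniformly within the window, and observed
#' 14C ages as `mu(true age) + Normal(0, lab sigma)` with lab sigma drawn
#' log-uniformly from `lab_error_range`.  When `ordered`, phase windows are
#' disjoint and the units carry depths consistent with the order.  Undated
#' units can be appended above/below/between/inside dated units to exercise
#' the stratigraphic inference rules.
#'
#' @param n_units number of dated analysis units (>= 1).
#' @param dates_per_unit dates per unit; recycled to `n_units`.
#' @param curve a [cal_curve] to observe through.
#' @param seed integer seed; the simulation is deterministic given it.
#' @param age_range cal BP window within which phases are placed.
#' @param span_range phase span range (years).
#' @param lab_error_range laboratory one-sigma range (14C years).
#' @param ordered give units depths (deeper = older) and disjoint windows.
#' @param undated character vector of placements for extra undated units,
#'   from `"above"`, `"below"`, `"between"`, `"subset"`, `"unrelated"`.
#' @return List with `collection` (a [collection_unit]) and `truth` (a
#'   `synthetic_truth`: per-phase boundaries, true event ages, lab errors,
#'   scenario tags, seed).
#' @export
simulate_collection <- function(n_units = 2L, dates_per_unit = 2L,
                                curve = make_curve("identity"),
                                seed,
                                age_range = c(1000, 12000),
                                span_range = c(200, 2000),
                                lab_error_range = c(30, 150),
                                ordered = FALSE, undated = character(0)) {
  if (missing(seed)) stop("a seed must be supplied")
  stopifnot(n_units >= 1L)
  if (age_range[2] <= age_range[1]) stop("infeasible age_range (younger > older)")
  set.seed(as.integer(seed))
  dates_per_unit <- rep_len(dates_per_unit, n_units)
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

  spans <- runif_log(n_units, span_range[1], span_range[2])
  if (ordered) {
    # disjoint windows, oldest first
    gaps <- runif_log(n_units + 1L, 50, 500)
    total <- sum(spans) + sum(gaps)
    if (total > diff(age_range))
      stop("infeasible config: ordered spans exceed the age range")
    top <- age_range[2] - gaps[1L]
    alpha <- beta <- numeric(n_units)
    for (j in seq_len(n_units)) {
      alpha[j] <- top
      beta[j] <- top - spans[j]
      top <- beta[j] - gaps[j + 1L]
    }
  } else {
    beta <- stats::runif(n_units, age_range[1], age_range[2] - spans)
    alpha <- beta + spans
  }

  truth_events <- vector("list", n_units)
  truth_errors <- vector("list", n_units)
  aus <- vector("list", n_units)
  for (j in seq_len(n_units)) {
    n <- dates_per_unit[j]
    t_true <- sort(stats::runif(n, beta[j], alpha[j]), decreasing = TRUE)
    lab_sd <- runif_log(n, lab_error_range[1], lab_error_range[2])
    obs <- curve_mu_at(curve, t_true) + stats::rnorm(n, 0, lab_sd)
    dates <- lapply(seq_len(n), function(i)
      geochron_date(age = round(obs[i]), error_minus = round(lab_sd[i]),
                    lab_id = sprintf("SYN-%d-%d", j, i)))
    aus[[j]] <- analysis_unit(
      id = sprintf("AU%d", j), dates = dates,
      depth = if (ordered) (n_units - j + 1) * 0.5 else NULL)
    truth_events[[j]] <- t_true
    truth_errors[[j]] <- lab_sd
  }

  tags <- character(0)
  k <- n_units
  for (p in undated) {
    k <- k + 1L
    au <- switch(p,
      above = { tags <- c(tags, if (ordered) "rule_c" else "rule_e")
        analysis_unit(sprintf("AU%d", k), depth = if (ordered) 0.25 else NULL) },
      below = { tags <- c(tags, if (ordered) "rule_d" else "rule_e")
        analysis_unit(sprintf("AU%d", k),
                      depth = if (ordered) (n_units + 1) * 0.5 else NULL) },
      between = { tags <- c(tags, if (ordered && n_units >= 2L) "rule_b" else "rule_e")
        analysis_unit(sprintf("AU%d", k),
                      depth = if (ordered && n_units >= 2L) 0.75 else NULL) },
      subset = { tags <- c(tags, "rule_a")
        analysis_unit(sprintf("AU%d", k), subset_of = "AU1") },
      unrelated = { tags <- c(tags, "rule_e")
        analysis_unit(sprintf("AU%d", k)) },
      stop("unknown undated placement: ", p))
    aus[[k]] <- au
  }

  cu <- collection_unit(sprintf("SYN-CU-%d", as.integer(seed)), aus)
  truth <- structure(
    list(alpha = alpha, beta = beta, events = truth_events,
         lab_errors = truth_errors, scenario_tags = tags,
         seed = as.integer(seed)),
    class = "synthetic_truth")
  list(collection = cu, truth = truth)
}

#' Deterministic fixtures for the stratigraphic inference rules
#'
#' One fixture per rule (a, b, b1, c, d, e): a small collection unit with
#' hand-specified dated sample ages and one undated unit, together with the
#' hand-computed expected inferred range.  These are bit-stable and involve
#' no random numbers.
#'
#' @return A named list of fixtures, each with `cu`, `dated_sample_ages`,
#'   `undated_id`, and `expected` (the expected one-row sample-age frame).
#' @export
scenario_fixtures <- function() {
  dated_sa <- function(id, older, younger)
    new_sample_age(id, "bounds", NA_real_, older, younger, "direct")
  dummy_date <- function() geochron_date(5000, 50, lab_id = "FIX-1")

  fixtures <- list()

  # rule a: undated unit U is a subset of dated D [12000, 9000]
  fixtures$rule_a <- list(
    cu = collection_unit("FIX-A", list(
      analysis_unit("D", dates = list(dummy_date()), depth = 1),
      analysis_unit("U", subset_of = "D"))),
    dated_sample_ages = dated_sa("D", 12000, 9000),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 12000, 9000, "rule_a"))

  # rule b: U between D1 (below, [15000, 13000]) and D2 (above, [11000, 10000])
  fixtures$rule_b <- list(
    cu = collection_unit("FIX-B", list(
      analysis_unit("D1", dates = list(dummy_date()), depth = 3),
      analysis_unit("U", depth = 2),
      analysis_unit("D2", dates = list(dummy_date()), depth = 1))),
    dated_sample_ages = rbind(dated_sa("D1", 15000, 13000),
                              dated_sa("D2", 11000, 10000)),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 13000, 11000, "rule_b"))

  # rule b1: as b but the dated ranges overlap -> full combined range
  fixtures$rule_b1 <- list(
    cu = collection_unit("FIX-B1", list(
      analysis_unit("D1", dates = list(dummy_date()), depth = 3),
      analysis_unit("U", depth = 2),
      analysis_unit("D2", dates = list(dummy_date()), depth = 1))),
    dated_sample_ages = rbind(dated_sa("D1", 15000, 12000),
                              dated_sa("D2", 13000, 10000)),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 15000, 10000, "rule_b1"))

  # rule c: U above all dated units; younger limit floors at 0
  fixtures$rule_c <- list(
    cu = collection_unit("FIX-C", list(
      analysis_unit("D", dates = list(dummy_date()), depth = 2),
      analysis_unit("U", depth = 1))),
    dated_sample_ages = dated_sa("D", 9000, 7000),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 7000, 0, "rule_c"))

  # rule d: U below all dated units, external older constraint 20000
  fixtures$rule_d <- list(
    cu = collection_unit("FIX-D", list(
      analysis_unit("D", dates = list(dummy_date()), depth = 1),
      analysis_unit("U", depth = 2, older_constraint = 20000))),
    dated_sample_ages = dated_sa("D", 9000, 7000),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 20000, 9000, "rule_d"))

  # rule e: no stratigraphic relationship -> full dated range
  fixtures$rule_e <- list(
    cu = collection_unit("FIX-E", list(
      analysis_unit("D1", dates = list(dummy_date())),
      analysis_unit("D2", dates = list(dummy_date())),
      analysis_unit("U"))),
    dated_sample_ages = rbind(dated_sa("D1", 14000, 11000),
                              dated_sa("D2", 9000, 6000)),
    undated_id = "U",
    expected = new_sample_age("U", "bounds", NA_real_, 14000, 6000, "rule_e"))

  fixtures
}
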