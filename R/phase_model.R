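#' Bayesian phase models for collection units
#'
#' A collection unit is modeled as a set of phases, one per dated analysis
#' unit.  Within phase j the event ages t_ij are, conditional on the phase
#' boundaries, independently uniform on [beta_j, alpha_j] (alpha = older
#' boundary, beta = younger boundary, both in cal BP), each event further
#' weighted by its calibrated age density.  The likelihood contribution of a
#' phase with n events is therefore (alpha - beta)^(-n); a configurable span
#' prior exponent s adds (alpha - beta)^s.  The default s = 0 is the flat
#' prior on the boundary pair; the alternative `"n-1"` flattens the
#' posterior span distribution instead.  When
#' the analysis units carry a clear stratigraphic order the phases are
#' chained oldest to youngest by requiring beta_(older) >= alpha_(younger)
#' for adjacent phases.
#'
#' @name phase_model
NULL

#' Build a phase specification for one dated analysis unit
#'
#' @param analysis_unit_ref identifier of the analysis unit.
#' @param event_densities list of `cal_density`, one per usable date.
#' @param include_predictive draw a predictive ("new date from the same
#'   pool") event each kept iteration; always on for chronology building.
#' @return A `phase_spec` object.
#' @export
phase_spec <- function(analysis_unit_ref, event_densities,
                       include_predictive = TRUE) {
  if (length(event_densities) == 0L)
    stop("a phase needs at least one event density; undated units are handled ",
         "by stratigraphic inference, not by the phase model")
  stopifnot(all(vapply(event_densities, inherits, logical(1), "cal_density")))
  structure(
    list(analysis_unit_ref = analysis_unit_ref,
         event_densities = event_densities,
         include_predictive = isTRUE(include_predictive)),
    class = "phase_spec"
  )
}

#' Build a sequence specification (a set of phases, possibly ordered)
#'
#' @param phases list of [phase_spec] objects.
#' @param ordered do the phases carry a clear stratigraphic order?
#' @param order integer permutation of `seq_along(phases)` giving the
#'   oldest-to-youngest order; required when `ordered` is `TRUE`.
#' @param span_prior_exponent exponent s of the (alpha - beta)^s span prior
#'   term: a number applied to every phase, or the string `"n-1"` for the
#'   per-phase value n_j - 1.  The default 0 is the flat prior on the
#'   boundary pair (the standard uniform-phase posterior); `"n-1"` flattens
#'   the posterior span distribution instead, which with wide boundary
#'   support produces extremely diffuse boundaries (see the methods
#'   vignette for the calibration evidence behind the default).
#' @return A `sequence_spec` object.
#' @export
sequence_spec <- function(phases, ordered = FALSE, order = NULL,
                          span_prior_exponent = 0) {
  stopifnot(all(vapply(phases, inherits, logical(1), "phase_spec")))
  if (ordered) {
    if (is.null(order)) order <- seq_along(phases)
    if (!setequal(order, seq_along(phases)) || length(order) != length(phases))
      stop("order must be a permutation of the phase indices")
  } else order <- NULL
  structure(
    list(phases = phases, ordered = isTRUE(ordered), order = order,
         span_prior_exponent = span_prior_exponent),
    class = "sequence_spec"
  )
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec: %d phase(s), %s>\n", length(x$phases),
              if (x$ordered) "ordered oldest-to-youngest" else "unordered"))
  invisible(x)
}

phase_span_exponent <- function(model, j) {
  s <- model$span_prior_exponent
  n <- length(model$phases[[j]]$event_densities)
  if (identical(s, "n-1")) n - 1 else as.numeric(s)
}

#' Infer stratigraphic ordering of dated analysis units
#'
#' Ordered is declared only when the order is unambiguous: either the
#' collection carries an explicit user-declared order, or every dated
#' analysis unit has a distinct numeric depth (deeper = older).  Ties or
#' partially missing depths degrade to unordered with a warning.
#'
#' @param cu a [collection_unit].
#' @param dated_ids ids of the analysis units entering the model (defaults
#'   to all units holding at least one date).
#' @return A list with elements `ordered` (flag) and `order` (indices into
#'   `dated_ids`, oldest first, or `NULL`).
#' @export
infer_order <- function(cu, dated_ids = NULL) {
  stopifnot(inherits(cu, "collection_unit"))
  ids <- vapply(cu$analysis_units, function(a) as.character(a$id), character(1))
  if (is.null(dated_ids)) {
    has_dates <- vapply(cu$analysis_units, function(a) length(a$dates) > 0, logical(1))
    dated_ids <- ids[has_dates]
  }
  dated_ids <- as.character(dated_ids)
  if (!is.null(cu$declared_order)) {
    decl <- as.character(cu$declared_order)
    if (all(dated_ids %in% decl)) {
      pos <- match(dated_ids, decl)
      return(list(ordered = TRUE, order = order(pos)))
    }
    warning("declared order does not cover all dated analysis units; treating as unordered")
    return(list(ordered = FALSE, order = NULL))
  }
  depths <- vapply(cu$analysis_units[match(dated_ids, ids)],
                   function(a) if (is.null(a$depth)) NA_real_ else as.numeric(a$depth),
                   numeric(1))
  if (length(dated_ids) >= 2L && !anyNA(depths)) {
    if (anyDuplicated(depths)) {
      warning("duplicate depths among dated analysis units; no clear ",
              "stratigraphic order, treating as unordered")
      return(list(ordered = FALSE, order = NULL))
    }
    return(list(ordered = TRUE, order = order(depths, decreasing = TRUE)))
  }
  list(ordered = FALSE, order = NULL)
}

#' Build the phase model for a collection unit
#'
#' One phase per dated analysis unit; radiocarbon dates are calibrated
#' against `curve` and calendar dates placed directly on the cal BP axis.
#' Undated analysis units are excluded (their ages are inferred afterwards
#' from stratigraphy).  Dates should be pre-filtered with
#' [filter_geochron_dates()].
#'
#' @param cu a [collection_unit] whose analysis units carry usable dates.
#' @param curve a [cal_curve].
#' @param span_prior_exponent see [sequence_spec()].
#' @return A [sequence_spec].
#' @export
build_collection_model <- function(cu, curve, span_prior_exponent = 0) {
  stopifnot(inherits(cu, "collection_unit"), inherits(curve, "cal_curve"))
  dated <- Filter(function(a) length(a$dates) > 0, cu$analysis_units)
  if (length(dated) == 0L)
    stop("collection unit ", cu$id, " has no dated analysis units; ",
         "no chronology can be modeled (collection must be dropped)")
  phases <- lapply(dated, function(a) {
    dens <- lapply(a$dates, date_density, curve = curve)
    phase_spec(a$id, dens)
  })
  ord <- infer_order(cu, dated_ids = vapply(dated, function(a) as.character(a$id),
                                            character(1)))
  sequence_spec(phases, ordered = ord$ordered, order = ord$order,
                span_prior_exponent = span_prior_exponent)
}

grid_range <- function(model) {
  g <- model$phases[[1L]]$event_densities[[1L]]$grid
  c(min(g), max(g))
}

#' Log posterior density of a model state, up to a constant
#'
#' The state holds, per phase, the event ages `t` (vector), the older
#' boundary `alpha` and the younger boundary `beta`.  The value is the sum
#' over phases of `sum(log d_ij(t_ij)) + (s_j - n_j) * log(alpha_j - beta_j)`
#' where `d_ij` is the calibrated probability mass at the grid point nearest
#' `t_ij`, with indicator terms enforcing `beta_j <= t_ij <= alpha_j`,
#' boundary support within the curve grid, and (if ordered) cross-phase
#' monotonicity; `-Inf` is returned as soon as any constraint fails.
#'
#' @param model a [sequence_spec].
#' @param state list of per-phase lists with elements `t`, `alpha`, `beta`,
#'   in model phase order.
#' @return A single numeric log density (up to an additive constant).
#' @export
log_posterior_density <- function(model, state) {
  stopifnot(inherits(model, "sequence_spec"), length(state) == length(model$phases))
  rng <- grid_range(model)
  lp <- 0
  for (j in seq_along(model$phases)) {
    ph <- model$phases[[j]]
    st <- state[[j]]
    n <- length(ph$event_densities)
    if (length(st$t) != n) stop("state phase ", j, " has wrong event count")
    a <- st$alpha; b <- st$beta
    if (!(a > b) || a > rng[2L] || b < rng[1L]) return(-Inf)
    if (any(st$t < b) || any(st$t > a)) return(-Inf)
    for (i in seq_len(n)) {
      d <- ph$event_densities[[i]]
      k <- which.min(abs(d$grid - st$t[i]))
      if (d$p[k] <= 0) return(-Inf)
      lp <- lp + log(d$p[k])
    }
    s <- phase_span_exponent(model, j)
    lp <- lp + (s - n) * log(a - b)
  }
  if (model$ordered) {
    ord <- model$order
    for (k in seq_len(length(ord) - 1L)) {
      older <- state[[ord[k]]]; younger <- state[[ord[k + 1L]]]
      if (older$beta < younger$alpha) return(-Inf)
    }
  }
  lp
}

# Inverse-CDF draw of y = alpha - beta from f(y) proportional to y^c on
# [y0, y1].  Handles the ubiquitous c = -1 case (default span prior) and the
# general power law.
draw_span <- function(c, y0, y1, u) {
  eps <- 1e-9
  y0 <- max(y0, eps)
  if (y1 <= y0) return(y0)
  if (abs(c + 1) < 1e-12) {
    y0 * (y1 / y0)^u
  } else {
    k <- c + 1
    (y0^k + u * (y1^k - y0^k))^(1 / k)
  }
}

# Draw one event from its calibrated density restricted to [lo_age, hi_age].
# cdf is the cumulative mass along the ascending grid; returns the current
# value when the restricted support carries no mass.
draw_event <- function(grid, cdf, lo_age, hi_age, current) {
  g0 <- grid[1L]; res <- grid[2L] - grid[1L]; G <- length(grid)
  lo <- max(1L, as.integer(ceiling((lo_age - g0) / res - 1e-9)) + 1L)
  hi <- min(G, as.integer(floor((hi_age - g0) / res + 1e-9)) + 1L)
  if (lo > hi) return(current)
  Flo <- if (lo > 1L) cdf[lo - 1L] else 0
  Fhi <- cdf[hi]
  if (Fhi - Flo <= 0) return(current)
  u <- stats::runif(1L, Flo, Fhi)
  idx <- findInterval(u, cdf) + 1L
  grid[min(max(idx, lo), hi)]
}

#' Sample the posterior of a phase model by MCMC
#'
#' A Metropolis-within-Gibbs scheme in which every conditional is sampled
#' exactly (so every proposal is accepted): each event age is drawn by
#' inverse CDF from its calibrated density restricted to its phase's current
#' boundaries; each boundary is drawn by inverse CDF of its power-law
#' conditional under the span prior; and a predictive event age (the
#' expected value of a new date from the same pool, the `Date()` analogue)
#' is drawn uniformly within the boundaries at each kept iteration.
#'
#' @param model a [sequence_spec].
#' @param n_iter iterations per chain (post-initialization, including
#'   burn-in).
#' @param burn_in iterations discarded at the start of each chain.
#' @param thin keep every `thin`-th iteration after burn-in.
#' @param chains number of independent chains (>= 2).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return A `posterior_samples` object: `draws` is a named list of
#'   (kept iterations x chains) matrices with names `t[j,i]`, `pred[j]`,
#'   `alpha[j]`, `beta[j]`; `phases` maps phase index to analysis unit;
#'   convergence diagnostics are attached as `$diagnostics` with a
#'   `$convergence_warning` flag.
#' @export
sample_posterior <- function(model, n_iter = 25000L, burn_in = 5000L,
                             thin = 5L, chains = 2L, seed) {
  stopifnot(inherits(model, "sequence_spec"))
  if (missing(seed)) stop("a seed must be supplied for reproducibility")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (chains < 2L) stop("at least 2 chains are required for diagnostics")
  K <- length(model$phases)
  rng <- grid_range(model)
  nvec <- vapply(model$phases, function(p) length(p$event_densities), integer(1))
  cexp <- vapply(seq_len(K), function(j)
    phase_span_exponent(model, j) - nvec[j], numeric(1))
  # precompute per-event grids and CDFs
  dens <- lapply(model$phases, function(p)
    lapply(p$event_densities, function(d)
      list(grid = d$grid, cdf = cumsum(d$p))))
  res <- dens[[1L]][[1L]]$grid[2L] - dens[[1L]][[1L]]$grid[1L]
  # phase order bookkeeping: pos_in_seq[j] = rank of phase j oldest-first
  ord <- if (model$ordered) model$order else NULL

  kept_idx <- seq.int(burn_in + thin, n_iter, by = thin)
  n_kept <- length(kept_idx)
  qnames <- c(
    unlist(lapply(seq_len(K), function(j)
      sprintf("t[%d,%d]", j, seq_len(nvec[j])))),
    sprintf("pred[%d]", seq_len(K)),
    sprintf("alpha[%d]", seq_len(K)),
    sprintf("beta[%d]", seq_len(K))
  )
  draws <- lapply(qnames, function(q) matrix(NA_real_, n_kept, chains))
  names(draws) <- qnames

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    st <- initialize_state(model, dens, rng)
    t_cur <- st$t; a_cur <- st$alpha; b_cur <- st$beta
    kk <- 0L
    for (it in seq_len(n_iter)) {
      for (j in seq_len(K)) {
        # events
        for (i in seq_len(nvec[j])) {
          t_cur[[j]][i] <- draw_event(dens[[j]][[i]]$grid, dens[[j]][[i]]$cdf,
                                      b_cur[j], a_cur[j], t_cur[[j]][i])
        }
        tmax <- max(t_cur[[j]]); tmin <- min(t_cur[[j]])
        # ordering limits for this phase's boundaries
        upper <- rng[2L]; lower <- rng[1L]
        if (!is.null(ord)) {
          r <- match(j, ord)
          if (r > 1L) upper <- min(upper, b_cur[ord[r - 1L]])
          if (r < K) lower <- max(lower, a_cur[ord[r + 1L]])
        }
        # alpha | rest: f(alpha) prop (alpha - beta)^c on [tmax, upper].
        # The span is floored at one grid step (where the window allows):
        # with events on a grid and continuous boundaries, exponents
        # c <= -2 would otherwise make coincident-event states absorbing.
        y1 <- upper - b_cur[j]
        y0 <- max(tmax - b_cur[j], min(res, y1))
        y <- draw_span(cexp[j], y0, max(y1, y0), stats::runif(1L))
        a_cur[j] <- b_cur[j] + y
        # beta | rest: f(beta) prop (alpha - beta)^c on [lower, tmin]
        y1 <- a_cur[j] - lower
        y0 <- max(a_cur[j] - tmin, min(res, y1))
        y <- draw_span(cexp[j], y0, max(y1, y0), stats::runif(1L))
        b_cur[j] <- a_cur[j] - y
      }
      if (kk < n_kept && it == kept_idx[kk + 1L]) {
        kk <- kk + 1L
        for (j in seq_len(K)) {
          for (i in seq_len(nvec[j]))
            draws[[sprintf("t[%d,%d]", j, i)]][kk, ch] <- t_cur[[j]][i]
          draws[[sprintf("pred[%d]", j)]][kk, ch] <-
            stats::runif(1L, b_cur[j], a_cur[j])
          draws[[sprintf("alpha[%d]", j)]][kk, ch] <- a_cur[j]
          draws[[sprintf("beta[%d]", j)]][kk, ch] <- b_cur[j]
        }
      }
    }
  }

  out <- structure(
    list(draws = draws,
         phases = data.frame(
           phase = seq_len(K),
           analysis_unit_ref = vapply(model$phases, function(p)
             as.character(p$analysis_unit_ref), character(1)),
           n_dates = nvec,
           stringsAsFactors = FALSE),
         ordered = model$ordered, order = model$order,
         chains = chains, seed = as.integer(seed), n_kept = n_kept),
    class = "posterior_samples"
  )
  diag <- convergence_diagnostics(out)
  out$diagnostics <- diag
  out$convergence_warning <- any(diag$rhat > 1.05, na.rm = TRUE)
  if (out$convergence_warning)
    warning("split R-hat exceeds 1.05 for: ",
            paste(diag$quantity[diag$rhat > 1.05], collapse = ", "),
            "; increase n_iter")
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples: %d phase(s), %d chains x %d kept draws%s>\n",
              nrow(x$phases), x$chains, x$n_kept,
              if (isTRUE(x$convergence_warning)) " [CONVERGENCE WARNING]" else ""))
  invisible(x)
}

# Feasible initialization: events at calibrated medians, boundaries one grid
# step outside the phase extremes; ordered models are repaired by moving
# events into order-compatible windows when the medians conflict with the
# declared order.
initialize_state <- function(model, dens, rng) {
  K <- length(model$phases)
  t0 <- lapply(seq_len(K), function(j)
    vapply(model$phases[[j]]$event_densities, function(d)
      density_quantile(d, 0.5), numeric(1)))
  res <- dens[[1L]][[1L]]$grid[2L] - dens[[1L]][[1L]]$grid[1L]
  if (model$ordered && K > 1L) {
    ord <- model$order
    meds <- vapply(t0, stats::median, numeric(1))
    # cutpoints between adjacent phases in declared order
    cuts <- c(rng[2L], rep(NA_real_, K - 1L), rng[1L])
    sorted_meds <- sort(meds[ord], decreasing = TRUE)
    for (k in seq_len(K - 1L)) cuts[k + 1L] <- mean(sorted_meds[k:(k + 1L)])
    for (k in seq_len(K)) {
      j <- ord[k]
      hi <- cuts[k]; lo <- cuts[k + 1L]
      for (i in seq_along(t0[[j]])) {
        if (t0[[j]][i] > hi - res || t0[[j]][i] < lo + res) {
          t0[[j]][i] <- draw_event(dens[[j]][[i]]$grid, dens[[j]][[i]]$cdf,
                                   lo + res, hi - res, NA_real_)
          if (is.na(t0[[j]][i]))
            stop("cannot initialize ordered model: no calibrated mass for an ",
                 "event in phase ", j, " within its order-compatible window")
        }
      }
    }
    alpha <- beta <- numeric(K)
    for (k in seq_len(K)) {
      j <- ord[k]
      alpha[j] <- min(max(t0[[j]]) + res / 2, cuts[k])
      beta[j] <- max(min(t0[[j]]) - res / 2, cuts[k + 1L])
    }
  } else {
    alpha <- vapply(t0, function(t) min(max(t) + res, rng[2L]), numeric(1))
    beta <- vapply(t0, function(t) max(min(t) - res, rng[1L]), numeric(1))
  }
  st <- list(t = t0, alpha = alpha, beta = beta)
  state_list <- lapply(seq_len(K), function(j)
    list(t = t0[[j]], alpha = alpha[j], beta = beta[j]))
  if (!is.finite(log_posterior_density_init_check(model, state_list)))
    stop("infeasible initialization for the phase model")
  st
}

# containment/ordering feasibility only (ignores zero-mass grid cells, which
# draw_event never visits)
log_posterior_density_init_check <- function(model, state) {
  rng <- grid_range(model)
  for (j in seq_along(model$phases)) {
    st <- state[[j]]
    if (!(st$alpha > st$beta) || st$alpha > rng[2L] || st$beta < rng[1L]) return(-Inf)
    if (any(st$t < st$beta) || any(st$t > st$alpha)) return(-Inf)
  }
  if (model$ordered) {
    ord <- model$order
    for (k in seq_len(length(ord) - 1L))
      if (state[[ord[k]]]$beta < state[[ord[k + 1L]]]$alpha) return(-Inf)
  }
  0
}

#' Convergence diagnostics for posterior samples
#'
#' Split-chain potential scale reduction (split R-hat) and effective sample
#' size via the initial-positive-sequence autocorrelation sum, computed per
#' monitored quantity.  A flag is set when any split R-hat exceeds 1.05.
#'
#' @param samples a `posterior_samples` object.
#' @return A `data.frame` with columns `quantity`, `rhat`, `ess`, plus an
#'   attribute `flag` (any R-hat > 1.05).
#' @export
convergence_diagnostics <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (samples$chains < 2L) stop("diagnostics need at least 2 chains")
  res <- do.call(rbind, lapply(names(samples$draws), function(q) {
    m <- samples$draws[[q]]
    data.frame(quantity = q, rhat = split_rhat(m), ess = ess_acf(m),
               stringsAsFactors = FALSE)
  }))
  attr(res, "flag") <- any(res$rhat > 1.05, na.rm = TRUE)
  res
}

split_rhat <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  splits <- cbind(m[seq_len(half), , drop = FALSE],
                  m[(n - half + 1L):n, , drop = FALSE])
  mns <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (!is.finite(W) || W <= 0) {
    if (is.finite(B) && B > 0) return(Inf)
    return(1)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

ess_acf <- function(m, max_lag = NULL) {
  n <- nrow(m); chains <- ncol(m)
  N <- n * chains
  if (is.null(max_lag)) max_lag <- min(n - 1L, 1000L)
  v <- mean(apply(m, 2L, stats::var))
  if (!is.finite(v) || v <= 0) return(NA_real_)
  # chain-averaged autocorrelation
  rho <- rowMeans(vapply(seq_len(chains), function(ch) {
    a <- stats::acf(m[, ch], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
    a[-1L]
  }, numeric(max_lag)))
  # Geyer initial positive sequence on paired sums
  npair <- length(rho) %/% 2L
  s <- 0
  for (k in seq_len(npair)) {
    pair <- rho[2L * k - 1L] + rho[2L * k]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  ess <- N / (1 + 2 * s)
  min(ess, N)
}

# q-from-old quantile of a vector of age draws: the age a such that a
# fraction q of the draws is older (>= a).
draw_quantile_from_old <- function(x, q_from_old) {
  round(as.numeric(stats::quantile(x, probs = 1 - q_from_old, names = FALSE,
                                   type = 7)))
}
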