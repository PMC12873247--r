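#' Stratigraphic age inference for undated analysis units
#'
#' An analysis unit without usable dates can still be assigned an age range
#' when its stratigraphic relationship to dated units is known.  Five
#' deterministic rules are applied, keyed by the relation of the undated
#' unit to the dated ones; superposition maps the *top* of a unit to its
#' younger age limit and its *bottom* to its older limit.
#'
#' * rule a — subset of a dated unit (e.g. one undated specimen from a dated
#'   stratum): copy that unit's range.
#' * rule b — bounded above and below by dated units: older limit from the
#'   top (younger limit) of the next dated unit below, younger limit from
#'   the bottom (older limit) of the next dated unit above.
#' * rule b1 — as b, but the two dated ranges overlap: time-averaging is
#'   assumed and the undated unit takes the full combined range (older limit
#'   of the unit below to younger limit of the unit above).
#' * rule c — above all dated units: older limit from the top of the next
#'   dated unit below; younger limit 0 (the radiocarbon "year zero",
#'   1950 CE) unless an external constraint tightens it.
#' * rule d — below all dated units: younger limit from the bottom of the
#'   next dated unit above; older limit from an external biostratigraphic or
#'   archeological constraint, else left undefined with a warning.
#' * rule e — no apparent stratigraphic relationship: the full age range of
#'   all dated units in the collection.
#'
#' No central age is ever estimated for an undated unit (rule f).
#'
#' @name strat_inference
NULL

#' Stratigraphic context of an undated analysis unit
#'
#' @param relation one of `"subset_of_dated"`, `"bounded_between"`,
#'   `"above_all_dated"`, `"below_all_dated"`, `"unrelated"`.
#' @param containing sample age (one-row data.frame) of the dated unit the
#'   undated unit is a subset of; required for `subset_of_dated`.
#' @param neighbor_below sample age of the next dated unit below (older
#'   side), where required.
#' @param neighbor_above sample age of the next dated unit above (younger
#'   side), where required.
#' @param external_older_constraint external older age limit (cal BP) for
#'   rule d, or `NA`.
#' @param external_younger_constraint external younger age limit (cal BP)
#'   for rule c, or `NA` (rule c then floors at 0).
#' @return A `strat_context` object.
#' @export
strat_context <- function(relation = c("subset_of_dated", "bounded_between",
                                       "above_all_dated", "below_all_dated",
                                       "unrelated"),
                          containing = NULL, neighbor_below = NULL,
                          neighbor_above = NULL,
                          external_older_constraint = NA_real_,
                          external_younger_constraint = NA_real_) {
  relation <- match.arg(relation)
  need <- switch(relation,
    subset_of_dated = !is.null(containing),
    bounded_between = !is.null(neighbor_below) && !is.null(neighbor_above),
    above_all_dated = !is.null(neighbor_below),
    below_all_dated = !is.null(neighbor_above),
    unrelated = TRUE)
  if (!need) stop("relation '", relation, "' is missing its required neighbor(s)")
  structure(
    list(relation = relation, containing = containing,
         neighbor_below = neighbor_below, neighbor_above = neighbor_above,
         external_older_constraint = external_older_constraint,
         external_younger_constraint = external_younger_constraint),
    class = "strat_context"
  )
}

#' Classify an undated analysis unit's stratigraphic relation
#'
#' Uses, in order of precedence: an explicit `subset_of` link on the unit;
#' numeric depths shared with the dated units (deeper = older); the
#' collection's declared order.  Units with none of these are `unrelated`.
#'
#' @param undated an [analysis_unit] with no usable dates.
#' @param cu the containing [collection_unit].
#' @param dated_sample_ages `data.frame` of sample ages for the dated units
#'   (from [event_sample_ages()] or [bounds_sample_ages()]).
#' @return A [strat_context].
#' @export
classify_undated_unit <- function(undated, cu, dated_sample_ages) {
  stopifnot(inherits(cu, "collection_unit"))
  dated_ids <- dated_sample_ages$analysis_unit_ref
  sa_of <- function(id) dated_sample_ages[dated_sample_ages$analysis_unit_ref ==
                                            as.character(id), , drop = FALSE]
  ext_old <- if (is.null(undated$older_constraint)) NA_real_ else
    as.numeric(undated$older_constraint)
  ext_young <- if (is.null(undated$younger_constraint)) NA_real_ else
    as.numeric(undated$younger_constraint)

  if (!is.null(undated$subset_of) && as.character(undated$subset_of) %in% dated_ids)
    return(strat_context("subset_of_dated", containing = sa_of(undated$subset_of),
                         external_older_constraint = ext_old,
                         external_younger_constraint = ext_young))

  ids <- vapply(cu$analysis_units, function(a) as.character(a$id), character(1))
  depth_of <- function(id) {
    a <- cu$analysis_units[[match(as.character(id), ids)]]
    if (is.null(a$depth)) NA_real_ else as.numeric(a$depth)
  }
  d0 <- if (is.null(undated$depth)) NA_real_ else as.numeric(undated$depth)
  dated_depths <- vapply(dated_ids, depth_of, numeric(1))

  # position index on a common axis: by depth if available, else by the
  # declared order (earlier in declared order = older = "below")
  if (!is.na(d0) && !anyNA(dated_depths) && !any(dated_depths == d0)) {
    below <- dated_ids[dated_depths > d0]   # deeper = older
    above <- dated_ids[dated_depths < d0]
    nb <- if (length(below)) sa_of(below[which.min(dated_depths[dated_depths > d0])]) else NULL
    na_ <- if (length(above)) sa_of(above[which.max(dated_depths[dated_depths < d0])]) else NULL
  } else if (!is.null(cu$declared_order) &&
             as.character(undated$id) %in% as.character(cu$declared_order) &&
             all(dated_ids %in% as.character(cu$declared_order))) {
    decl <- as.character(cu$declared_order)   # oldest first
    p0 <- match(as.character(undated$id), decl)
    pd <- match(dated_ids, decl)
    below_p <- pd[pd < p0]; above_p <- pd[pd > p0]
    nb <- if (length(below_p)) sa_of(decl[max(below_p)]) else NULL
    na_ <- if (length(above_p)) sa_of(decl[min(above_p)]) else NULL
  } else {
    return(strat_context("unrelated",
                         external_older_constraint = ext_old,
                         external_younger_constraint = ext_young))
  }
  relation <- if (!is.null(nb) && !is.null(na_)) "bounded_between"
              else if (!is.null(nb)) "above_all_dated"
              else if (!is.null(na_)) "below_all_dated"
              else "unrelated"
  strat_context(relation, neighbor_below = nb, neighbor_above = na_,
                external_older_constraint = ext_old,
                external_younger_constraint = ext_young)
}

#' Infer the age range of an undated analysis unit
#'
#' Applies rules a, b, b1, c, d, e (see [strat_inference]) to a classified
#' stratigraphic context.  The result never carries a central age.
#'
#' @param ctx a [strat_context].
#' @param dated_sample_ages `data.frame` of the collection's dated sample
#'   ages (used by rule e and for the chronology kind).
#' @param analysis_unit_ref id of the undated unit, stamped on the result.
#' @param rule_d_cap optional older-limit cap (cal BP) used when rule d has
#'   no external constraint; default `NA` leaves the older limit undefined.
#' @return A one-row sample-age `data.frame` with `provenance` recording the
#'   rule used.
#' @export
infer_undated_range <- function(ctx, dated_sample_ages, analysis_unit_ref,
                                rule_d_cap = NA_real_) {
  stopifnot(inherits(ctx, "strat_context"))
  if (is.null(dated_sample_ages) || nrow(dated_sample_ages) == 0L)
    stop("cannot infer an undated range without any dated sample ages")
  kind <- dated_sample_ages$chronology_kind[1L]
  mk <- function(older, younger, rule)
    new_sample_age(analysis_unit_ref, kind, NA_real_, older, younger, rule)

  switch(ctx$relation,
    subset_of_dated = mk(ctx$containing$agelimitolder,
                         ctx$containing$agelimityounger, "rule_a"),
    bounded_between = {
      below <- ctx$neighbor_below; above <- ctx$neighbor_above
      overlap <- below$agelimityounger <= above$agelimitolder &&
                 above$agelimityounger <= below$agelimitolder
      if (overlap)
        mk(below$agelimitolder, above$agelimityounger, "rule_b1")
      else
        mk(below$agelimityounger, above$agelimitolder, "rule_b")
    },
    above_all_dated = {
      younger <- if (!is.na(ctx$external_younger_constraint))
        ctx$external_younger_constraint else 0
      mk(ctx$neighbor_below$agelimityounger, younger, "rule_c")
    },
    below_all_dated = {
      older <- ctx$external_older_constraint
      if (is.na(older)) {
        older <- rule_d_cap
        if (is.na(older))
          warning("undated unit ", analysis_unit_ref, " lies below all dated ",
                  "units with no external older constraint; older limit ",
                  "left undefined")
      }
      mk(older, ctx$neighbor_above$agelimitolder, "rule_d")
    },
    unrelated = mk(max(dated_sample_ages$agelimitolder, na.rm = TRUE),
                   min(dated_sample_ages$agelimityounger, na.rm = TRUE),
                   "rule_e")
  )
}

# classify + infer for every undated unit of a collection
infer_undated_sample_ages <- function(cu, dated_sample_ages, kind,
                                      rule_d_cap = NA_real_) {
  undated <- Filter(function(a) length(a$dates) == 0L, cu$analysis_units)
  if (length(undated) == 0L) return(dated_sample_ages[0, , drop = FALSE])
  do.call(rbind, lapply(undated, function(a) {
    ctx <- classify_undated_unit(a, cu, dated_sample_ages)
    infer_undated_range(ctx, dated_sample_ages, a$id, rule_d_cap = rule_d_cap)
  }))
}
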