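#' Reading collections, filtering dates, and writing chronology tables
#'
#' Collection-unit records are read either from local JSON fixtures (the
#' bundled format mirrors the relevant Neotoma tables: a collection unit
#' holds analysis units, which hold geochronological dates) or, when a
#' network is available, from the Neotoma API.  The date filters reproduce
#' the selection used for chronology construction: single-sided and modern
#' dates, dates with missing or zero errors, author-rejected dates, and
#' dates from human remains are excluded before modeling.
#'
#' @name neotoma_io
NULL

#' Construct an analysis unit
#'
#' @param id unique identifier within the collection unit.
#' @param name display name.
#' @param dates list of [geochron_date] objects (possibly empty).
#' @param depth optional depth in meters (>= 0).
#' @param subset_of optional id of the analysis unit this unit is a subset
#'   of (e.g. a single specimen drawn from a dated stratum).
#' @param older_constraint,younger_constraint optional external age limits
#'   (cal BP) from biostratigraphic or archeological evidence.
#' @return An `analysis_unit` object.
#' @export
analysis_unit <- function(id, name = as.character(id), dates = list(),
                          depth = NULL, subset_of = NULL,
                          older_constraint = NULL, younger_constraint = NULL) {
  if (!is.null(depth) && (is.na(depth) || depth < 0))
    stop("analysis unit depth must be >= 0 when present")
  stopifnot(all(vapply(dates, inherits, logical(1), "geochron_date")))
  structure(
    list(id = id, name = name, depth = depth, dates = dates,
         subset_of = subset_of, older_constraint = older_constraint,
         younger_constraint = younger_constraint),
    class = "analysis_unit"
  )
}

#' Construct a collection unit
#'
#' @param id unique identifier.
#' @param analysis_units list of [analysis_unit] objects with unique ids.
#' @param site_ref site identifier or name.
#' @param declared_order optional vector of analysis-unit ids giving an
#'   explicit stratigraphic order, oldest first.
#' @return A `collection_unit` object.
#' @export
collection_unit <- function(id, analysis_units, site_ref = NA,
                            declared_order = NULL) {
  stopifnot(all(vapply(analysis_units, inherits, logical(1), "analysis_unit")))
  ids <- vapply(analysis_units, function(a) as.character(a$id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate analysis-unit ids in collection unit ", id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(
    list(id = id, site_ref = site_ref, analysis_units = analysis_units,
         declared_order = declared_order),
    class = "collection_unit"
  )
}

#' @export
print.collection_unit <- function(x, ...) {
  nd <- sum(vapply(x$analysis_units, function(a) length(a$dates), integer(1)))
  cat(sprintf("<collection_unit %s (site %s): %d analysis units, %d dates>\n",
              x$id, x$site_ref, length(x$analysis_units), nd))
  invisible(x)
}

date_from_record <- function(rec) {
  geochron_date(
    age = rec$age,
    error_minus = if (!is.null(rec$error_minus)) rec$error_minus else rec$error,
    error_plus = if (!is.null(rec$error_plus)) rec$error_plus
                 else if (!is.null(rec$error_minus)) rec$error_minus else rec$error,
    kind = if (!is.null(rec$kind)) rec$kind else "radiocarbon",
    lab_id = if (!is.null(rec$lab_id)) rec$lab_id else NA_character_,
    material = if (!is.null(rec$material)) rec$material else NA_character_,
    method = if (!is.null(rec$method)) rec$method else NA_character_,
    rejected = isTRUE(rec$rejected),
    human_remains = isTRUE(rec$human_remains),
    single_sided = isTRUE(rec$single_sided)
  )
}

#' Read a collection unit from a local fixture or the Neotoma API
#'
#' Local sources are JSON files (or already-parsed lists) with a
#' `collectionunit` object holding `id`, optional `site`, optional
#' `declared_order`, and `analysis_units`, each with `id`, optional `name`,
#' `depth`, `subset_of`, and a `dates` array of geochronological records.
#' An API locator is either a `list(siteid = )` or an `https://` URL; API
#' responses are cached to `cache_dir` so repeated reads need no network.
#'
#' @param source file path, URL, parsed list, or `list(siteid = )` locator.
#' @param cache_dir directory for cached API responses.
#' @return A [collection_unit] (or a list of them when the source holds
#'   several).
#' @export
read_collection <- function(source, cache_dir = tempdir()) {
  if (is.list(source) && !is.null(source$siteid))
    return(read_collection_api(source$siteid, cache_dir))
  if (is.character(source) && length(source) == 1L && grepl("^https?://", source))
    return(collection_from_json(fetch_json_cached(source, cache_dir)))
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("collection source not found: ", source)
    return(collection_from_json(jsonlite::fromJSON(source, simplifyVector = FALSE)))
  }
  if (is.list(source)) return(collection_from_json(source))
  stop("unrecognized collection source")
}

collection_from_json <- function(x) {
  if (!is.null(x$collectionunit)) x <- x$collectionunit
  if (is.null(x$id) || is.null(x$analysis_units))
    stop("malformed collection record: required fields 'id' and ",
         "'analysis_units' missing or empty")
  aus <- lapply(x$analysis_units, function(a) {
    if (is.null(a$id)) stop("malformed analysis unit: field 'id' missing")
    dates <- lapply(if (is.null(a$dates)) list() else a$dates, date_from_record)
    analysis_unit(
      id = a$id,
      name = if (!is.null(a$name)) a$name else as.character(a$id),
      dates = dates,
      depth = a$depth,
      subset_of = a$subset_of,
      older_constraint = a$older_constraint,
      younger_constraint = a$younger_constraint
    )
  })
  collection_unit(x$id, aus,
                  site_ref = if (!is.null(x$site)) x$site else NA,
                  declared_order = if (!is.null(x$declared_order))
                    unlist(x$declared_order) else NULL)
}

fetch_json_cached <- function(url, cache_dir) {
  key <- file.path(cache_dir, paste0("neochron-", substr(digest_hex(url), 1, 16),
                                     ".json"))
  if (file.exists(key)) return(jsonlite::fromJSON(key, simplifyVector = FALSE))
  res <- jsonlite::fromJSON(url, simplifyVector = FALSE)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(res, auto_unbox = TRUE), key)
  res
}

# small stable hex digest (sum-based; only used for cache file names)
digest_hex <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2^31
  sprintf("%08x%08x", h, sum(v) %% 2^31)
}

# Map the Neotoma v2.0 sites/{id} response (with geochronologic datasets)
# to collection units.  Requires network; responses are cached.
read_collection_api <- function(siteid, cache_dir = tempdir()) {
  url <- sprintf("https://api.neotomadb.org/v2.0/data/sites/%s/datasets_elc",
                 siteid)
  res <- tryCatch(fetch_json_cached(url, cache_dir),
                  error = function(e)
                    stop("Neotoma API fetch failed for siteid ", siteid, ": ",
                         conditionMessage(e), call. = FALSE))
  sites <- res$data
  if (is.null(sites) || length(sites) == 0L)
    stop("Neotoma API returned no data for siteid ", siteid)
  cus <- list()
  for (site in sites) {
    for (cu in site$site$collectionunits) {
      aus_map <- list()
      for (ds in cu$datasets) {
        if (!identical(ds$datasettype, "geochronologic")) next
        for (smp in ds$samples) {
          auid <- as.character(smp$analysisunitid)
          recs <- lapply(smp$geochrons, function(g) {
            list(lab_id = g$labnumber, age = g$age, error = g$errorolder,
                 error_minus = g$erroryounger, error_plus = g$errorolder,
                 kind = "radiocarbon",
                 material = g$materialdated,
                 rejected = isTRUE(g$infinite))
          })
          if (is.null(aus_map[[auid]]))
            aus_map[[auid]] <- list(id = auid, dates = list())
          aus_map[[auid]]$dates <- c(aus_map[[auid]]$dates, recs)
        }
      }
      if (length(aus_map) == 0L) next
      cus[[length(cus) + 1L]] <- collection_from_json(
        list(id = cu$collectionunitid, site = site$site$sitename,
             analysis_units = unname(aus_map)))
    }
  }
  if (length(cus) == 0L) stop("no geochronologic collection units for siteid ", siteid)
  if (length(cus) == 1L) cus[[1L]] else cus
}

#' Filter geochronological dates for chronology construction
#'
#' Excludes, with one primary reason code each (checked in this order):
#' `single_sided` (one-sided limits such as ">31,500"), `modern` (stored age
#' <= 10), `zero_error` (missing or zero error values), `rejected` (age
#' estimate rejected by the original author), `human_remains`.  Optionally,
#' free-text scanning of the material/method fields for rejection or
#' human-remains keywords can be switched on.
#'
#' @param dates list of [geochron_date] objects.
#' @param keyword_scan also flag dates whose `material`/`method` text
#'   contains "reject" or "human" (off by default).
#' @return List with `usable` (list of dates), `excluded` (list of dates),
#'   and `reasons` (character vector parallel to `excluded`).
#' @export
filter_geochron_dates <- function(dates, keyword_scan = FALSE) {
  reason_of <- function(d) {
    txt <- tolower(paste(d$material, d$method, collapse = " "))
    if (isTRUE(d$single_sided)) return("single_sided")
    if (!is.na(d$age) && d$age <= 10) return("modern")
    if (is.na(d$error_minus) || is.na(d$error_plus) ||
        d$error_minus == 0 || d$error_plus == 0) return("zero_error")
    if (isTRUE(d$rejected) || (keyword_scan && grepl("reject", txt)))
      return("rejected")
    if (isTRUE(d$human_remains) || (keyword_scan && grepl("human", txt)))
      return("human_remains")
    NA_character_
  }
  reasons <- vapply(dates, reason_of, character(1))
  list(usable = dates[is.na(reasons)],
       excluded = dates[!is.na(reasons)],
       reasons = reasons[!is.na(reasons)])
}

# apply the date filter to every analysis unit of a collection
filter_collection_dates <- function(cu, keyword_scan = FALSE) {
  stopifnot(inherits(cu, "collection_unit"))
  excluded <- list()
  aus <- lapply(cu$analysis_units, function(a) {
    f <- filter_geochron_dates(a$dates, keyword_scan = keyword_scan)
    if (length(f$excluded) > 0L)
      excluded[[as.character(a$id)]] <<- data.frame(
        analysis_unit_ref = as.character(a$id),
        labnumber = vapply(f$excluded, function(d) as.character(d$lab_id),
                           character(1)),
        reason = f$reasons, stringsAsFactors = FALSE)
    a$dates <- f$usable
    a
  })
  list(collection = collection_unit(cu$id, aus, site_ref = cu$site_ref,
                                    declared_order = cu$declared_order),
       excluded = if (length(excluded)) do.call(rbind, unname(excluded))
                  else data.frame(analysis_unit_ref = character(0),
                                  labnumber = character(0),
                                  reason = character(0)))
}

#' Is a collection unit eligible for chronology construction?
#'
#' Eligible collections have, after filtering, at least one usable
#' uncalibrated radiocarbon date whose minimum (younger) one-sigma age
#' estimate (age minus error) is less than 30,000 14C BP.  Collections
#' whose only dates are calendar-scale are ineligible.
#'
#' @param cu a [collection_unit] whose dates have already been filtered.
#' @return List with `eligible` (flag) and `reason` (text when ineligible).
#' @export
select_collection <- function(cu) {
  stopifnot(inherits(cu, "collection_unit"))
  dates <- unlist(lapply(cu$analysis_units, function(a) a$dates),
                  recursive = FALSE)
  rc <- Filter(function(d) d$kind == "radiocarbon", dates)
  if (length(rc) == 0L)
    return(list(eligible = FALSE, reason = "no usable radiocarbon dates"))
  ok <- any(vapply(rc, function(d) (d$age - d$error_minus) < 30000, logical(1)))
  if (!ok)
    return(list(eligible = FALSE,
                reason = "no radiocarbon date with younger 1-sigma limit < 30,000 14C BP"))
  list(eligible = TRUE, reason = NA_character_)
}

#' Write chronology, sample-age, and chron-control tables
#'
#' Emits the three-table relational layout used by the Neotoma schema as
#' CSV: `chronologies.csv`, `sampleages.csv`, `chroncontrols.csv`, with
#' monotonically assigned temporary ids.  [read_chronology_tables()] reads
#' them back.
#'
#' @param chronologies list of `chronology` objects (see
#'   [build_chronologies()]).
#' @param dest destination directory (created if missing).
#' @return Invisibly, the named list of the three data frames written.
#' @export
write_chronology_tables <- function(chronologies, dest) {
  stopifnot(all(vapply(chronologies, inherits, logical(1), "chronology")))
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  chron_rows <- list(); sa_rows <- list(); cc_rows <- list()
  sa_id <- 0L; cc_id <- 0L
  for (k in seq_along(chronologies)) {
    ch <- chronologies[[k]]
    chron_rows[[k]] <- data.frame(
      chronologyid = k,
      collectionunitid = as.character(ch$collectionunit_ref),
      chronologyname = ch$name,
      agemodel = ch$agemodel,
      ageboundolder = ch$ageboundolder,
      ageboundyounger = ch$ageboundyounger,
      dateprepared = ch$date_prepared,
      stringsAsFactors = FALSE)
    sa <- ch$sample_ages
    sa_rows[[k]] <- data.frame(
      sampleageid = sa_id + seq_len(nrow(sa)),
      chronologyid = k,
      analysisunitid = sa$analysis_unit_ref,
      agemodel = sa$chronology_kind,
      age = sa$age,
      ageolder = sa$agelimitolder,
      ageyounger = sa$agelimityounger,
      provenance = sa$provenance,
      stringsAsFactors = FALSE)
    sa_id <- sa_id + nrow(sa)
    if (!is.null(ch$controls) && nrow(ch$controls) > 0L) {
      cc <- ch$controls
      cc_rows[[length(cc_rows) + 1L]] <- data.frame(
        chroncontrolid = cc_id + seq_len(nrow(cc)),
        chronologyid = k,
        analysisunitid = cc$analysis_unit_ref,
        labnumber = cc$labnumber,
        age = cc$age,
        agelimitolder = cc$agelimitolder,
        agelimityounger = cc$agelimityounger,
        controltype = cc$control_type,
        stringsAsFactors = FALSE)
      cc_id <- cc_id + nrow(cc)
    }
  }
  tabs <- list(
    chronologies = do.call(rbind, chron_rows),
    sampleages = do.call(rbind, sa_rows),
    chroncontrols = if (length(cc_rows)) do.call(rbind, cc_rows)
                    else data.frame()
  )
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(dest, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(tabs)
}

#' @rdname write_chronology_tables
#' @param src directory holding the three CSV files.
#' @export
read_chronology_tables <- function(src) {
  out <- lapply(c(chronologies = "chronologies", sampleages = "sampleages",
                  chroncontrols = "chroncontrols"), function(nm) {
    f <- file.path(src, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f)
    tab <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (col in intersect(c("collectionunitid", "analysisunitid"), names(tab)))
      tab[[col]] <- as.character(tab[[col]])
    tab
  })
  out
}

#' Emit an OxCal v4.4 script for a collection unit
#'
#' Generates the Phase/Boundary/Sequence construction used for the phase
#' model: each dated analysis unit becomes a `Phase()` holding one
#' `R_Date()` per radiocarbon date (or `C_Date()` for calendar-scale
#' dates) plus a `Date()` call for the predictive event, flanked by two
#' `Boundary()` calls; ordered collections wrap the phases, oldest to
#' youngest, in a `Sequence()`.  Asymmetric errors are emitted with the
#' mean of the two sides (OxCal's date calls take a single error).
#'
#' @param cu a [collection_unit] (filtered to usable dates).
#' @param ordered override the inferred ordering flag; default infers via
#'   [infer_order()].
#' @return A single string of OxCal code.
#' @export
emit_oxcal_script <- function(cu, ordered = NULL) {
  stopifnot(inherits(cu, "collection_unit"))
  dated <- Filter(function(a) length(a$dates) > 0, cu$analysis_units)
  if (length(dated) == 0L) stop("no dated analysis units to emit")
  ord <- infer_order(cu)
  if (is.null(ordered)) ordered <- ord$ordered
  idx <- if (ordered && !is.null(ord$order)) ord$order else seq_along(dated)
  phase_block <- function(a, indent) {
    pad <- strrep(" ", indent)
    lines <- c(
      sprintf('%sBoundary("start %s");', pad, a$name),
      sprintf('%sPhase("%s")', pad, a$name),
      sprintf("%s{", pad))
    for (d in a$dates) {
      err <- round(mean(c(d$error_minus, d$error_plus)))
      lab <- if (is.na(d$lab_id)) "" else d$lab_id
      call <- if (d$kind == "radiocarbon") "R_Date" else "C_Date"
      age <- if (d$kind == "radiocarbon") round(d$age)
             else round(1950 - d$age)  # C_Date takes a calendar year
      lines <- c(lines, sprintf('%s  %s("%s",%d,%d);', pad, call, lab, age, err))
    }
    lines <- c(lines,
               sprintf('%s  Date("event %s");', pad, a$name),
               sprintf("%s};", pad),
               sprintf('%sBoundary("end %s");', pad, a$name))
    lines
  }
  body <- unlist(lapply(dated[idx], phase_block,
                        indent = if (ordered) 4L else 2L))
  lines <- c("Plot()", "{")
  if (ordered) {
    lines <- c(lines,
               sprintf('  Sequence("CU %s")', cu$id), "  {",
               body, "  };")
  } else {
    lines <- c(lines, body)
  }
  lines <- c(lines, "};")
  paste(lines, collapse = "\n")
}
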