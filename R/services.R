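#' Care types and quality domains
#'
#' The four types of supported accommodation distinguished in the analysis,
#' and the QuIRC-SA quality-of-care domains each carries. Residential care
#' (move-on and non-move-on oriented) and supported housing services are
#' rated on seven domains; floating outreach services, which have no
#' communal premises, lack the living-environment domain and carry six.
#'
#' @return `care_types()` returns the four care-type codes.
#'   `quirc_domains(care_type)` returns the domain names for one care type.
#' @param care_type one of `care_types()`.
#' @export
care_types <- function() {
  c("residential_move_on", "residential_non_move_on",
    "supported_housing", "floating_outreach")
}

#' @rdname care_types
#' @export
quirc_domains <- function(care_type) {
  care_type <- match.arg(care_type, care_types())
  d <- c("living_environment", "therapeutic_environment",
         "treatments_interventions", "self_management_autonomy",
         "social_interface", "human_rights", "recovery_practice")
  if (care_type == "floating_outreach") d <- setdiff(d, "living_environment")
  d
}

# raw (non-quirc) columns every service table must carry
service_columns <- function() {
  c("service_id", "care_type", "places", "staff_fte_per_user",
    "annual_budget", "length_of_stay", "occupied_places", "movers_2yr")
}

quirc_cols <- function(care_type) paste0("quirc_", quirc_domains(care_type))

#' Validate a table of service records
#'
#' Checks column presence, value signs, the occupancy invariant
#' (`occupied_places <= places`), quality-score bounds, and the care-type
#' specific domain sets (floating outreach must not carry a
#' living-environment score). `NA` is allowed in numeric fields (to be
#' filled by [impute_missing()]); structural fields (`service_id`,
#' `care_type`, `places`) must be complete.
#'
#' @param services a data frame of service records.
#' @param cap_occupancy if `TRUE`, rows with `occupied_places > places` are
#'   capped at full occupancy with a warning instead of raising an error.
#' @return the validated (possibly capped) data frame, with an
#'   `outlier_flag` column added if absent, classed `"service_table"`.
#' @export
validate_services <- function(services, cap_occupancy = FALSE) {
  services <- as.data.frame(services)
  missing_cols <- setdiff(service_columns(), names(services))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(services$care_type %in% care_types()))
    stop("unknown care_type value(s): ",
         paste(unique(setdiff(services$care_type, care_types())), collapse = ", "))
  if (anyNA(services$service_id) || anyNA(services$care_type) ||
      anyNA(services$places))
    stop("service_id, care_type and places must be complete")
  if (!("outlier_flag" %in% names(services))) services$outlier_flag <- FALSE
  services$outlier_flag <- as.logical(services$outlier_flag)

  num_fields <- setdiff(service_columns(), c("service_id", "care_type"))
  for (f in num_fields) {
    bad <- which(!is.na(services[[f]]) & services[[f]] < 0)
    if (length(bad))
      stop(sprintf("negative value in field '%s' at row %d", f, bad[1]))
  }
  if (any(!is.na(services$places) & services$places <= 0))
    stop("places must be a positive count")

  over <- which(!is.na(services$occupied_places) &
                  services$occupied_places > services$places)
  if (length(over)) {
    if (cap_occupancy) {
      warning(sprintf("occupied_places capped at places for %d row(s)",
                      length(over)))
      services$occupied_places[over] <- services$places[over]
    } else {
      stop(sprintf("occupied_places exceeds places at row %d (service %s)",
                   over[1], services$service_id[over[1]]))
    }
  }

  for (ct in unique(services$care_type)) {
    rows <- services$care_type == ct
    need <- quirc_cols(ct)
    missing_q <- setdiff(need, names(services))
    if (length(missing_q))
      stop(sprintf("care type %s requires quality column(s): %s",
                   ct, paste(missing_q, collapse = ", ")))
    if (ct == "floating_outreach" && "quirc_living_environment" %in% names(services)) {
      if (any(!is.na(services$quirc_living_environment[rows])))
        stop("floating outreach services must not carry a living_environment score")
    }
    for (qc in need) {
      v <- services[[qc]][rows]
      if (any(!is.na(v) & (v < 0 | v > 100)))
        stop(sprintf("quality score out of [0,100] in %s for care type %s", qc, ct))
    }
  }
  class(services) <- unique(c("service_table", class(services)))
  services
}

#' Read and write service tables
#'
#' Service records are kept as flat CSV, one row per service, with the raw
#' resource and outcome variables plus one `quirc_<domain>` column per
#' quality domain. An optional `outlier_flag` column (logical) marks
#' services the analyst regards as outliers; flagged rows are retained but
#' can be dropped at load time.
#'
#' @param path file path of the CSV table.
#' @param care_type optional filter; keep only this care type.
#' @param drop_outliers drop rows with `outlier_flag = TRUE`.
#' @param cap_occupancy passed to [validate_services()].
#' @return `read_services()` returns a validated `"service_table"` data
#'   frame; `write_services()` invisibly returns `path`.
#' @export
read_services <- function(path, care_type = NULL, drop_outliers = FALSE,
                          cap_occupancy = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- validate_services(df, cap_occupancy = cap_occupancy)
  if (!is.null(care_type)) {
    care_type <- match.arg(care_type, care_types())
    df <- df[df$care_type == care_type, , drop = FALSE]
  }
  if (drop_outliers) df <- df[!df$outlier_flag, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_services
#' @param services a service table.
#' @export
write_services <- function(services, path) {
  write.csv(as.data.frame(services), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive DEA-ready rate variables from raw service records
#'
#' Converts raw records into the comparable rates used in the efficiency
#' assessment, removing the size effect: budget per place (GBP/year),
#' places, staff FTE per user, mean length of stay (years), occupancy (%),
#' movers to more independent accommodation per place, and the size-scaled
#' quality score for each domain (`domain score x places / 100`, so a score
#' of 90 weighs more in a 100-place service than in a 10-place one).
#'
#' @param services a validated service table (see [validate_services()]).
#' @return a data frame with columns `service_id`, `care_type`,
#'   `budget_per_place`, `places`, `staff_per_user`, `length_of_stay`,
#'   `occupancy_pct`, `movers_per_place`, and `qs_<domain>` for each quality
#'   domain present.
#' @export
derive_variables <- function(services) {
  if (any(services$places <= 0)) stop("places must be positive to derive rates")
  out <- data.frame(
    service_id = services$service_id,
    care_type = services$care_type,
    budget_per_place = services$annual_budget / services$places,
    places = services$places,
    staff_per_user = services$staff_fte_per_user,
    length_of_stay = services$length_of_stay,
    occupancy_pct = 100 * services$occupied_places / services$places,
    movers_per_place = services$movers_2yr / services$places,
    stringsAsFactors = FALSE
  )
  all_domains <- paste0("quirc_", c("living_environment", "therapeutic_environment",
                                    "treatments_interventions", "self_management_autonomy",
                                    "social_interface", "human_rights", "recovery_practice"))
  for (qc in intersect(all_domains, names(services))) {
    out[[sub("^quirc_", "qs_", qc)]] <- services[[qc]] * services$places / 100
  }
  out
}

#' Impute missing values from within-care-type empirical distributions
#'
#' Each missing numeric value is replaced by a uniform draw from the
#' observed values of the same field within the same care type (a Monte
#' Carlo hot-deck). Observed values are never altered; at least three
#' observed donors are required per (care type, field).
#'
#' @param services a validated service table.
#' @param seed integer seed; the imputation is deterministic given the seed.
#' @return the service table with all imputable `NA`s filled.
#' @export
impute_missing <- function(services, seed = NULL) {
  num_fields <- c(setdiff(service_columns(), c("service_id", "care_type")),
                  grep("^quirc_", names(services), value = TRUE))
  num_fields <- intersect(num_fields, names(services))
  with_seed(seed, {
    for (ct in unique(services$care_type)) {
      rows <- which(services$care_type == ct)
      fields <- num_fields
      if (ct == "floating_outreach")
        fields <- setdiff(fields, "quirc_living_environment")
      for (f in fields) {
        v <- services[[f]][rows]
        nas <- which(is.na(v))
        if (!length(nas)) next
        donors <- v[!is.na(v)]
        if (length(donors) == 0)
          stop(sprintf("field '%s' entirely missing for care type %s", f, ct))
        if (length(donors) < 3)
          stop(sprintf("fewer than 3 observed values of '%s' for care type %s",
                       f, ct))
        services[[f]][rows[nas]] <- sample(donors, length(nas), replace = TRUE)
      }
    }
    services
  })
}
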