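#' Expert adequacy rules
#'
#' An adequacy rule is the unit of expert knowledge used to interpret one
#' service variable for one care type before efficiency is computed: an
#' adequate range `[lo, hi]` in the variable's own units, a direction
#' stating what counts as better competence inside the range
#' (`higher_better`, `lower_better`, or `target_band` for variables with an
#' ideal interval such as length of stay in time-limited services), and a
#' penalty multiplier applied when the value falls outside the range.
#' Values are mapped to a competence score in `[floor, 1]`: inside the
#' range, a linear monotone map onto `[0.5, 1]` oriented by the direction
#' (for `target_band`, distance from the band centre); outside, the
#' competence of the nearest bound divided by `penalty_factor`, decaying
#' further linearly with the distance from the range in range-width units.
#' Alternatively `transform_kind = "product_sum_gravity"` interprets the
#' value through labelled fuzzy membership functions with consequent
#' competence levels, aggregated by the product-sum-gravity method
#' (activation by membership, sum aggregation, centre-of-gravity
#' defuzzification over the consequents).
#'
#' @param care_type one of [care_types()].
#' @param variable derived-variable name (see [derive_variables()]).
#' @param role `"input"` or `"output"` (how the variable enters DEA).
#' @param adequate_range numeric `c(lo, hi)`, `lo < hi`.
#' @param direction `"higher_better"`, `"lower_better"` or `"target_band"`.
#' @param penalty_factor multiplier (>= 1) penalizing out-of-range values;
#'   default 2.
#' @param transform_kind `"linear_monotone"` (default) or
#'   `"product_sum_gravity"`.
#' @param fuzzy_sets for `product_sum_gravity`: list of
#'   `list(label, breakpoints, competence)` where `breakpoints` has length 3
#'   (triangular) or 4 (trapezoidal) and `competence` is the consequent
#'   level in (0, 1].
#' @param penalty_slope linear growth rate of the penalty beyond the range,
#'   per range-width of distance.
#' @param provenance free-text note (`"expert"` or
#'   `"data-derived stand-in"`).
#' @return an object of class `"adequacy_rule"`.
#' @export
adequacy_rule <- function(care_type, variable, role,
                          adequate_range, direction = "higher_better",
                          penalty_factor = 2,
                          transform_kind = c("linear_monotone", "product_sum_gravity"),
                          fuzzy_sets = NULL, penalty_slope = 1,
                          provenance = "expert") {
  care_type <- match.arg(care_type, care_types())
  role <- match.arg(role, c("input", "output"))
  direction <- match.arg(direction, c("higher_better", "lower_better", "target_band"))
  transform_kind <- match.arg(transform_kind)
  adequate_range <- as.numeric(adequate_range)
  if (length(adequate_range) != 2 || !all(is.finite(adequate_range)) ||
      adequate_range[1] >= adequate_range[2])
    stop("adequate_range must be c(lo, hi) with lo < hi")
  if (penalty_factor < 1) stop("penalty_factor must be >= 1")
  if (transform_kind == "product_sum_gravity") {
    if (is.null(fuzzy_sets))
      fuzzy_sets <- fuzzy_triangles(adequate_range[1], adequate_range[2],
                                    penalty_factor)
    for (fs in fuzzy_sets) {
      if (!length(fs$breakpoints) %in% c(3, 4))
        stop("fuzzy set breakpoints must have length 3 or 4")
      if (is.unsorted(fs$breakpoints))
        stop("fuzzy set breakpoints must be nondecreasing")
      if (fs$competence <= 0 || fs$competence > 1)
        stop("fuzzy consequent competence must be in (0, 1]")
    }
  }
  structure(list(care_type = care_type, variable = variable, role = role,
                 adequate_range = adequate_range, direction = direction,
                 penalty_factor = penalty_factor,
                 transform_kind = transform_kind, fuzzy_sets = fuzzy_sets,
                 penalty_slope = penalty_slope, provenance = provenance),
            class = "adequacy_rule")
}

#' Default three-set fuzzy partition for an adequate range
#'
#' Low / adequate / high triangular sets spanning one range-width beyond
#' each bound. The adequate set peaks at the range centre with consequent
#' competence 1; the low and high sets peak one half-width outside the
#' bounds with consequent `0.5 / penalty_factor` (the penalized competence
#' of a boundary value under the linear-monotone convention).
#'
#' @param lo,hi adequate range bounds.
#' @param penalty_factor out-of-range penalty multiplier.
#' @return a list of three fuzzy sets usable as `fuzzy_sets` in
#'   [adequacy_rule()].
#' @export
fuzzy_triangles <- function(lo, hi, penalty_factor = 2) {
  w <- hi - lo
  cons <- 0.5 / penalty_factor
  list(
    list(label = "low", breakpoints = c(lo - 2 * w, lo - w / 2, (lo + hi) / 2),
         competence = cons),
    list(label = "adequate", breakpoints = c(lo, (lo + hi) / 2, hi),
         competence = 1),
    list(label = "high", breakpoints = c((lo + hi) / 2, hi + w / 2, hi + 2 * w),
         competence = cons)
  )
}

#' Assemble a knowledge base of adequacy rules
#'
#' A knowledge base holds at most one rule per (care type, variable) pair
#' plus an explicit set of pass-through variables that enter DEA untouched.
#' Every variable used by a scenario must be resolvable to a rule or a
#' pass-through marker.
#'
#' @param rules a list of [adequacy_rule()] objects.
#' @param pass_through character vector of variable names analysed raw.
#' @param provenance free-text note on the origin of the rules.
#' @return an object of class `"knowledge_base"`.
#' @export
knowledge_base <- function(rules = list(), pass_through = character(),
                           provenance = "expert") {
  if (inherits(rules, "adequacy_rule")) rules <- list(rules)
  keys <- vapply(rules, function(r) paste(r$care_type, r$variable, sep = ":"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate rule for key: ", keys[duplicated(keys)][1])
  names(rules) <- keys
  if (!length(rules))
    warning("empty knowledge base: all variables are pass-through")
  structure(list(rules = rules, pass_through = pass_through,
                 provenance = provenance),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base:", length(x$rules), "rule(s),",
      length(x$pass_through), "pass-through variable(s)\n")
  cat("Provenance:", x$provenance, "\n")
  if (length(x$rules)) {
    for (k in names(x$rules)) {
      r <- x$rules[[k]]
      cat(sprintf("  %-45s [%g, %g] %s x%g (%s)\n", k,
                  r$adequate_range[1], r$adequate_range[2], r$direction,
                  r$penalty_factor, r$transform_kind))
    }
  }
  invisible(x)
}

# retrieve a rule (or NULL for pass-through, error otherwise)
kb_lookup <- function(kb, care_type, variable) {
  key <- paste(care_type, variable, sep = ":")
  rule <- kb$rules[[key]]
  if (!is.null(rule)) return(rule)
  if (variable %in% kb$pass_through) return(NULL)
  stop("no adequacy rule or pass-through marker for ", key)
}

#' Read/write a knowledge base as YAML
#'
#' @param kb a `"knowledge_base"`.
#' @param path YAML file path.
#' @return `read_knowledge_base()` returns a `"knowledge_base"`;
#'   `write_knowledge_base()` invisibly returns `path`.
#' @export
write_knowledge_base <- function(kb, path) {
  ser <- list(provenance = kb$provenance, pass_through = kb$pass_through,
              rules = lapply(unname(kb$rules), unclass))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw$rules, function(r) {
    adequacy_rule(r$care_type, r$variable, r$role,
                  unlist(r$adequate_range), r$direction,
                  r$penalty_factor %||% 2,
                  r$transform_kind %||% "linear_monotone",
                  r$fuzzy_sets, r$penalty_slope %||% 1,
                  r$provenance %||% "expert")
  })
  knowledge_base(rules, as.character(raw$pass_through %||% character()),
                 raw$provenance %||% "expert")
}

#' Data-derived stand-in knowledge base
#'
#' Builds a knowledge base from the data themselves when no expert panel is
#' available: for each derived variable the adequate range is the empirical
#' interquartile range within the care type, the penalty is 2, and the
#' direction follows a fixed convention -- budget per place and staff per
#' user `higher_better` (adequate resourcing), occupancy, movers per place
#' and all quality domains `higher_better`, and length of stay a
#' `target_band` of `band_los` years for time-limited care (supported
#' housing, floating outreach and move-on residential care); `places` and,
#' for non-time-limited residential care, `length_of_stay` are
#' pass-through. Every rule is marked `"data-derived stand-in"`.
#'
#' @param services a validated service table with at least 5 records per
#'   care type present.
#' @param band_los adequate length-of-stay band (years) for time-limited
#'   care types.
#' @return a `"knowledge_base"` covering every derived variable of every
#'   care type present in `services`.
#' @export
default_knowledge_base <- function(services, band_los = c(1, 2)) {
  derived <- derive_variables(services)
  rules <- list()
  time_limited <- c("supported_housing", "floating_outreach", "residential_move_on")
  for (ct in unique(derived$care_type)) {
    d <- derived[derived$care_type == ct, , drop = FALSE]
    if (nrow(d) < 5)
      stop("need at least 5 records per care type (", ct, " has ", nrow(d), ")")
    iqr_range <- function(v) {
      qs <- unname(quantile(v, c(0.25, 0.75), na.rm = TRUE))
      if (qs[1] >= qs[2]) qs <- qs[1] * c(0.9, 1.1) + c(-1e-6, 1e-6)
      qs
    }
    mk <- function(variable, role, range, direction)
      adequacy_rule(ct, variable, role, range, direction,
                    penalty_factor = 2, provenance = "data-derived stand-in")
    rules <- c(rules, list(
      mk("budget_per_place", "input", iqr_range(d$budget_per_place), "higher_better"),
      mk("staff_per_user", "input", iqr_range(d$staff_per_user), "higher_better"),
      mk("occupancy_pct", "output", iqr_range(d$occupancy_pct), "higher_better"),
      mk("movers_per_place", "output", iqr_range(d$movers_per_place), "higher_better")
    ))
    if (ct %in% time_limited)
      rules <- c(rules, list(mk("length_of_stay", "output", band_los, "target_band")))
    for (qs in grep("^qs_", names(d), value = TRUE)) {
      if (all(is.na(d[[qs]]))) next
      rules <- c(rules, list(mk(qs, "output", iqr_range(d[[qs]]), "higher_better")))
    }
  }
  knowledge_base(rules,
                 pass_through = c("places", "length_of_stay"),
                 provenance = "data-derived stand-in")
}

# competence floor: keeps DEA-ready reciprocals bounded
COMPETENCE_FLOOR <- 0.05

#' Interpret a variable value as a competence score
#'
#' Applies one adequacy rule to one or more values, returning competence on
#' the common `[0.05, 1]` scale (see [adequacy_rule()] for the mapping).
#'
#' @param rule an `"adequacy_rule"`.
#' @param x numeric vector of finite, nonnegative values.
#' @return numeric vector of competence scores in `[0.05, 1]`.
#' @export
transform_value <- function(rule, x) {
  if (any(!is.finite(x))) stop("values must be finite")
  if (rule$transform_kind == "product_sum_gravity")
    return(psg_competence(rule, x))
  lo <- rule$adequate_range[1]; hi <- rule$adequate_range[2]
  w <- hi - lo
  inside <- function(v) {
    switch(rule$direction,
           higher_better = 0.5 + 0.5 * (v - lo) / w,
           lower_better  = 0.5 + 0.5 * (hi - v) / w,
           target_band   = 1 - abs(v - (lo + hi) / 2) / w)
  }
  comp <- numeric(length(x))
  inr <- x >= lo & x <= hi
  comp[inr] <- inside(x[inr])
  out <- !inr
  if (any(out)) {
    bound <- ifelse(x[out] < lo, lo, hi)
    dist <- abs(x[out] - bound) / w
    comp[out] <- inside(bound) /
      (rule$penalty_factor * (1 + rule$penalty_slope * dist))
  }
  pmin(pmax(comp, COMPETENCE_FLOOR), 1)
}

# membership of x in one fuzzy set (triangular or trapezoidal)
fuzzy_membership <- function(breakpoints, x) {
  b <- breakpoints
  if (length(b) == 3) b <- c(b[1], b[2], b[2], b[3])
  mu <- numeric(length(x))
  up <- x >= b[1] & x < b[2]
  mu[up] <- (x[up] - b[1]) / max(b[2] - b[1], .Machine$double.eps)
  mu[x >= b[2] & x <= b[3]] <- 1
  dn <- x > b[3] & x <= b[4]
  mu[dn] <- (b[4] - x[dn]) / max(b[4] - b[3], .Machine$double.eps)
  mu
}

# product-sum-gravity: activate each set by membership, aggregate by sum,
# defuzzify by the centre of gravity of the consequent competence levels
psg_competence <- function(rule, x) {
  hull <- range(unlist(lapply(rule$fuzzy_sets, `[[`, "breakpoints")))
  xc <- pmin(pmax(x, hull[1]), hull[2])
  mu <- vapply(rule$fuzzy_sets,
               function(fs) fuzzy_membership(fs$breakpoints, xc),
               numeric(length(xc)))
  mu <- matrix(mu, nrow = length(xc))
  cons <- vapply(rule$fuzzy_sets, `[[`, numeric(1), "competence")
  tot <- rowSums(mu)
  comp <- ifelse(tot > 1e-12, as.vector(mu %*% cons) / tot, min(cons))
  pmin(pmax(comp, COMPETENCE_FLOOR), 1)
}

# DEA-ready scale constant for outputs
OUTPUT_SCALE <- 100

#' Build DEA-ready input/output matrices for a scenario
#'
#' Interprets every scenario variable of every service through the
#' knowledge base and orients the result for the envelopment model:
#' competence of output variables is used directly (scaled by a constant,
#' larger = better), competence of input variables is inverted by
#' reciprocal (smaller = better, bounded by the competence floor so values
#' stay strictly positive). Pass-through variables enter with their raw
#' values.
#'
#' @param kb a `"knowledge_base"`.
#' @param derived a derived-variable table from [derive_variables()]
#'   containing a single care type.
#' @param scenario a `"scenario"` (see [build_scenarios()]).
#' @return a list with matrices `X` (services x inputs) and `Y`
#'   (services x outputs), row names = service ids.
#' @export
transform_record <- function(kb, derived, scenario) {
  ct <- unique(derived$care_type)
  if (length(ct) != 1)
    stop("transform_record expects a single care type per call")
  one <- function(variable, role) {
    v <- derived[[variable]]
    if (is.null(v)) stop("derived table lacks scenario variable ", variable)
    rule <- kb_lookup(kb, ct, variable)
    if (is.null(rule)) return(v)  # pass-through, raw value
    comp <- transform_value(rule, v)
    if (role == "input") 1 / comp else OUTPUT_SCALE * comp
  }
  X <- vapply(scenario$inputs, one, numeric(nrow(derived)), role = "input")
  Y <- vapply(scenario$outputs, one, numeric(nrow(derived)), role = "output")
  X <- matrix(X, nrow = nrow(derived),
              dimnames = list(derived$service_id, scenario$inputs))
  Y <- matrix(Y, nrow = nrow(derived),
              dimnames = list(derived$service_id, scenario$outputs))
  if (any(!is.finite(X)) || any(X <= 0))
    stop("nonpositive or nonfinite DEA input after transformation")
  if (any(!is.finite(Y)) || any(Y < 0))
    stop("negative or nonfinite DEA output after transformation")
  list(X = X, Y = Y)
}
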