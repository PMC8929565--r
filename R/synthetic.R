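#' Built-in synthetic cohort presets
#'
#' Per-care-type distributional presets (mean, standard deviation, minimum,
#' maximum) for the six raw service variables, matching the published summary
#' statistics of the English supported accommodation sample, plus
#' quality-score parameters on the 0-100 scale. One printed inconsistency is
#' corrected: the floating-outreach occupied-places maximum is listed as 6
#' against a mean of 28.89, so the preset uses the places maximum (80)
#' instead.
#'
#' Quality-domain statistics were not published; the presets use a common
#' stand-in per care type (supported housing highest, floating outreach
#' lowest, reflecting the reported quality ordering), bounded in [0, 100].
#'
#' @return an object of class `"synthetic_spec"`: a list with one entry per
#'   care type, each holding a `vars` table (mean, sd, min, max per raw
#'   variable) and a `quality` table (mean, sd per domain).
#' @export
published_presets <- function() {
  v <- function(mean, sd, min, max) list(mean = mean, sd = sd, min = min, max = max)
  q <- function(mean, sd, domains) {
    stats::setNames(lapply(domains, function(d) list(mean = mean, sd = sd)), domains)
  }
  spec <- list(
    residential_non_move_on = list(
      vars = list(
        places           = v(21.26, 7.12, 9, 40),
        staff_fte_per_user = v(0.66, 0.31, 0.34, 1.66),
        annual_budget    = v(500623.10, 167559.51, 211897.40, 941766.23),
        length_of_stay   = v(10, 5.42, 4, 20),
        occupied_places  = v(19.68, 7.46, 8, 37),
        movers_2yr       = v(0.58, 0.69, 0, 2)),
      quality = q(60, 12, quirc_domains("residential_non_move_on"))),
    residential_move_on = list(
      vars = list(
        places           = v(15.67, 7.52, 7, 27),
        staff_fte_per_user = v(0.83, 0.56, 0.46, 2.25),
        annual_budget    = v(386467.36, 285133.49, 265535.16, 1024207.06),
        length_of_stay   = v(3.13, 1.55, 2, 6),
        occupied_places  = v(11.56, 5.41, 7, 23),
        movers_2yr       = v(6.22, 3.46, 2, 12)),
      quality = q(60, 12, quirc_domains("residential_move_on"))),
    supported_housing = list(
      vars = list(
        places           = v(10.99, 5.11, 3, 28),
        staff_fte_per_user = v(0.45, 0.27, 0.10, 1.61),
        annual_budget    = v(334635.12, 155682.08, 91363.00, 852721.33),
        length_of_stay   = v(3.24, 2.97, 1, 20),
        occupied_places  = v(10.27, 5.15, 1, 28),
        movers_2yr       = v(5.63, 6.84, 0, 40)),
      quality = q(65, 12, quirc_domains("supported_housing"))),
    floating_outreach = list(
      vars = list(
        places           = v(29.97, 22.90, 5, 80),
        staff_fte_per_user = v(0.17, 0.17, 0.03, 0.97),
        annual_budget    = v(171950.08, 131354.68, 28685.67, 458970.67),
        length_of_stay   = v(2.83, 2.16, 1, 9),
        occupied_places  = v(28.89, 23.02, 4, 80),  # printed max 6 is inconsistent
        movers_2yr       = v(13, 16.49, 0, 75)),
      quality = q(55, 12, quirc_domains("floating_outreach")))
  )
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic cohort spec for", length(x), "care types:\n")
  for (ct in names(x)) {
    cat(" ", ct, "-", length(x[[ct]]$vars), "raw variables,",
        length(x[[ct]]$quality), "quality domains\n")
  }
  invisible(x)
}

#' Read/write a synthetic spec as YAML
#' @param spec a `"synthetic_spec"` object.
#' @param path YAML file path.
#' @return `read_synthetic_spec()` returns a `"synthetic_spec"`;
#'   `write_synthetic_spec()` invisibly returns `path`.
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  structure(yaml::read_yaml(path), class = "synthetic_spec")
}

# truncated-normal draws by inverse-CDF; degenerate sd collapses to the mean
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (lo > hi) stop("unsatisfiable range: min > max")
  if (sd <= 0 || lo == hi) return(rep(min(max(mean, lo), hi), n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  x <- qnorm(runif(n, p_lo, p_hi), mean, sd)
  pmin(pmax(x, lo), hi)  # guard the tails against rounding
}

# mean of a normal(mu, sd) truncated to [lo, hi]
trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  if (z < 1e-12) return(min(max(mu, lo), hi))
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location parameter whose truncated mean equals the target mean: asymmetric
# truncation (e.g. a bound close to the mean) otherwise biases the sample
# mean away from the published value
trunc_norm_location <- function(target, sd, lo, hi) {
  if (sd <= 0) return(target)
  f <- function(mu) trunc_norm_mean(mu, sd, lo, hi) - target
  span <- 10 * sd
  stats::uniroot(f, lower = lo - span, upper = hi + span, tol = 1e-8)$root
}

# truncated-normal draws calibrated so the population mean matches `mean`
rtrunc_norm_cal <- function(n, mean, sd, lo, hi) {
  if (lo > hi) stop("unsatisfiable range: min > max")
  if (sd <= 0 || lo == hi || !is.finite(hi - lo))
    return(rtrunc_norm(n, mean, sd, lo, hi))
  rtrunc_norm(n, trunc_norm_location(mean, sd, lo, hi), sd, lo, hi)
}

#' Generate a synthetic service cohort
#'
#' Draws `n` service records for one care type from a [published_presets()]
#' style spec. Each raw variable follows a truncated normal distribution
#' truncated at the spec's min and max, with the location parameter
#' calibrated (moment-matched) so that the truncated mean equals the spec's
#' mean: with asymmetric truncation, using the target mean directly as the
#' location would bias the realised sample mean. Counts are rounded and
#' re-clipped. Occupied places and movers are generated
#' jointly with places (as an occupancy fraction and a per-place rate times
#' the drawn places) so that `occupied_places <= places` always holds.
#' Quality scores are truncated-normal in [0, 100]; floating-outreach
#' cohorts never carry a living-environment score.
#'
#' @param care_type one of [care_types()].
#' @param n number of services to generate.
#' @param spec a `"synthetic_spec"`; defaults to the built-in presets.
#' @param seed integer seed for reproducibility.
#' @return a validated `"service_table"` data frame of `n` records.
#' @export
generate_services <- function(care_type, n, spec = published_presets(), seed = NULL) {
  care_type <- match.arg(care_type, care_types())
  if (n < 1) stop("n must be at least 1")
  ctspec <- spec[[care_type]]
  if (is.null(ctspec)) stop("spec does not cover care type ", care_type)
  vs <- ctspec$vars
  for (nm in names(vs))
    if (vs[[nm]]$min > vs[[nm]]$max)
      stop("unsatisfiable spec for ", nm, ": min > max")

  with_seed(seed, {
    draw <- function(p) rtrunc_norm_cal(n, p$mean, p$sd, p$min, p$max)
    places <- pmin(pmax(round(draw(vs$places)), vs$places$min), vs$places$max)

    p_occ <- vs$occupied_places
    occ_frac <- rtrunc_norm(n, p_occ$mean / vs$places$mean,
                            p_occ$sd / vs$places$mean / 2, 0, 1)
    occupied <- round(occ_frac * places)
    occupied <- pmin(pmax(occupied, p_occ$min), pmin(p_occ$max, places))
    occupied <- pmin(occupied, places)

    p_mov <- vs$movers_2yr
    mov_rate <- rtrunc_norm(n, p_mov$mean / vs$places$mean,
                            p_mov$sd / vs$places$mean / 2, 0, Inf)
    movers <- round(mov_rate * places)
    movers <- pmin(pmax(movers, p_mov$min), p_mov$max)

    df <- data.frame(
      service_id = sprintf("%s_%03d", abbrev_care(care_type), seq_len(n)),
      care_type = care_type,
      places = places,
      staff_fte_per_user = draw(vs$staff_fte_per_user),
      annual_budget = draw(vs$annual_budget),
      length_of_stay = draw(vs$length_of_stay),
      occupied_places = occupied,
      movers_2yr = movers,
      outlier_flag = FALSE,
      stringsAsFactors = FALSE
    )
    for (d in quirc_domains(care_type)) {
      qp <- ctspec$quality[[d]]
      df[[paste0("quirc_", d)]] <- rtrunc_norm(n, qp$mean, qp$sd, 0, 100)
    }
    validate_services(df)
  })
}

abbrev_care <- function(ct) {
  c(residential_move_on = "rmo", residential_non_move_on = "rnm",
    supported_housing = "sh", floating_outreach = "fo")[[ct]]
}

#' Generate a cohort with known true efficiencies
#'
#' Builds a test cohort on a constructed variable-returns-to-scale frontier
#' with known input-oriented efficiency for every unit. Frontier units lie
#' on the concave curve `y_r = w_r * sqrt(t)` along a fixed input ray
#' `x_h = t * c_h`; because the outputs are a concave increasing function of
#' the ray position, no convex combination of frontier units dominates any
#' of them, so each has efficiency exactly 1. Each inefficient unit is a
#' frontier point with all inputs divided by its true efficiency
#' `theta` (and outputs kept), so its input-oriented VRS score equals
#' `theta` whenever the frontier units are present.
#'
#' Inefficient units are scaled off interior frontier points only, never off
#' the maximal-output corner. A unit whose output ties the cohort maximum
#' loses its constructed truth under data perturbation: whenever its own
#' perturbed output exceeds every frontier output, self-reference is the
#' only feasible envelopment and the score collapses to 1 for that draw,
#' which biases noisy recovery upwards. Keeping a frontier point strictly
#' above every inefficient unit's output avoids this corner artefact. The
#' frontier positions are equally spaced along the ray so that consecutive
#' frontier outputs are separated by more than typical perturbation noise.
#'
#' @param n_frontier number of frontier units (>= 2).
#' @param n_inefficient number of inefficient units.
#' @param true_theta optional vector of true efficiencies in (0, 1] for the
#'   inefficient units (recycled); drawn uniformly from `theta_range` if
#'   `NULL`.
#' @param n_inputs,n_outputs dimensionality of the input/output space.
#' @param theta_range range for randomly drawn true efficiencies.
#' @param seed integer seed.
#' @return a list of class `"frontier_cohort"` with `X` (units x inputs),
#'   `Y` (units x outputs), `theta` (true efficiency per unit, 1 for
#'   frontier units) and `frontier` (logical).
#' @export
generate_frontier_cohort <- function(n_frontier, n_inefficient,
                                     true_theta = NULL,
                                     n_inputs = 2, n_outputs = 1,
                                     theta_range = c(0.3, 1), seed = NULL) {
  if (n_frontier < 2) stop("at least 2 frontier units are required")
  with_seed(seed, {
    ray <- runif(n_inputs, 0.5, 2)
    w <- runif(n_outputs, 0.5, 2)
    t_front <- seq(1, 9, length.out = n_frontier)
    Xf <- outer(t_front, ray)                    # n_frontier x n_inputs
    Yf <- outer(sqrt(t_front), w)                # n_frontier x n_outputs

    if (is.null(true_theta)) {
      theta_i <- runif(n_inefficient, theta_range[1], theta_range[2])
    } else {
      if (any(true_theta <= 0 | true_theta > 1))
        stop("true_theta must lie in (0, 1]")
      theta_i <- rep_len(true_theta, n_inefficient)
    }
    # interior points only: see the corner-artefact note above
    pick <- sample(n_frontier - 1L, n_inefficient, replace = TRUE)
    Xi <- Xf[pick, , drop = FALSE] / theta_i
    Yi <- Yf[pick, , drop = FALSE]

    X <- rbind(Xf, Xi)
    Y <- rbind(Yf, Yi)
    n <- nrow(X)
    rownames(X) <- rownames(Y) <- sprintf("dmu_%02d", seq_len(n))
    structure(list(X = X, Y = Y,
                   theta = c(rep(1, n_frontier), theta_i),
                   frontier = c(rep(TRUE, n_frontier),
                                rep(FALSE, n_inefficient))),
              class = "frontier_cohort")
  })
}
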