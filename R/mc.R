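#' Monte Carlo engine configuration
#'
#' Settings for the uncertainty-propagation loop: each iteration perturbs
#' every raw service value with symmetric triangular noise of relative
#' half-width `variation` (default 5% each side), re-derives the rate
#' variables, re-interprets them through the knowledge base and re-solves
#' the DEA model. The loop stops, after at least `min_sims` iterations and
#' checking every `batch` iterations, when the relative standard error of
#' the mean score is at or below `stop_rel_se` (default 2.5%) for every
#' service, or at `n_max` iterations (default 500).
#'
#' @param variation relative half-width of the triangular perturbation,
#'   in (0, 1).
#' @param n_max maximum number of simulations.
#' @param stop_rel_se relative standard error threshold for the mean.
#' @param min_sims minimum number of simulations before testing convergence.
#' @param batch iterations between convergence checks.
#' @param seed integer seed; a full run is reproducible given the seed.
#' @return an object of class `"mc_config"`.
#' @export
mc_config <- function(variation = 0.05, n_max = 500, stop_rel_se = 0.025,
                      min_sims = 30, batch = 10, seed = NULL) {
  if (variation <= 0 || variation >= 1) stop("variation must be in (0, 1)")
  if (n_max < min_sims || min_sims < 2) stop("need n_max >= min_sims >= 2")
  structure(list(variation = variation, n_max = n_max,
                 stop_rel_se = stop_rel_se, min_sims = min_sims,
                 batch = batch, seed = seed),
            class = "mc_config")
}

#' Symmetric triangular perturbation
#'
#' Replaces each value `v` by a draw from the symmetric triangular
#' distribution with mode `v` on `[v (1 - variation), v (1 + variation)]`.
#' Zeros stay zero (the multiplicative support collapses). Draws use the
#' current RNG stream.
#'
#' @param values finite, nonnegative numeric vector.
#' @param variation relative half-width in (0, 1).
#' @return the perturbed vector.
#' @export
perturb_triangular <- function(values, variation = 0.05) {
  if (variation <= 0 || variation >= 1) stop("variation must be in (0, 1)")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be nonnegative")
  u <- runif(length(values))
  # inverse CDF of the symmetric triangular distribution on [-1, 1], mode 0
  z <- ifelse(u < 0.5, sqrt(2 * u) - 1, 1 - sqrt(2 * (1 - u)))
  values * (1 + variation * z)
}

# perturb all raw numeric fields of a service table, preserving invariants
perturb_services <- function(services, variation) {
  fields <- c("places", "staff_fte_per_user", "annual_budget",
              "length_of_stay", "occupied_places", "movers_2yr",
              grep("^quirc_", names(services), value = TRUE))
  for (f in intersect(fields, names(services))) {
    v <- services[[f]]
    ok <- !is.na(v)
    v[ok] <- perturb_triangular(v[ok], variation)
    services[[f]] <- v
  }
  # quality scores stay on the 0-100 scale and occupancy stays feasible
  for (qc in grep("^quirc_", names(services), value = TRUE))
    services[[qc]] <- pmin(services[[qc]], 100)
  services$occupied_places <- pmin(services$occupied_places, services$places)
  services
}

#' Monte Carlo RTE assessment of one scenario
#'
#' Runs the full perturb / derive / interpret / envelop loop for one
#' scenario and returns the per-service distribution of efficiency scores.
#' Iterations where the LP fails on a pathological draw are retried with a
#' fresh draw (at most 3 retries each).
#'
#' @param services a validated service table of a single care type with at
#'   least 2 services.
#' @param scenario a `"scenario"` from [build_scenarios()].
#' @param kb a `"knowledge_base"`.
#' @param config an [mc_config()].
#' @return an object of class `"rte_dist"`: list with `samples` (iterations
#'   x services matrix of scores), `n`, `mean`, `sd`, `rel_se`
#'   (`sd / (mean * sqrt(n))` per service), `converged`, plus the scenario
#'   and care type.
#' @export
run_simulation <- function(services, scenario, kb, config = mc_config()) {
  ct <- unique(services$care_type)
  if (length(ct) != 1) stop("run_simulation expects a single care type")
  if (nrow(services) < 2) stop("need at least 2 services")

  with_seed(config$seed, {
    samples <- matrix(NA_real_, config$n_max, nrow(services),
                      dimnames = list(NULL, services$service_id))
    n <- 0
    converged <- FALSE
    while (n < config$n_max && !converged) {
      samples[n + 1, ] <- mc_iteration(services, scenario, kb, config$variation)
      n <- n + 1
      check_now <- n >= config$min_sims &&
        (n %% config$batch == 0 || n == config$n_max)
      if (check_now) {
        s <- samples[seq_len(n), , drop = FALSE]
        m <- colMeans(s)
        rel_se <- apply(s, 2, sd) / (m * sqrt(n))
        converged <- all(rel_se <= config$stop_rel_se)
      }
    }
    samples <- samples[seq_len(n), , drop = FALSE]
    m <- colMeans(samples)
    s_dev <- apply(samples, 2, sd)
    structure(list(samples = samples, n = as.integer(n), mean = m, sd = s_dev,
                   rel_se = s_dev / (m * sqrt(n)),
                   converged = converged,
                   scenario = scenario, care_type = ct),
              class = "rte_dist")
  })
}

mc_iteration <- function(services, scenario, kb, variation, retries = 3) {
  for (attempt in seq_len(retries + 1)) {
    pert <- perturb_services(services, variation)
    res <- tryCatch({
      mats <- transform_record(kb, derive_variables(pert), scenario)
      dea(mats$X, mats$Y, slacks = FALSE)$theta
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (attempt == retries + 1)
      stop("DEA failed after ", retries, " retries: ", conditionMessage(res))
  }
}

#' @export
print.rte_dist <- function(x, digits = 4, ...) {
  cat(sprintf("RTE distribution, scenario %s (%s): %d simulations, %s\n",
              x$scenario$id, x$care_type, x$n,
              if (x$converged) "converged" else "not converged"))
  print(round(x$mean, digits))
  invisible(x)
}

#' Summarize a Monte Carlo RTE distribution
#'
#' @param object an `"rte_dist"` from [run_simulation()].
#' @param ... unused.
#' @return a data frame with one row per service: mean, sd, relative
#'   standard error of the mean, 2.5/50/97.5% quantiles, simulation count
#'   and convergence flag.
#' @export
summary.rte_dist <- function(object, ...) {
  if (object$n < 1) stop("empty sample")
  qs <- apply(object$samples, 2, quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(
    service_id = colnames(object$samples),
    mean = unname(object$mean),
    sd = unname(object$sd),
    rel_se = unname(object$rel_se),
    q025 = unname(qs[1, ]), median = unname(qs[2, ]), q975 = unname(qs[3, ]),
    n = object$n, converged = object$converged,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
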