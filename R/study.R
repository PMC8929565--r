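#' Run a full scenario-wise RTE study
#'
#' Orchestrates the whole pipeline for one care type: the baseline scenario
#' first, then every quality scenario, each through the Monte Carlo engine
#' ([run_simulation()]). Per-scenario seeds are derived deterministically
#' from the configuration seed so the study as a whole is reproducible.
#'
#' @param services a validated single-care-type service table.
#' @param kb a `"knowledge_base"`; defaults to the data-derived stand-in
#'   from [default_knowledge_base()].
#' @param scenarios scenario list; defaults to [build_scenarios()] for the
#'   table's care type.
#' @param config an [mc_config()].
#' @return an object of class `"rte_study"`: list with `means` (service x
#'   scenario matrix of mean scores), `global_average` (per-scenario
#'   unweighted mean of the service means), `distributions` (one
#'   `"rte_dist"` per scenario), `care_type`, `kb`, `config`.
#' @export
rte_study <- function(services, kb = default_knowledge_base(services),
                      scenarios = NULL, config = mc_config()) {
  ct <- unique(services$care_type)
  if (length(ct) != 1) stop("rte_study expects a single care type")
  if (is.null(scenarios)) scenarios <- build_scenarios(ct)

  dists <- vector("list", length(scenarios))
  names(dists) <- names(scenarios)
  for (k in seq_along(scenarios)) {
    cfg_k <- config
    if (!is.null(config$seed))
      cfg_k$seed <- (config$seed + 7919L * scenarios[[k]]$id) %% .Machine$integer.max
    dists[[k]] <- run_simulation(services, scenarios[[k]], kb, cfg_k)
  }
  means <- vapply(dists, function(d) d$mean, numeric(nrow(services)))
  means <- matrix(means, nrow = nrow(services),
                  dimnames = list(services$service_id, names(scenarios)))
  structure(list(means = means,
                 global_average = colMeans(means),
                 distributions = dists,
                 scenarios = scenarios,
                 care_type = ct, kb = kb, config = config),
            class = "rte_study")
}

#' @export
print.rte_study <- function(x, digits = 4, ...) {
  cat(sprintf("RTE study: %s, %d services, %d scenarios\n",
              x$care_type, nrow(x$means), ncol(x$means)))
  tab <- rbind(round(x$means, digits),
               `Global average` = round(x$global_average, digits))
  print(tab)
  invisible(x)
}

#' @export
summary.rte_study <- function(object, ...) {
  conv <- vapply(object$distributions, `[[`, logical(1), "converged")
  nsim <- vapply(object$distributions, function(d) as.integer(d$n), integer(1))
  data.frame(scenario = names(object$distributions),
             global_average = unname(object$global_average),
             n_sims = unname(nsim), converged = unname(conv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
plot.rte_study <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(lapply(x$distributions, function(d) as.vector(d$samples)),
                    names = vapply(x$scenarios, `[[`, integer(1), "id"),
                    xlab = "Scenario", ylab = "RTE score", ylim = c(0, 1),
                    col = "grey85", ...)
  graphics::points(seq_along(x$global_average), x$global_average,
                   pch = 19, col = "firebrick")
  graphics::title(main = sprintf("RTE by scenario (%s)", x$care_type))
  invisible(x)
}

#' Wilcoxon signed-rank comparison of quality scenarios against the baseline
#'
#' Pairs per-service mean RTE scores (baseline vs quality scenario) and
#' applies the two-sided Wilcoxon signed-rank test: zero differences are
#' dropped per the standard procedure, the exact null distribution is used
#' for n <= 25 without ties, and the normal approximation with tie
#' correction otherwise. A global impact class is attached per scenario
#' (positive/negative when the mean difference exceeds `delta` in magnitude
#' and the test is significant at `alpha`, neutral otherwise), alongside
#' per-service classes from [classify_impact()].
#'
#' @param study an `"rte_study"`.
#' @param scenario_id scenarios to compare (default: all non-baseline).
#' @param delta minimum mean-RTE difference for a non-neutral class.
#' @param alpha significance level.
#' @param adjust p-value adjustment across scenario comparisons: `"none"`
#'   (default, matching single-comparison reporting) or `"holm"`.
#' @return an object of class `"impact_assessment"`: a data frame `table`
#'   (scenario, V statistic, p-value, mean difference, class) plus a
#'   `service_classes` matrix (service x scenario).
#' @export
compare_to_baseline <- function(study, scenario_id = NULL,
                                delta = 0.05, alpha = 0.05,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  ids <- vapply(study$scenarios, `[[`, integer(1), "id")
  if (is.null(scenario_id)) scenario_id <- ids[ids != 1L]
  if (!1L %in% ids) stop("study lacks the baseline scenario")
  base_col <- which(ids == 1L)
  if (nrow(study$means) < 6)
    warning("fewer than 6 services: the signed-rank test has little power")

  rows <- lapply(scenario_id, function(sid) {
    col <- which(ids == sid)
    if (!length(col)) stop("scenario ", sid, " not present in the study")
    base <- study$means[, base_col]
    scen <- study$means[, col]
    wt <- signed_rank_test(scen, base)
    diff_mean <- mean(scen - base)
    cls <- if (wt$p.value < alpha && diff_mean > delta) "positive"
           else if (wt$p.value < alpha && diff_mean < -delta) "negative"
           else "neutral"
    data.frame(scenario = sid, statistic = unname(wt$statistic),
               p_value = wt$p.value, mean_diff = diff_mean, class = cls,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (adjust == "holm") {
    tab$p_adjusted <- stats::p.adjust(tab$p_value, "holm")
    tab$class <- ifelse(tab$p_adjusted < alpha & abs(tab$mean_diff) > delta,
                        ifelse(tab$mean_diff > 0, "positive", "negative"),
                        "neutral")
  }

  svc <- vapply(scenario_id, function(sid) {
    col <- which(ids == sid)
    classify_impact(study$distributions[[base_col]],
                    study$distributions[[col]],
                    delta = delta, alpha = alpha)
  }, character(nrow(study$means)))
  svc <- matrix(svc, nrow = nrow(study$means),
                dimnames = list(rownames(study$means),
                                paste0("scenario_", scenario_id)))
  structure(list(table = tab, service_classes = svc,
                 delta = delta, alpha = alpha, care_type = study$care_type),
            class = "impact_assessment")
}

# Paired two-sided Wilcoxon signed-rank. Zero differences dropped; exact
# null (psignrank) for n <= 25 without ties; exact null by direct sign
# enumeration for n <= 12 with tied |differences| (where psignrank does not
# apply); normal approximation with continuity and tie correction
# otherwise. All pairs tied -> degenerate no-difference result (p = 1).
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = c(V = 0), p.value = 1))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    p <- suppressWarnings(
      wilcox.test(d, exact = TRUE)$p.value)
  } else if (n <= 12) {
    # enumerate all 2^n sign assignments under the null
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  } else {
    p <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = c(V = V), p.value = p)
}

#' Classify the per-service impact of a quality scenario
#'
#' Compares the simulated score distributions of one service under the
#' baseline and under a quality scenario: the class is `"positive"` when
#' the mean difference exceeds `delta` and a two-sample Wilcoxon rank-sum
#' test on the simulation samples is significant at `alpha`, `"negative"`
#' for the mirror case, `"neutral"` otherwise.
#'
#' @param baseline_dist,scenario_dist `"rte_dist"` objects over the same
#'   services.
#' @param delta minimum mean difference for a non-neutral class.
#' @param alpha significance level of the two-sample test.
#' @return character vector of classes, one per service.
#' @export
classify_impact <- function(baseline_dist, scenario_dist,
                            delta = 0.05, alpha = 0.05) {
  stopifnot(identical(colnames(baseline_dist$samples),
                      colnames(scenario_dist$samples)))
  vapply(colnames(baseline_dist$samples), function(sv) {
    b <- baseline_dist$samples[, sv]
    s <- scenario_dist$samples[, sv]
    dm <- mean(s) - mean(b)
    if (abs(dm) <= delta) return("neutral")
    p <- if (sd(b) == 0 && sd(s) == 0) {
      if (abs(dm) > 0) 0 else 1
    } else {
      suppressWarnings(wilcox.test(s, b, exact = FALSE)$p.value)
    }
    if (p < alpha) { if (dm > 0) "positive" else "negative" } else "neutral"
  }, character(1))
}

#' @export
print.impact_assessment <- function(x, digits = 4, ...) {
  cat(sprintf("Impact of quality scenarios vs baseline (%s)\n", x$care_type))
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 3)
  tab$mean_diff <- round(tab$mean_diff, digits)
  print(tab, row.names = FALSE)
  pct <- impact_percentages(x)
  cat("Per-service classes (% across services and scenarios):\n")
  print(round(pct, 1))
  invisible(x)
}

# percentage of services per class, pooled over scenarios
impact_percentages <- function(impact) {
  cls <- factor(impact$service_classes,
                levels = c("negative", "neutral", "positive"))
  100 * table(cls) / length(cls)
}

#' Write study results and comparison tables to files
#'
#' Produces the per-care-type report: a CSV and a markdown table of service
#' x scenario mean scores with a global-average row (4-decimal formatting,
#' with a shading bucket per cell: quintiles of [0, 1], darker = less
#' efficient), and, when an impact assessment is supplied, a comparison
#' summary with p-values and class percentages.
#'
#' @param study an `"rte_study"`.
#' @param impacts optional `"impact_assessment"` from
#'   [compare_to_baseline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths of the files written.
#' @export
render_report <- function(study, impacts = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- rbind(study$means, `Global average` = study$global_average)
  csv_path <- file.path(dir, sprintf("rte_means_%s.csv", study$care_type))
  write.csv(round(tab, 4), csv_path, quote = FALSE)

  md_path <- file.path(dir, sprintf("rte_means_%s.md", study$care_type))
  bucket <- function(v) 5 - pmin(pmax(ceiling(v * 5), 1), 5)  # 0 light .. 4 dark
  lines <- c(
    sprintf("# Mean RTE scores by scenario (%s)", study$care_type),
    "",
    paste0("| Service | ", paste(colnames(tab), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(tab) + 1), collapse = "|"), "|"),
    vapply(seq_len(nrow(tab)), function(r) {
      cells <- sprintf("%.4f (s%d)", tab[r, ], bucket(tab[r, ]))
      paste0("| ", rownames(tab)[r], " | ", paste(cells, collapse = " | "), " |")
    }, character(1)),
    "",
    "Shading buckets s0 (lightest, most efficient) to s4 (darkest)."
  )
  paths <- c(csv_path, md_path)

  if (!is.null(impacts)) {
    cmp_path <- file.path(dir, sprintf("impact_%s.csv", study$care_type))
    write.csv(impacts$table, cmp_path, row.names = FALSE, quote = FALSE)
    pct <- impact_percentages(impacts)
    lines <- c(lines, "", "## Impact vs baseline", "",
               paste0("| Scenario | V | p | mean diff | class |"),
               "|---|---|---|---|---|",
               vapply(seq_len(nrow(impacts$table)), function(r) {
                 with(impacts$table[r, ],
                      sprintf("| %d | %.1f | %.3g | %.4f | %s |",
                              scenario, statistic, p_value, mean_diff, class))
               }, character(1)),
               "",
               sprintf("Per-service classes: %.1f%% negative, %.1f%% neutral, %.1f%% positive.",
                       pct[["negative"]], pct[["neutral"]], pct[["positive"]]))
    paths <- c(paths, cmp_path)
  }
  writeLines(lines, md_path)
  invisible(paths)
}
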