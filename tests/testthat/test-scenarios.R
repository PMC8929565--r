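test_that("scenario sets match the published design exactly", {
  counts <- c(residential_move_on = 8, residential_non_move_on = 8,
              supported_housing = 8, floating_outreach = 7)
  for (ct in names(counts)) {
    sc <- build_scenarios(ct)
    expect_length(sc, counts[[ct]])
    base <- sc[[1]]
    expect_equal(base$inputs, c("places", "staff_per_user", "budget_per_place"))
    expect_equal(base$outputs,
                 c("length_of_stay", "occupancy_pct", "movers_per_place"))
    expect_true(is.na(base$quality_domain))
    for (s in sc[-1]) {
      expect_length(s$outputs, 4)  # baseline + exactly one quality domain
      expect_equal(setdiff(s$outputs, base$outputs),
                   paste0("qs_", s$quality_domain))
    }
  }
  # domain order: living environment enters at scenario 2 where present,
  # floating outreach starts with the therapeutic environment instead
  expect_equal(build_scenarios("residential_move_on")[[2]]$quality_domain,
               "living_environment")
  expect_equal(build_scenarios("floating_outreach")[[2]]$quality_domain,
               "therapeutic_environment")
  expect_false(any(vapply(build_scenarios("floating_outreach"), function(s)
    identical(s$quality_domain, "living_environment"), logical(1))))
})

test_that("study orchestration reports per-service means with a global average", {
  sv <- generate_services("supported_housing", 8, seed = 111)
  kb <- default_knowledge_base(sv)
  st <- rte_study(sv, kb, config = mc_config(seed = 112, n_max = 60))

  expect_equal(dim(st$means), c(8, 8))
  expect_equal(unname(st$global_average), unname(colMeans(st$means)))
  expect_true(all(st$means > 0 & st$means <= 1))

  # global average is an unweighted mean: invariant to service ordering
  perm <- sample(nrow(sv))
  expect_equal(unname(colMeans(st$means[perm, ])),
               unname(st$global_average))

  # identical services: with near-zero noise every mean is close to 1
  # (the reciprocal competence transform amplifies raw noise severalfold,
  # so the bound is looser than the raw variation)
  same <- sv[rep(1, 6), ]
  same$service_id <- paste0("dup_", 1:6)
  st3 <- rte_study(same, kb, config = mc_config(variation = 1e-3, seed = 113,
                                                n_max = 40))
  expect_true(all(st3$means > 0.95))
})

test_that("a constant quality column leaves the deterministic scores unchanged", {
  # with the convexity constraint, an output column that is identical across
  # services adds no binding constraint to the envelopment LP
  sv <- generate_services("supported_housing", 10, seed = 121)
  kb <- default_knowledge_base(sv)
  dv <- derive_variables(sv)
  sc <- build_scenarios("supported_housing")
  base <- transform_record(kb, dv, sc[[1]])
  th_base <- dea(base$X, base$Y, slacks = FALSE)$theta

  qcol <- sc[[2]]$outputs[4]
  dv_const <- dv
  dv_const[[qcol]] <- 0
  kb_pass <- kb
  kb_pass$pass_through <- c(kb_pass$pass_through, qcol)
  kb_pass$rules[[paste("supported_housing", qcol, sep = ":")]] <- NULL
  plus <- transform_record(kb_pass, dv_const, sc[[2]])
  expect_true(all(plus$Y[, 4] == 0))
  th_plus <- dea(plus$X, plus$Y, slacks = FALSE)$theta
  expect_equal(unname(th_plus), unname(th_base), tolerance = 1e-9)
})

test_that("adding a quality output never lowers deterministic scores end to end", {
  sv <- generate_services("residential_move_on", 9, seed = 131)
  kb <- default_knowledge_base(sv)
  dv <- derive_variables(sv)
  sc <- build_scenarios("residential_move_on")
  base <- transform_record(kb, dv, sc[[1]])
  th_base <- dea(base$X, base$Y, slacks = FALSE)$theta
  for (k in 2:length(sc)) {
    m <- transform_record(kb, dv, sc[[k]])
    th <- dea(m$X, m$Y, slacks = FALSE)$theta
    expect_true(all(th >= th_base - 1e-7), label = paste("scenario", k))
  }
})

test_that("signed-rank comparison matches exact enumeration and handles degenerate input", {
  set.seed(141)
  # random paired samples, n <= 10, against the independent enumeration oracle
  for (k in 1:20) {
    n <- sample(4:10, 1)
    x <- round(runif(n, 0, 1), 2)
    y <- round(runif(n, 0, 1), 2)
    got <- rtebench:::signed_rank_test(x, y)
    expect_equal(got$p.value, enum_signed_rank_p(x, y), tolerance = 1e-12,
                 label = sprintf("case %d", k))
  }

  # ten equal positive shifts: two-sided exact p = 2 * (1/2)^10
  x <- seq(0.1, 1, by = 0.1)
  got <- rtebench:::signed_rank_test(x + 0.1, x)
  expect_equal(got$p.value, 2 * (1 / 2)^10)

  # identical columns: degenerate no-difference result
  got0 <- rtebench:::signed_rank_test(x, x)
  expect_equal(got0$p.value, 1)
})

test_that("baseline comparisons classify impact with the documented rule", {
  sv <- generate_services("floating_outreach", 12, seed = 151)
  kb <- default_knowledge_base(sv)
  st <- rte_study(sv, kb, config = mc_config(seed = 152, n_max = 60))
  imp <- compare_to_baseline(st)

  expect_equal(nrow(imp$table), 6)  # 7 scenarios - baseline
  expect_true(all(imp$table$p_value >= 0 & imp$table$p_value <= 1))
  expect_true(all(imp$table$class %in% c("negative", "neutral", "positive")))
  expect_equal(dim(imp$service_classes), c(12, 6))

  # class percentages partition the services
  pct <- rtebench:::impact_percentages(imp)
  expect_equal(sum(pct), 100)

  # scenario identical to baseline -> neutral with p = 1
  st_id <- st
  st_id$means[, 2] <- st_id$means[, 1]
  st_id$distributions[[2]]$samples <- st_id$distributions[[1]]$samples
  st_id$distributions[[2]]$mean <- st_id$distributions[[1]]$mean
  imp_id <- compare_to_baseline(st_id, scenario_id = 2)
  expect_equal(imp_id$table$p_value, 1)
  expect_equal(imp_id$table$class, "neutral")
  expect_true(all(imp_id$service_classes == "neutral"))

  # dominance: a large disjoint downward shift is negative (downward avoids
  # the theta <= 1 ceiling that would mask an upward shift near the frontier)
  st_dom <- st
  st_dom$means[, 3] <- st_dom$means[, 1] * 0.4
  st_dom$distributions[[3]]$samples <- st_dom$distributions[[1]]$samples * 0.4
  st_dom$distributions[[3]]$mean <- st_dom$distributions[[1]]$mean * 0.4
  imp_dom <- compare_to_baseline(st_dom, scenario_id = 3)
  expect_equal(imp_dom$table$class, "negative")
  expect_true(all(imp_dom$service_classes == "negative"))

  # a shift below delta/2 stays neutral under the default threshold
  st_small <- st
  st_small$means[, 4] <- st_small$means[, 1] + 0.025
  imp_small <- compare_to_baseline(st_small, scenario_id = 4)
  expect_equal(imp_small$table$class, "neutral")
})

test_that("shift detection power: a +0.05 shift at sd 0.01 with n = 30 is caught", {
  set.seed(161)
  hits <- 0L
  reps <- 200
  for (k in seq_len(reps)) {
    base <- runif(30, 0.4, 0.9)
    scen <- pmin(base + rnorm(30, 0.05, 0.01), 1)
    p <- rtebench:::signed_rank_test(scen, base)$p.value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("reports carry the result matrix, formatting and class summary", {
  sv <- generate_services("supported_housing", 6, seed = 171)
  kb <- default_knowledge_base(sv)
  st <- rte_study(sv, kb, scenarios = build_scenarios("supported_housing")[1:2],
                  config = mc_config(seed = 172, n_max = 40))
  imp <- compare_to_baseline(st, scenario_id = 2)
  dir <- withr::local_tempdir()
  paths <- render_report(st, imp, dir = dir)
  expect_true(all(file.exists(paths)))

  tab <- read.csv(paths[1], row.names = 1, check.names = FALSE)
  expect_equal(nrow(tab), 7)  # 6 services + global average
  expect_equal(rownames(tab)[7], "Global average")
  expect_equal(unname(unlist(tab[7, ])), unname(round(st$global_average, 4)))

  md <- readLines(paths[2])
  expect_true(any(grepl("^\\| Service \\|", md)))
  expect_true(any(grepl("\\d\\.\\d{4}", md)))  # 4-decimal formatting
})
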