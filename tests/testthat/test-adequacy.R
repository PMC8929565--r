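test_that("rule construction validates its invariants", {
  r <- adequacy_rule("floating_outreach", "budget_per_place", "input",
                     c(5000, 6000), "higher_better")
  expect_s3_class(r, "adequacy_rule")
  expect_equal(r$penalty_factor, 2)
  expect_error(adequacy_rule("floating_outreach", "x", "input", c(6000, 5000)),
               "lo < hi")
  expect_error(adequacy_rule("floating_outreach", "x", "input", c(1, 2),
                             penalty_factor = 0.5), ">= 1")
})

test_that("knowledge bases key rules uniquely and report pass-through", {
  r1 <- adequacy_rule("floating_outreach", "budget_per_place", "input",
                      c(5000, 6000))
  kb <- knowledge_base(list(r1), pass_through = "places")
  expect_identical(rtebench:::kb_lookup(kb, "floating_outreach",
                                        "budget_per_place"), r1)
  expect_null(rtebench:::kb_lookup(kb, "floating_outreach", "places"))
  expect_error(rtebench:::kb_lookup(kb, "floating_outreach", "movers_per_place"),
               "no adequacy rule")

  r2 <- adequacy_rule("floating_outreach", "budget_per_place", "input",
                      c(4000, 7000))
  expect_error(knowledge_base(list(r1, r2)), "duplicate")
  expect_warning(knowledge_base(list()), "pass-through")

  # YAML round trip preserves rules
  path <- withr::local_tempfile(fileext = ".yaml")
  write_knowledge_base(kb, path)
  back <- read_knowledge_base(path)
  rb <- rtebench:::kb_lookup(back, "floating_outreach", "budget_per_place")
  expect_equal(rb$adequate_range, r1$adequate_range)
  expect_equal(rb$direction, r1$direction)
  expect_equal(back$pass_through, "places")
})

test_that("linear monotone competence maps the adequate range onto [0.5, 1]", {
  r <- adequacy_rule("floating_outreach", "budget_per_place", "input",
                     c(5000, 6000), "higher_better")
  expect_equal(transform_value(r, 6000), 1)
  expect_equal(transform_value(r, 5500), 0.75)
  expect_equal(transform_value(r, 5000), 0.5)
  # just outside: competence of the bound divided by the penalty factor
  expect_equal(transform_value(r, 5000 - 1e-9), 0.25, tolerance = 1e-6)
  expect_equal(transform_value(r, 6000 + 1e-9), 0.5, tolerance = 1e-6)
  # strictly decreasing with distance beyond the range
  below <- transform_value(r, c(4900, 4500, 4000, 3000))
  expect_true(all(diff(below) < 0))

  # monotone inside, oriented by direction
  xs <- seq(5000, 6000, by = 100)
  expect_true(all(diff(transform_value(r, xs)) > 0))
  rl <- adequacy_rule("floating_outreach", "los", "output", c(5000, 6000),
                      "lower_better")
  expect_true(all(diff(transform_value(rl, xs)) < 0))

  rb <- adequacy_rule("supported_housing", "length_of_stay", "output",
                      c(1, 2), "target_band")
  expect_equal(transform_value(rb, 1.5), 1)
  expect_equal(transform_value(rb, 1), 0.5)
  expect_equal(transform_value(rb, 2), 0.5)
  expect_lt(transform_value(rb, 2.6), 0.25 + 1e-9)
})

test_that("penalty bound holds for a sweep of rules and values", {
  set.seed(41)
  for (rep in 1:25) {
    lo <- runif(1, 1, 50); hi <- lo + runif(1, 1, 50)
    pf <- runif(1, 1, 4)
    dir <- sample(c("higher_better", "lower_better", "target_band"), 1)
    r <- adequacy_rule("supported_housing", "v", "output", c(lo, hi), dir,
                       penalty_factor = pf)
    x_out <- c(lo - runif(3, 0, hi - lo), hi + runif(3, 0, hi - lo))
    x_out <- x_out[x_out >= 0]
    for (x in x_out) {
      bound <- if (x < lo) lo else hi
      cb <- transform_value(r, bound)
      cx <- transform_value(r, x)
      expect_lte(cx, cb + 1e-12)
      expect_gte(cx, cb / (pf * (1 + abs(x - bound) / (hi - lo))) - 1e-12)
    }
  }
})

test_that("product-sum-gravity defuzzification respects its consequents", {
  r <- adequacy_rule("supported_housing", "v", "output", c(10, 20),
                     transform_kind = "product_sum_gravity")
  cons <- vapply(r$fuzzy_sets, `[[`, numeric(1), "competence")
  # full membership of the adequate set at the band centre
  expect_equal(transform_value(r, 15), 1)
  # at the low set's peak, only the low set is active
  expect_equal(transform_value(r, r$fuzzy_sets[[1]]$breakpoints[2]),
               max(cons[1], rtebench:::COMPETENCE_FLOOR))
  # output always within the consequent hull (floored)
  xs <- seq(-20, 60, by = 0.5)
  out <- transform_value(r, xs)
  expect_true(all(out >= min(cons) - 1e-12 | out == rtebench:::COMPETENCE_FLOOR))
  expect_true(all(out <= max(cons) + 1e-12))
})

test_that("data-derived knowledge bases cover all variables with documented directions", {
  sv <- generate_services("supported_housing", 12, seed = 5)
  kb <- default_knowledge_base(sv)
  dv <- derive_variables(sv)

  r <- rtebench:::kb_lookup(kb, "supported_housing", "budget_per_place")
  expect_equal(r$adequate_range,
               unname(quantile(dv$budget_per_place, c(0.25, 0.75))))
  expect_equal(r$provenance, "data-derived stand-in")

  # length of stay: a target band containing the expected two-year horizon
  rlos <- rtebench:::kb_lookup(kb, "supported_housing", "length_of_stay")
  expect_equal(rlos$direction, "target_band")
  expect_true(rlos$adequate_range[1] <= 2 && 2 <= rlos$adequate_range[2])

  # every provenance is the stand-in marker
  provs <- vapply(kb$rules, `[[`, character(1), "provenance")
  expect_true(all(provs == "data-derived stand-in"))

  # non-time-limited residential care: stay length is not banded
  rv <- generate_services("residential_non_move_on", 8, seed = 6)
  kb2 <- default_knowledge_base(rv)
  expect_null(rtebench:::kb_lookup(kb2, "residential_non_move_on",
                                   "length_of_stay"))

  expect_error(default_knowledge_base(generate_services("supported_housing", 4,
                                                        seed = 1)),
               "at least 5")
})

test_that("DEA-ready vectors are oriented and strictly positive", {
  sv <- generate_services("supported_housing", 8, seed = 9)
  kb <- default_knowledge_base(sv)
  dv <- derive_variables(sv)
  sc <- build_scenarios("supported_housing")[[2]]
  mats <- transform_record(kb, dv, sc)

  expect_equal(dim(mats$X), c(8, 3))
  expect_equal(dim(mats$Y), c(8, 4))
  expect_true(all(mats$X > 0))
  expect_true(all(mats$Y >= 0))

  # identical services map to identical DEA vectors
  dv2 <- dv[c(1, 1), ]
  m2 <- transform_record(kb, dv2, sc)
  expect_equal(m2$X[1, ], m2$X[2, ])
  expect_equal(m2$Y[1, ], m2$Y[2, ])

  # best competence maps to the extreme DEA values
  r <- adequacy_rule("supported_housing", "budget_per_place", "input",
                     c(5000, 6000))
  expect_equal(1 / transform_value(r, 6000), 1)  # minimal input at competence 1
})

test_that("improving a variable's competence never worsens the deterministic score", {
  # two-service instance; push service 1's movers rate toward the adequate range
  base <- toy_services(n = 6)
  kb <- default_knowledge_base(base)
  sc <- build_scenarios("supported_housing")[[1]]
  dv <- derive_variables(validate_services(base))

  rule <- rtebench:::kb_lookup(kb, "supported_housing", "movers_per_place")
  worse <- dv; worse$movers_per_place[1] <- rule$adequate_range[1] - 0.3
  better <- dv; better$movers_per_place[1] <- rule$adequate_range[2]
  expect_gt(transform_value(rule, better$movers_per_place[1]),
            transform_value(rule, worse$movers_per_place[1]))

  th_worse <- dea(transform_record(kb, worse, sc)$X,
                  transform_record(kb, worse, sc)$Y)$theta[1]
  th_better <- dea(transform_record(kb, better, sc)$X,
                   transform_record(kb, better, sc)$Y)$theta[1]
  expect_gte(th_better, th_worse - 1e-9)
})
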