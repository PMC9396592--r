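test_that("generator honors its contract and is reproducible", {
  cfg <- synth_config(n_vars = 30, n_links = 45, seed = 11)
  gen <- generate_random_cld(cfg)
  expect_equal(n_variables(gen$model), 30)
  expect_equal(n_links(gen$model), 45)
  expect_equal(nrow(validate_model(gen$model)), 0)
  gen2 <- generate_random_cld(cfg)
  expect_identical(gen, gen2)
  # different seeds give different models
  gen3 <- generate_random_cld(synth_config(30, 45, seed = 12))
  expect_false(identical(gen$model$links, gen3$model$links))
})

test_that("generator tables round-trip through assembly", {
  gen <- generate_random_cld(synth_config(n_vars = 20, n_links = 30,
                                          seed = 7))
  m2 <- assemble_model(gen$model$variables, gen$model$links,
                       name = gen$model$name)
  expect_identical(gen$model, m2)
})

test_that("infeasible configurations fail before generation", {
  expect_error(synth_config(5, 25), class = "cld_feasibility_error")
  expect_error(synth_config(10, 20, hub_spec = 12),
               class = "cld_feasibility_error")
  expect_error(synth_config(10, 20, p_negative = 1.4),
               class = "cld_feasibility_error")
  expect_error(synth_config(10, 5, n_exogenous = 8),
               class = "cld_feasibility_error")
  expect_error(synth_config(10, 20, planted_archetypes = "unknown_arch"),
               class = "cld_feasibility_error")
})

test_that("with no negative links every loop is reinforcing", {
  gen <- generate_random_cld(synth_config(12, 30, p_negative = 0,
                                          seed = 5))
  loops <- enumerate_feedback_loops(gen$model)
  expect_gt(length(loops), 0)
  expect_true(all(vapply(loops, `[[`, character(1), "loop_class") ==
                  "reinforcing"))
})

test_that("planted truth is verifiable against the emitted model", {
  cfg <- synth_config(n_vars = 25, n_links = 45, n_exogenous = 5,
                      hub_spec = c(10, 8), planted_archetypes = "drifting_goals",
                      seed = 21)
  gen <- generate_random_cld(cfg)
  m <- gen$model; tr <- gen$truth
  d <- degree_summary(m)

  # exogenous: out-only by construction
  expect_length(tr$planted_exogenous, 5)
  for (x in tr$planted_exogenous) {
    expect_equal(d$in_degree[d$id == x], 0)
    expect_gt(d$out_degree[d$id == x], 0)
  }
  # hubs: exact planted densities
  expect_equal(tr$planted_hubs$density, c(10, 8))
  for (i in seq_len(nrow(tr$planted_hubs)))
    expect_equal(d$link_density[d$id == tr$planted_hubs$id[i]],
                 tr$planted_hubs$density[i])
  # planted loops exist with the intended class
  loops <- enumerate_feedback_loops(m)
  keys <- vapply(loops, function(lp) cycle_signature(lp$variable_cycle),
                 character(1))
  for (pl in tr$planted_loops) {
    j <- match(cycle_signature(pl$cycle), keys)
    expect_false(is.na(j))
    expect_equal(loops[[j]]$loop_class, pl$class)
  }
  # planted archetype binding is among the matches
  pb <- tr$planted_archetype_bindings[[1]]
  found <- match_template(m, builtin_templates()[[pb$template]], 1)
  bnds <- vapply(found, function(f) paste(f$role_binding, collapse = "|"),
                 character(1))
  expect_true(paste(pb$binding, collapse = "|") %in% bnds)
})

test_that("every entity carries at least one stakeholder source", {
  gen <- generate_random_cld(synth_config(15, 25, seed = 9))
  expect_true(all(nzchar(gen$model$variables$sources)))
  expect_true(all(nzchar(gen$model$links$sources)))
})

test_that("the paper-shaped preset reproduces the hub decile structure", {
  gen <- generate_random_cld(paper_shape_config(seed = 2))
  m <- gen$model
  expect_equal(n_variables(m), 94)
  expect_equal(n_links(m), 144)
  expect_length(gen$truth$planted_exogenous, 31)
  h <- find_hubs(m)
  expect_equal(h$threshold, 6)
  expect_equal(nrow(h$hubs), 10)
  expect_equal(sort(h$hubs$link_density, decreasing = TRUE),
               c(12, 9, 9, 8, 7, 7, 6, 6, 6, 6))
  expect_setequal(h$hubs$id, gen$truth$planted_hubs$id)
})

test_that("the staffing fixture encodes the expected loop structure", {
  m <- make_fig5_fixture()
  expect_equal(nrow(validate_model(m)), 0)
  loops <- label_loops(enumerate_feedback_loops(m), fig5_loop_registry())
  expect_gte(length(loops), 4)
  named <- loops[vapply(loops, function(lp)
    lp$label %in% c("R1", "B9", "B10", "B11"), logical(1))]
  expect_length(named, 4)
  classes <- stats::setNames(
    vapply(named, `[[`, character(1), "loop_class"),
    vapply(named, `[[`, character(1), "label"))
  expect_equal(classes[["R1"]], "reinforcing")
  expect_equal(classes[["B9"]], "balancing")
  expect_equal(classes[["B10"]], "balancing")
  expect_equal(classes[["B11"]], "balancing")
  expect_true("rurality" %in% find_exogenous_drivers(m)$exogenous)
})

test_that("recovery is perfect on an easy grid", {
  grid <- list(
    synth_config(n_vars = 20, n_links = 30, n_exogenous = 4,
                 hub_spec = c(10, 8), seed = 1),
    synth_config(n_vars = 22, n_links = 34, n_exogenous = 3,
                 planted_archetypes = "drifting_goals", seed = 1))
  res <- recovery_experiment(grid, n_reps = 10, seed = 123)
  expect_equal(res$exogenous_recovery, c(1, 1))
  expect_equal(res$hub_recovery[1], 1)
  expect_equal(res$loop_recovery[2], 1)
  expect_equal(res$archetype_recovery[2], 1)
  # deterministic under the same master seed
  expect_identical(res, recovery_experiment(grid, n_reps = 10, seed = 123))
})
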