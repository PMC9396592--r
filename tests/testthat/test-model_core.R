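test_that("assembly builds a valid model and auto-creates link endpoints", {
  m <- assemble_model(data.frame(label = c("A", "B")),
                      data.frame(from = "A", to = "B", polarity = "+"))
  expect_equal(n_variables(m), 2)
  expect_equal(n_links(m), 1)
  expect_equal(m$links$polarity, "positive")
  expect_equal(nrow(validate_model(m)), 0)

  # variables named only in link rows are auto-created and inherit the
  # link's provenance
  m2 <- assemble_model(NULL, data.frame(
    from = "Turnover", to = "Satisfaction", polarity = "-",
    sources = "veteran"))
  expect_setequal(m2$variables$id, c("turnover", "satisfaction"))
  expect_equal(m2$variables$sources, c("veteran", "veteran"))
})

test_that("assembly rejects conflicting duplicates, bad tokens and self-loops", {
  links <- data.frame(from = c("A", "A"), to = c("B", "B"),
                      polarity = c("+", "-"))
  expect_error(assemble_model(NULL, links), class = "cld_conflict_error")
  expect_error(assemble_model(NULL, data.frame(from = "A", to = "B",
                                               polarity = "?")),
               class = "cld_parse_error")
  expect_error(assemble_model(NULL, data.frame(from = "A", to = "A",
                                               polarity = "+")),
               class = "cld_selfloop_error")
  # agreeing duplicates merge with unioned provenance
  m <- assemble_model(NULL, data.frame(
    from = c("A", "a"), to = c("B", "B"), polarity = c("+", "same"),
    sources = c("veteran", "vso")))
  expect_equal(n_links(m), 1)
  expect_equal(m$links$sources, "veteran|vso")
})

test_that("assembly is permutation-invariant over input row order", {
  vars <- data.frame(label = c("A", "B", "C", "D"))
  links <- data.frame(from = c("A", "B", "C", "D"),
                      to = c("B", "C", "D", "A"),
                      polarity = c("+", "-", "+", "-"),
                      sources = c("veteran", "vso", "modeler", "va_system"))
  m1 <- assemble_model(vars, links)
  for (seed in 1:5) {
    set.seed(seed)
    m2 <- assemble_model(vars[sample(4), , drop = FALSE],
                         links[sample(4), , drop = FALSE])
    expect_identical(m1, m2)
  }
})

test_that("ids are normalized case-insensitively with collapsed whitespace", {
  m <- assemble_model(NULL, data.frame(
    from = c("VA  Provider Turnover", "va provider turnover"),
    to = c("X", "Y"), polarity = "+"))
  expect_equal(n_variables(m), 3)
  expect_true("va provider turnover" %in% m$variables$id)
})

test_that("opposite directions between two variables are distinct links", {
  m <- assemble_model(NULL, data.frame(
    from = c("A", "B"), to = c("B", "A"), polarity = c("+", "-")))
  expect_equal(n_links(m), 2)
  expect_setequal(m$links$polarity, c("positive", "negative"))
})

test_that("merge unions entities and provenance; merge with self is identity", {
  base <- assemble_model(NULL, data.frame(from = "A", to = "B",
                                          polarity = "+",
                                          sources = "veteran"))
  add <- assemble_model(
    data.frame(label = "C"),
    data.frame(from = "B", to = "C", polarity = "-", sources = "vso"))
  merged <- merge_models(base, add)
  expect_equal(n_variables(merged), 3)
  expect_equal(n_links(merged), 2)
  expect_identical(merge_models(base, base), base)
  # provenance union on a shared link
  add2 <- assemble_model(NULL, data.frame(from = "A", to = "B",
                                          polarity = "+", sources = "vso"))
  expect_equal(merge_models(base, add2)$links$sources, "veteran|vso")
})

test_that("merge conflict policies behave as contracted", {
  base <- assemble_model(NULL, data.frame(from = "A", to = "B",
                                          polarity = "+",
                                          sources = "veteran"))
  add <- assemble_model(NULL, data.frame(from = "A", to = "B",
                                         polarity = "-", sources = "vso"))
  expect_error(merge_models(base, add), class = "cld_conflict_error")
  pb <- merge_models(base, add, "prefer_base")
  expect_equal(pb$links$polarity, "positive")
  expect_equal(pb$links$sources, "veteran|vso")
  pa <- merge_models(base, add, "prefer_addition")
  expect_equal(pa$links$polarity, "negative")
  expect_equal(pa$links$sources, "veteran|vso")
})

test_that("merge is associative over disjoint additions", {
  a <- assemble_model(NULL, data.frame(from = "A", to = "B", polarity = "+"))
  b <- assemble_model(NULL, data.frame(from = "C", to = "D", polarity = "-"))
  cc <- assemble_model(NULL, data.frame(from = "E", to = "F", polarity = "+"))
  expect_identical(merge_models(merge_models(a, b), cc),
                   merge_models(a, merge_models(b, cc)))
})

test_that("diff is exact, invertible and empty on identical models", {
  before <- assemble_model(NULL, data.frame(
    from = c("A", "B"), to = c("B", "C"), polarity = c("+", "-")))
  expect_true(is_empty_diff(diff_models(before, before)))

  after <- assemble_model(
    data.frame(label = c("A", "B", "C", "D")),
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
               polarity = c("-", "-", "+")))
  d <- diff_models(before, after)
  expect_equal(d$added_variables, "d")
  expect_equal(d$added_links, "c -> d")
  expect_equal(length(d$removed_links), 0)
  expect_true("polarity" %in% d$changed$field)  # A->B flipped sign
  expect_identical(apply_diff(before, d), after)

  # pure deletion
  smaller <- assemble_model(data.frame(label = c("A", "B", "C")),
                            data.frame(from = "A", to = "B",
                                       polarity = "+"))
  d2 <- diff_models(before, smaller)
  expect_equal(d2$removed_links, "b -> c")
  expect_equal(length(d2$added_links), 0)
  expect_identical(apply_diff(before, d2), smaller)
})

test_that("diff/apply round-trips a validation-round-sized revision", {
  # revision adds 8 variables and 15 connections to a draft model
  base_links <- data.frame(
    from = sprintf("v%02d", 1:10), to = sprintf("v%02d", c(2:10, 1)),
    polarity = "+")
  before <- assemble_model(NULL, base_links)
  new_vars <- sprintf("w%02d", 1:8)
  extra <- data.frame(
    from = c(new_vars, sprintf("v%02d", 1:7)),
    to = c(sprintf("v%02d", 1:8), new_vars[c(1:7)]),
    polarity = rep(c("+", "-"), length.out = 15))
  after <- assemble_model(NULL, rbind(base_links, extra))
  d <- diff_models(before, after)
  expect_length(d$added_variables, 8)
  expect_length(d$added_links, 15)
  expect_length(d$removed_variables, 0)
  expect_length(d$removed_links, 0)
  expect_identical(apply_diff(before, d), after)
})

test_that("validate_model reports violations instead of raising", {
  m <- assemble_model(NULL, data.frame(from = c("A", "B"), to = c("B", "C"),
                                       polarity = "+"))
  expect_equal(nrow(validate_model(m)), 0)

  # bypass assembly: dangling link endpoint
  broken <- m
  broken$links <- rbind(broken$links, data.frame(
    from = "a", to = "zz", polarity = "positive", tags = "", sources = "",
    proposed = FALSE, note = ""))
  v <- validate_model(broken)
  expect_true("referential_integrity" %in% v$rule)

  # empty label
  broken2 <- m
  broken2$variables$label[1] <- "  "
  expect_true("nonempty_label" %in% validate_model(broken2)$rule)
})
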