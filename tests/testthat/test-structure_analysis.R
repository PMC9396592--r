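test_that("loop polarity follows the even/odd negative rule", {
  expect_equal(classify_loop_polarity(c("+", "-", "-")), "reinforcing")
  expect_equal(classify_loop_polarity(c("+", "+", "-")), "balancing")
  expect_equal(classify_loop_polarity(c("+", "+", "+", "+")), "reinforcing")
  expect_error(classify_loop_polarity(character(0)),
               class = "cld_argument_error")
})

test_that("polarity rule holds exhaustively for all sign vectors up to length 8", {
  for (len in 1:8) {
    grid <- expand.grid(rep(list(c("positive", "negative")), len),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      signs <- unlist(grid[i, ], use.names = FALSE)
      expected <- if (sum(signs == "negative") %% 2 == 0)
        "reinforcing" else "balancing"
      expect_equal(classify_loop_polarity(signs), expected)
    }
  }
})

test_that("small cycles enumerate as expected", {
  two <- assemble_model(NULL, data.frame(from = c("A", "B"),
                                         to = c("B", "A"), polarity = "+"))
  loops <- enumerate_feedback_loops(two)
  expect_length(loops, 1)
  expect_equal(loops[[1]]$variable_cycle, c("a", "b"))
  expect_equal(loops[[1]]$loop_class, "reinforcing")

  dag <- assemble_model(NULL, data.frame(from = c("A", "A", "B"),
                                         to = c("B", "C", "C"),
                                         polarity = "+"))
  expect_length(enumerate_feedback_loops(dag), 0)
})

test_that("complete digraphs have the closed-form simple-cycle counts", {
  # sum over k=2..n of choose(n,k)*(k-1)!
  expected <- c(`2` = 1, `3` = 5, `4` = 20, `5` = 84)
  for (n in 2:5) {
    loops <- enumerate_feedback_loops(complete_digraph(n))
    expect_length(loops, expected[[as.character(n)]])
  }
})

test_that("enumeration matches the brute-force DFS oracle on random models", {
  for (seed in 1:40) {
    n <- sample(3:10, 1)
    m <- random_small_model(n, sample(n:(2 * n), 1), seed)
    got <- vapply(enumerate_feedback_loops(m), function(lp)
      cycle_signature(lp$variable_cycle), character(1))
    want <- vapply(brute_force_cycles(m), cycle_signature, character(1))
    expect_setequal(got, want)
    expect_false(any(duplicated(got)))
  }
})

test_that("canonical rotation and deterministic ordering are stable", {
  m <- complete_digraph(4)
  a <- enumerate_feedback_loops(m)
  b <- enumerate_feedback_loops(m)
  expect_identical(a, b)
  for (lp in a) {
    ids <- lp$variable_cycle
    expect_equal(ids[1], min(ids))  # canonical rotation
  }
  lens <- vapply(a, function(lp) length(lp$variable_cycle), integer(1))
  expect_true(all(diff(lens) >= 0))  # sorted by length first
})

test_that("max_length and the safety cap bound enumeration", {
  m <- complete_digraph(5)
  short <- enumerate_feedback_loops(m, max_length = 2)
  expect_length(short, choose(5, 2))
  expect_error(enumerate_feedback_loops(m, max_count = 10),
               class = "cld_enumeration_error")
})

test_that("flipping one link's sign flips exactly the loops through it", {
  m <- random_small_model(6, 10, seed = 99)
  loops_before <- enumerate_feedback_loops(m)
  # flip the first link
  m2 <- m
  i <- 1
  flip_from <- m2$links$from[i]; flip_to <- m2$links$to[i]
  m2$links$polarity[i] <- setdiff(polarities(), m2$links$polarity[i])
  loops_after <- enumerate_feedback_loops(m2)
  key <- function(lp) cycle_signature(lp$variable_cycle)
  before <- stats::setNames(vapply(loops_before, `[[`, character(1),
                                   "loop_class"),
                            vapply(loops_before, key, character(1)))
  after <- stats::setNames(vapply(loops_after, `[[`, character(1),
                                  "loop_class"),
                           vapply(loops_after, key, character(1)))
  expect_setequal(names(before), names(after))
  uses_link <- function(lp) {
    ids <- lp$variable_cycle
    nxt <- c(ids[-1], ids[1])
    any(ids == flip_from & nxt == flip_to)
  }
  flipped <- vapply(loops_before, uses_link, logical(1))
  for (j in seq_along(loops_before)) {
    k <- key(loops_before[[j]])
    if (flipped[j]) expect_false(before[[k]] == after[[k]])
    else expect_equal(before[[k]], after[[k]])
  }
})

test_that("degree summary is consistent with the link count", {
  m <- make_fig5_fixture()
  d <- degree_summary(m)
  expect_equal(sum(d$in_degree), n_links(m, include_proposed = FALSE))
  expect_equal(sum(d$out_degree), n_links(m, include_proposed = FALSE))
  expect_equal(d$link_density, d$in_degree + d$out_degree)
})

test_that("proposed links are excluded from structural analysis by default", {
  m <- assemble_model(NULL, data.frame(
    from = c("A", "B"), to = c("B", "A"), polarity = "+",
    proposed = c(FALSE, TRUE)))
  expect_length(enumerate_feedback_loops(m), 0)
  expect_length(enumerate_feedback_loops(m, include_proposed = TRUE), 1)
  expect_equal(sum(degree_summary(m)$link_density), 2)
  expect_equal(sum(degree_summary(m, include_proposed = TRUE)$link_density), 4)
})

test_that("exogenous/sink/orphan classification follows the degree pattern", {
  m <- assemble_model(
    data.frame(label = c("Exo", "Mid", "Sink", "Orphan")),
    data.frame(from = c("Exo", "Mid"), to = c("Mid", "Sink"),
               polarity = "+"))
  r <- find_exogenous_drivers(m)
  expect_equal(r$exogenous, "exo")
  expect_equal(r$sinks, "sink")
  expect_equal(r$orphans, "orphan")  # no links: orphan, not exogenous
  expect_equal(r$interior, "mid")
  # the four lists partition the variables
  expect_setequal(c(r$exogenous, r$sinks, r$orphans, r$interior),
                  m$variables$id)
})

test_that("no exogenous or orphan variable ever appears in a loop", {
  for (seed in 1:10) {
    gen <- generate_random_cld(synth_config(15, 25, n_exogenous = 4,
                                            seed = seed))
    r <- find_exogenous_drivers(gen$model)
    in_loops <- unique(unlist(lapply(enumerate_feedback_loops(gen$model),
                                     `[[`, "variable_cycle")))
    expect_length(intersect(c(r$exogenous, r$orphans), in_loops), 0)
  }
})

test_that("hub threshold is the k-th largest density with ties included", {
  # n=10 densities 7,3,3,2,2,2,2,1,1,1 -> k=1, threshold 7, one hub
  links <- data.frame(
    from = c("H", "H", "H", "H", "H", "I", "J", "B", "B", "C", "F", "G"),
    to = c("B", "C", "D", "E", "F", "H", "H", "C", "D", "E", "K", "I"),
    polarity = "+")
  m <- assemble_model(NULL, links)
  d <- degree_summary(m)
  expect_equal(sort(d$link_density, decreasing = TRUE),
               c(7, 3, 3, 2, 2, 2, 2, 1, 1, 1))
  h <- find_hubs(m)
  expect_equal(h$threshold, 7)
  expect_equal(h$hubs$id, "h")
  expect_error(find_hubs(m, decile = 1.2), class = "cld_argument_error")
})

test_that("all-equal densities are a degenerate hub report with warning", {
  m <- assemble_model(NULL, data.frame(from = c("A", "B", "C"),
                                       to = c("B", "C", "A"),
                                       polarity = "+"))
  expect_warning(h <- find_hubs(m), class = "cld_degenerate_warning")
  expect_equal(nrow(h$hubs), 3)
  expect_true(h$degenerate)
})

test_that("raising the decile never increases the hub count", {
  m <- generate_random_cld(paper_shape_config(seed = 4))$model
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95), function(q)
    nrow(find_hubs(m, decile = q)$hubs), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("registry labels attach to loops and unmatched entries warn", {
  m <- make_fig5_fixture()
  loops <- enumerate_feedback_loops(m)
  labelled <- label_loops(loops, fig5_loop_registry())
  labs <- vapply(labelled, `[[`, character(1), "label")
  expect_true(all(c("R1", "B9", "B10", "B11") %in% labs))
  expect_false(any(duplicated(labs)))

  # empty registry: systematic names
  plain <- label_loops(loops)
  expect_true(all(grepl("^loop_\\d{4}$",
                        vapply(plain, `[[`, character(1), "label"))))

  expect_warning(
    label_loops(loops, list(R9 = c("nowhere", "else"))),
    class = "cld_unmatched_label_warning")
})
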