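test_that("variable accounting: one integer state per node and condition", {
  single <- signaling_network(
    nodes = data.frame(id = "A", role = "protein", observed = FALSE),
    edges = data.frame(source = character(), target = character(),
                       sign = integer()))
  prob1 <- build_training_problem(
    single, matrix(NA_integer_, 0, 1, dimnames = list(NULL, "c1")))
  acc1 <- variable_accounting(prob1)
  expect_equal(sum(acc1$n[acc1$domain == "integer"]), 1)

  net3 <- signaling_network(
    nodes = data.frame(id = c("A", "B", "C"), role = "protein", observed = TRUE),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1L))
  prof <- toy_profile(matrix(0L, 3, 2, dimnames = list(c("A", "B", "C"), NULL)))
  acc3 <- variable_accounting(build_training_problem(net3, prof))
  expect_equal(sum(acc3$n[acc3$domain == "integer"]), 6)
  expect_true(all(acc3$domain[acc3$family != "x"] == "binary"))
})

test_that("ternary product linearization is exact on all nine combinations", {
  split_sign <- function(v) c(plus = as.integer(v == 1), minus = as.integer(v == -1))
  for (u in -1:1) {
    for (d in -1:1) {
      us <- split_sign(u); ds <- split_sign(d)
      lin <- linearize_product(us["plus"], us["minus"], ds["plus"], ds["minus"])
      expect_equal(lin$p, u * d)
      expect_true(all(lin$w %in% 0:1))
    }
  }
})

test_that("a single matched activation edge fits perfectly", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  oracle <- brute_force_solve(net, prof)
  expect_equal(oracle$objective, 0)
  expect_equal(oracle$states["A", "c1"], 1L)
  expect_equal(oracle$states["B", "c1"], 1L)

  prob <- build_training_problem(net, prof)
  sol <- solve_problem(prob)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  dec <- decode_solution(prob, sol)
  expect_equal(dec$states["A", "c1"], 1)
  expect_equal(dec$states["B", "c1"], 1)
  expect_true(dec$occurrences["A->B", "c1"])
  expect_equal(dec$removed, character())
})

test_that("with no observations the optimum removes every candidate edge", {
  net <- toy_edge_net(observed = c(A = FALSE, B = FALSE))
  prof <- as_ternary_profile(matrix(NA_integer_, 0, 1,
                                    dimnames = list(NULL, "c1")))
  prob <- build_training_problem(net, prof)
  sol <- solve_problem(prob)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$fit_term, 0)
  expect_equal(sol$simplicity_term, 1)
  expect_equal(sol$objective, prob$gamma)
})

test_that("problem construction validates its inputs", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(0L, 2, 1, dimnames = list(c("A", "B"), NULL)))
  expect_error(build_training_problem(net, prof, gamma = 0.5), "gamma")
  expect_error(build_training_problem(net, prof, gamma = -2), "gamma")
  bad_prof <- toy_profile(matrix(0L, 1, 1, dimnames = list("Z", NULL)))
  expect_error(build_training_problem(net, bad_prof), "not in network")
  expect_error(
    build_training_problem(net, prof,
                           prior = data.frame(condition = "c9", node = "A",
                                              direction = 1L)),
    "not in profile")

  out_net <- signaling_network(
    nodes = data.frame(id = c("TF1", "OUT"),
                       role = c("transcription_factor", "output"),
                       observed = c(TRUE, FALSE)),
    edges = data.frame(source = "TF1", target = "OUT", sign = 1L))
  oprof <- toy_profile(matrix(0L, 1, 1, dimnames = list("TF1", NULL)))
  expect_error(
    build_training_problem(out_net, oprof,
                           prior = data.frame(condition = "c1", node = "OUT",
                                              direction = 1L)),
    "output")
})

test_that("output-node states equal the signed sum of their factors", {
  net <- signaling_network(
    nodes = data.frame(id = c("TF1", "TF2", "OUT"),
                       role = c("transcription_factor",
                                "transcription_factor", "output"),
                       observed = c(TRUE, TRUE, FALSE)),
    edges = data.frame(source = c("TF1", "TF2"), target = "OUT",
                       sign = c(1L, -1L)))
  prof <- toy_profile(matrix(c(1L, -1L), 2, 1,
                             dimnames = list(c("TF1", "TF2"), NULL)))
  prob <- build_training_problem(net, prof)
  sol <- solve_problem(prob)
  dec <- decode_solution(prob, sol)
  expect_equal(sol$fit_term, 0)
  expect_equal(dec$states["OUT", "c1"], 2)  # (+1) - (-1)
})

test_that("mismatch indicators equal the disagreement they penalize", {
  # a prior pinned against the observation makes one mismatch unavoidable
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  prior <- data.frame(condition = "c1", node = "A", direction = -1L)
  prob <- suppressMessages(build_training_problem(net, prof, prior))
  sol <- solve_problem(prob)
  expect_equal(sol$status, "optimal")
  dec <- decode_solution(prob, sol)
  v <- sol$values
  for (j in c("A", "B")) {
    a <- v[[paste("a", j, "c1", sep = "|")]]
    expect_equal(a, as.numeric(dec$states[j, "c1"] != prof[j, "c1"]))
  }
  # pinning A to -1 leaves B without a positive deliverer, so both
  # observed +1 entries become unavoidable mismatches
  expect_equal(sol$fit_term, 2)
})

test_that("prediction problems drop the removal machinery", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  prob <- build_prediction_problem(net, prof)
  acc <- variable_accounting(prob)
  expect_false("y" %in% acc$family)
  sol <- solve_problem(prob)
  expect_equal(sol$objective, 0)
  expect_equal(sol$simplicity_term, 0)
})

test_that("LP export writes a readable model", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  prob <- build_training_problem(net, prof)
  lp <- withr::local_tempfile(fileext = ".lp")
  write_lp(prob, lp)
  txt <- readLines(lp)
  expect_true(any(txt == "Minimize"))
  expect_true(any(txt == "Subject To"))
  expect_true(any(grepl("^Bounds", txt)))
})
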