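test_that("the exact permutation test gives 1/n! for strictly monotone events", {
  ev <- data.frame(age_ma = c(10.7, 9.3, 2.4, 1.1, 1.0),
                   t_cold = c(6, 4, -4, -8, -10),
                   t_warm = c(20, 18, 12, 8, 6))
  res <- tolerance_trend_test(ev, "cold")
  expect_equal(res$p_value, 1 / 120, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$statistic, 0.9)

  # sign-flipped character reverses the one-sided p (up to the tie at the
  # observed ordering itself)
  ev2 <- ev; ev2$t_cold <- -ev$t_cold
  res2 <- tolerance_trend_test(ev2, "cold")
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  # p-values live on the k/n! grid
  expect_equal(res$p_value * 120, round(res$p_value * 120))
})

test_that("a constant character yields p = 1 with a warning, not an error", {
  ev <- data.frame(age_ma = c(5, 3, 1), t_cold = c(2, 2, 2),
                   t_warm = c(9, 9, 9))
  expect_warning(res <- tolerance_trend_test(ev, "cold"), "constant")
  expect_equal(res$p_value, 1)
  expect_error(tolerance_trend_test(ev[1:2, ], "cold"), "3 events")
})

test_that("rank-based permutation p is invariant to monotone age transforms", {
  ev <- data.frame(age_ma = c(10.7, 9.3, 2.4, 1.1, 1.0),
                   t_cold = c(6, 2, -4, -9, -8),
                   t_warm = c(20, 16, 12, 7, 8))
  p1 <- tolerance_trend_test(ev, "cold", rank_based = TRUE)$p_value
  ev2 <- ev; ev2$age_ma <- log(ev$age_ma)
  p2 <- tolerance_trend_test(ev2, "cold", rank_based = TRUE)$p_value
  ev3 <- ev; ev3$age_ma <- ev$age_ma^3
  p3 <- tolerance_trend_test(ev3, "cold", rank_based = TRUE)$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("alternative trend methods agree on direction", {
  ev <- data.frame(age_ma = c(10.7, 9.3, 2.4, 1.1, 1.0),
                   t_cold = c(6, 4, -4, -8, -10),
                   t_warm = c(20, 18, 12, 8, 6))
  tt <- tolerance_trend_test(ev, "cold", method = "t_test")
  expect_lt(tt$p_value, 0.05)
  set.seed(66)
  pb <- tolerance_trend_test(ev, method = "posterior_beta",
                             beta_samples = rnorm(1000, -30, 5))
  expect_lt(pb$p_value, 0.01)
})

test_that("beringia_match reports matches and distances against the curve", {
  ser <- sim_delta18o(n_samples = 150, noise_sd = 0, seed = 3)
  curve <- calibrate_paleocurve(running_mean(ser, 25))
  ev <- data.frame(clade = c("a", "b"), age_ma = c(0, 0),
                   t_cold = c(-10, 0), t_warm = c(5, 12))
  m <- beringia_match(ev, curve)
  expect_equal(m$beringia_temp_c, c(-9, -9), tolerance = 1e-10)
  expect_identical(m$match, c(TRUE, FALSE))
  expect_equal(m$distance_c[2], 9, tolerance = 1e-10)

  # margin -> infinity matches everything
  m_inf <- beringia_match(ev, curve, margin = 1e6)
  expect_true(all(m_inf$match))

  expect_error(beringia_match(data.frame(clade = "z", age_ma = 99,
                                         t_cold = 0, t_warm = 1), curve),
               "z")
})

test_that("a synthetic scenario with straddling tolerances matches end to end", {
  ser <- sim_delta18o(n_samples = 200, noise_sd = 0.05, seed = 4)
  curve <- calibrate_paleocurve(running_mean(ser, 50))
  ages <- c(10.7, 9.3, 2.4, 1.1, 1.0)
  bt <- temp_at(curve, ages)
  ev <- data.frame(clade = paste0("anc", 1:5), age_ma = ages,
                   t_cold = bt - 3, t_warm = bt + 3)
  m <- beringia_match(ev, curve)
  expect_true(all(m$match))
  expect_equal(m$distance_c, rep(0, 5))
})

test_that("parsimony reconstruction matches trivial and exhaustive cases", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  allsame <- stats::setNames(rep("Fabaceae", 4), c("A", "B", "C", "D"))
  f <- fitch_mp(tr, allsame)
  expect_equal(f$score, 0)
  expect_true(all(vapply(f$node_states, identical, TRUE, "Fabaceae")))
  expect_error(fitch_mp(tr, allsame[1:3]), "uncoded")

  trees <- list(
    read_newick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);"),
    read_newick("(((A:1,B:1):1,C:1):1,(D:1,(E:1,F:1):1):1);"),
    read_newick("((A:1,B:1,C:1):1,(D:1,E:1):1);"))   # polytomy
  set.seed(55)
  for (tr in trees) {
    tips <- tr$tip.label
    for (rep in 1:8) {
      st <- stats::setNames(sample(c("F", "P", "E"), length(tips),
                                   replace = TRUE), tips)
      got <- fitch_mp(tr, st)
      want <- oracle_sankoff(tr, st)
      expect_equal(got$score, want$score)
      for (nd in names(want$node_states)) {
        expect_equal(sort(got$node_states[[nd]]), want$node_states[[nd]])
      }
    }
  }
})

test_that("the fixture hostplant history reconstructs the published states", {
  fx <- fixture_polyommatus()
  nodes <- fx$nodes()
  f <- fitch_mp(fx$chronogram, fx$hostplants, nodes = nodes)
  expect_identical(f$node_states[[as.character(nodes[["Neotropical"]])]],
                   "Fabaceae")
  expect_identical(f$node_states[[as.character(nodes[["Icaricia-Plebulina"]])]],
                   "Fabaceae")
  expect_identical(f$node_states[[as.character(nodes[["Lycaeides"]])]],
                   "Fabaceae")
  expect_identical(f$node_states[[as.character(nodes[["Agriades"]])]],
                   "Primulaceae")
  expect_identical(f$node_states[[as.character(nodes[["Vacciniina"]])]],
                   "Ericaceae")
})
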