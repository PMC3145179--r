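test_that("tree simulation is deterministic and unit-tagged", {
  a <- sim_tree(12, seed = 7)
  b <- sim_tree(12, seed = 7)
  expect_identical(write_newick(a$chronogram), write_newick(b$chronogram))
  expect_identical(write_newick(a$phylogram), write_newick(b$phylogram))
  expect_identical(length_unit(a$chronogram), "Ma")
  expect_identical(length_unit(a$phylogram), "subs_per_site")
  expect_true(ape::is.ultrametric(a$chronogram, tol = 1e-8))

  two <- sim_tree(2, seed = 8)$chronogram
  expect_equal(ape::Ntip(two), 2)
  expect_error(sim_tree(1, seed = 1), "n must")
  expect_error(sim_tree(5, birth = 0.1, death = 0.2, seed = 1), "birth")
})

test_that("pure-birth trees carry the generating speciation rate", {
  # independent check through ape's Yule ML estimator, averaged over seeds
  birth <- 0.35
  est <- vapply(1:200, function(s) {
    tr <- sim_tree(25, birth = birth, death = 0, seed = 10000 + s)$chronogram
    ape::yule(tr)$lambda
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - birth), 4 * se + 0.02)
})

test_that("trait simulation honours degenerate and directional settings", {
  tr <- sim_tree(10, seed = 20)$phylogram
  z <- sim_bm_traits(tr, alpha = c(3, 9), beta = c(0, 0),
                     Sigma = matrix(0, 2, 2), seed = 21)
  expect_equal(unname(z$tips), matrix(rep(c(3, 9), each = 10), 10, 2),
               tolerance = 1e-6)

  # deterministic under seed
  s1 <- sim_bm_traits(tr, alpha = c(0, 1), Sigma = diag(2), seed = 22)
  s2 <- sim_bm_traits(tr, alpha = c(0, 1), Sigma = diag(2), seed = 22)
  expect_identical(s1$tips, s2$tips)
  expect_identical(s1$nodes, s2$nodes)

  # a negative cold-trend makes deeper-path tips colder on average
  deep_minus_shallow <- vapply(1:40, function(s) {
    st <- sim_tree(16, seed = 30 + s, rate_sd = 0.6)
    sim <- sim_bm_traits(st$phylogram, alpha = c(0, 10), beta = c(-80, 0),
                         Sigma = diag(c(1e-4, 1e-4)), seed = 60 + s)
    d <- beringia:::node_depths(st$phylogram)[1:16]
    stats::cor(d, sim$tips[, 1])
  }, numeric(1))
  expect_lt(mean(deep_minus_shallow), -0.9)
})

test_that("simulated tip covariance matches the lambda-transformed closed form", {
  tr <- read_newick("((A:1,B:2):0.5,(C:0.7,D:1.1):1.3);")
  Sigma <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  lam <- 0.7
  reps <- 2000
  acc <- matrix(0, 8, 8)
  for (r in 1:reps) {
    z <- sim_bm_traits(tr, alpha = c(0, 0), Sigma = Sigma, lambda = lam,
                       seed = 40000 + r)
    v <- c(z$tips[, 1], z$tips[, 2])
    acc <- acc + tcrossprod(v)
  }
  emp <- acc / reps
  want <- kronecker(Sigma, beringia:::lambda_vcv(phylo_vcv(tr), lam))
  expect_lt(max(abs(emp - want)), 0.05 * max(abs(want)) + 0.05)
})

test_that("DEC forward simulation inherits, records, and reproduces", {
  ar <- toy_areas3()
  tr <- sim_tree(12, seed = 70)$chronogram
  no_disp <- sim_dec_ranges(tr, ar, d = 0, e = 0, root_range = "B",
                            cap = 2, seed = 71)
  expect_true(all(vapply(no_disp$tip_ranges, identical, TRUE, "B")))
  expect_equal(nrow(no_disp$events), 0)

  a <- sim_dec_ranges(tr, ar, d = 0.1, e = 0.02, root_range = "A", seed = 72)
  b <- sim_dec_ranges(tr, ar, d = 0.1, e = 0.02, root_range = "A", seed = 72)
  expect_identical(a$events, b$events)
  expect_identical(a$tip_ranges, b$tip_ranges)
})

test_that("forward-simulated event counts follow the analytic dispersal rate", {
  # near-degenerate cherry: one long branch of t Ma, the other negligible;
  # from root {B} (two neighbours) with e = 0 and rare events the count of
  # first gains is Poisson(d * t * 2) to first order
  ar <- toy_areas3()
  tr <- read_newick("(X:4,Y:0.0001);", "Ma")
  d <- 0.01
  counts <- vapply(1:500, function(s) {
    sim <- sim_dec_ranges(tr, ar, d = d, e = 0, root_range = "B",
                          cap = 3, seed = 20000 + s)
    sum(sim$events$child_node == 1)
  }, numeric(1))
  lam <- d * 4 * 2
  expect_lt(abs(mean(counts) - lam), 4 * stats::sd(counts) / sqrt(500) + 0.01)
})

test_that("the delta-18O simulator produces the documented trend", {
  flat <- sim_delta18o(n_samples = 120, noise_sd = 0, seed = 1)
  fit <- stats::lm(d18o_permil ~ age_ma, data = flat)
  expect_equal(unname(fit$coefficients[1]), 4.2, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[2]), (2.0 - 4.2) / 14, tolerance = 1e-9)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)

  a <- sim_delta18o(seed = 2); b <- sim_delta18o(seed = 2)
  expect_identical(a, b)
  expect_error(sim_delta18o(n_samples = 50), "100")
  expect_error(sim_delta18o(noise_sd = -1), "noise_sd")

  # smoothing a noisy series tracks the noiseless trend within theory bounds
  ok <- 0; tot <- 0
  for (s in 1:50) {
    noisy <- sim_delta18o(n_samples = 200, noise_sd = 0.2, seed = 300 + s)
    sm <- running_mean(noisy, 50)
    trend <- 4.2 + (2.0 - 4.2) * sm$age_ma / 14
    core <- 51:150
    dev <- abs(sm$d18o_smoothed[core] - trend[core])
    ok <- ok + sum(dev < 3 * 0.2 / sqrt(50))
    tot <- tot + length(core)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("the fixture encodes the published backbone and colonization ages", {
  fx <- fixture_polyommatus()
  expect_identical(length_unit(fx$chronogram), "Ma")
  nodes <- fx$nodes()
  ages <- beringia:::node_ages_chronogram(fx$chronogram)[nodes]
  expect_equal(unname(ages), c(10.7, 9.3, 2.4, 1.1, 1.0), tolerance = 1e-9)

  # the Neotropical taxa form a clade excluding all Nearctic-only genera
  neo <- c("Echinargus_isola", "Hemiargus_hanno", "Cyclargus_ammon",
           "Pseudolucia_chilensis", "Nabokovia_faga")
  anc <- mrca_node(fx$chronogram, neo)
  below <- beringia:::descendant_tips(fx$chronogram)[[anc]]
  expect_setequal(fx$chronogram$tip.label[below], neo)

  # all tip areas belong to the ten-area system; OW/NW split species appear
  # twice with disjoint ranges
  expect_true(all(unlist(fx$tip_ranges) %in% fx$areas$areas))
  for (sp in c("Lycaeides_idas", "Agriades_glandon", "Vacciniina_optilete")) {
    ow <- fx$tip_ranges[[paste0(sp, "_OW")]]
    nw <- fx$tip_ranges[[paste0(sp, "_NW")]]
    expect_length(intersect(ow, nw), 0)
  }
  # phylogram is deterministic and non-clock (directional model identifiable)
  fx2 <- fixture_polyommatus()
  expect_identical(write_newick(fx$phylogram), write_newick(fx2$phylogram))
  d <- beringia:::node_depths(fx$phylogram)[1:19]
  expect_gt(stats::sd(d) / mean(d), 0.01)
})
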