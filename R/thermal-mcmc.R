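#' MCMC run-length configuration
#'
#' Two presets: `"desk"` (200,000 iterations, burn-in 5,000, sample period
#' 100) sized for interactive use and the test suite, and `"paper"`
#' (5,000,000 iterations, burn-in 5,000, sample period 100) matching the
#' published analysis settings. Any field can be overridden.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param iterations,burn_in,sample_period Overrides.
#' @param proposal_scales Optional named list overriding proposal standard
#'   deviations for the blocks `alpha`, `beta`, `sigma_log`, `rho`, `lambda`,
#'   `delta`, `kappa` (alpha/beta scales are relative to the data scale).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(preset = c("desk", "paper"), iterations = NULL,
                        burn_in = NULL, sample_period = NULL,
                        proposal_scales = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(iterations = 2e5, burn_in = 5e3, sample_period = 100),
    paper = list(iterations = 5e6, burn_in = 5e3, sample_period = 100))
  if (!is.null(iterations)) cfg$iterations <- iterations
  if (!is.null(burn_in)) cfg$burn_in <- burn_in
  if (!is.null(sample_period)) cfg$sample_period <- sample_period
  if (cfg$iterations <= cfg$burn_in) stop("iterations must exceed burn_in")
  if (cfg$sample_period < 1) stop("sample_period must be >= 1")
  cfg$proposal_scales <- utils::modifyList(
    list(alpha = 0.2, beta = 0.15, sigma_log = 0.08, rho = 0.05,
         lambda = 0.04, delta = 0.1, kappa = 0.1),
    if (is.null(proposal_scales)) list() else proposal_scales)
  cfg$preset <- preset
  class(cfg) <- "mcmc_config"
  cfg
}

# Metropolis-Hastings kernel shared by fit_mcmc() and stepping_stone().
# `power` tempers the likelihood (power = 0 samples the prior).
bm_mcmc_kernel <- function(x, tree, model, config, seed, power = 1,
                           estimate_delta = FALSE, estimate_kappa = FALSE,
                           lambda_fixed = NULL) {
  x <- align_traits(x, tree)
  n <- nrow(x)
  directional <- model == "B"
  set.seed(seed)
  v_data <- mean(apply(x, 2, stats::var))
  if (!is.finite(v_data) || v_data <= 0) v_data <- 1
  sd_data <- pmax(apply(x, 2, stats::sd), 0.1 * sqrt(v_data))
  base_tf <- transform_tree(tree, 1, 1, 1)
  depth_scale <- max(stats::sd(base_tf$depths), 1e-3 * mean(base_tf$depths),
                     1e-12)

  ls_lo <- 0.5 * log(1e-6 * v_data); ls_hi <- 0.5 * log(1e6 * v_data)
  prior_sd_alpha <- 1e3 * sd_data
  prior_sd_beta <- 1e3 * sd_data / depth_scale

  make_cache <- function(lambda, delta, kappa) {
    if (delta == 1 && kappa == 1) {
      V0 <- base_tf$V; depths <- base_tf$depths
    } else {
      tf <- transform_tree(tree, 1, delta, kappa)
      V0 <- tf$V; depths <- tf$depths
    }
    V <- lambda_vcv(V0, lambda)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    list(R = R, ldV = 2 * sum(log(diag(R))),
         Zx = backsolve(R, x, transpose = TRUE),
         Zd = backsolve(R, cbind(depths), transpose = TRUE)[, 1],
         Z1 = backsolve(R, cbind(rep(1, n)), transpose = TRUE)[, 1],
         depths = depths)
  }
  loglik_cached <- function(cache, alpha, beta, ls, rho) {
    s1 <- exp(2 * ls[1]); s2 <- exp(2 * ls[2]); s12 <- rho * exp(sum(ls))
    detS <- s1 * s2 - s12^2
    if (detS <= 0) return(-Inf)
    ZE1 <- cache$Zx[, 1] - alpha[1] * cache$Z1 - beta[1] * cache$Zd
    ZE2 <- cache$Zx[, 2] - alpha[2] * cache$Z1 - beta[2] * cache$Zd
    m11 <- sum(ZE1 * ZE1); m22 <- sum(ZE2 * ZE2); m12 <- sum(ZE1 * ZE2)
    quad <- (s2 * m11 - 2 * s12 * m12 + s1 * m22) / detS
    -n * log(2 * pi) - cache$ldV - n / 2 * log(detS) - 0.5 * quad
  }
  logprior <- function(alpha, beta, ls, rho, lambda, delta, kappa) {
    if (any(ls < ls_lo) || any(ls > ls_hi)) return(-Inf)
    if (rho <= -1 || rho >= 1) return(-Inf)
    if (lambda < 0 || lambda > 1) return(-Inf)
    if (delta <= 0 || delta > 3 || kappa < 0 || kappa > 3) return(-Inf)
    sum(stats::dnorm(alpha, 0, prior_sd_alpha, log = TRUE)) +
      (if (directional)
         sum(stats::dnorm(beta, 0, prior_sd_beta, log = TRUE)) else 0)
  }

  # start near the profile ML fit
  ml <- tryCatch(
    bm_profile_fit(x, base_tf$V, base_tf$depths, directional,
                   lambda = lambda_fixed),
    error = function(e) NULL)
  if (!is.null(ml)) {
    alpha <- ml$alpha; beta <- if (directional) ml$beta else c(0, 0)
    ls <- 0.5 * log(pmax(diag(ml$Sigma), 1e-6 * v_data))
    rho <- ml$Sigma[1, 2] / sqrt(prod(pmax(diag(ml$Sigma), 1e-12)))
    rho <- min(max(rho, -0.95), 0.95)
    lambda <- min(max(ml$lambda, 0.02), 0.98)
  } else {
    alpha <- colMeans(x); beta <- c(0, 0)
    ls <- 0.5 * log(pmax(apply(x, 2, stats::var), 1e-6)); rho <- 0
    lambda <- 0.5
  }
  if (!is.null(lambda_fixed)) lambda <- lambda_fixed
  delta <- 1; kappa <- 1

  ps <- config$proposal_scales
  sc_alpha <- ps$alpha * sd_data
  sc_beta <- ps$beta * sd_data / depth_scale

  blocks <- c("alpha", "sigma")
  if (directional) blocks <- c(blocks, "beta")
  if (is.null(lambda_fixed)) blocks <- c(blocks, "lambda")
  if (estimate_delta) blocks <- c(blocks, "delta")
  if (estimate_kappa) blocks <- c(blocks, "kappa")

  cache <- make_cache(lambda, delta, kappa)
  if (is.null(cache)) stop("initial covariance is singular")
  ll <- loglik_cached(cache, alpha, beta, ls, rho)
  lp <- logprior(alpha, beta, ls, rho, lambda, delta, kappa)
  post <- power * ll + lp
  if (!is.finite(post)) stop("non-finite initial posterior")

  iters <- config$iterations
  keep_at <- seq_len(iters)
  keep_at <- keep_at[keep_at > config$burn_in &
                     (keep_at - config$burn_in) %% config$sample_period == 0]
  n_keep <- length(keep_at)
  samples <- matrix(NA_real_, n_keep, 12,
                    dimnames = list(NULL, c(
                      "iteration", "alpha_cold", "alpha_warm", "beta_cold",
                      "beta_warm", "sigma11", "sigma12", "sigma22",
                      "lambda", "delta", "kappa", "loglik")))
  acc <- stats::setNames(numeric(length(blocks)), blocks)
  tries <- stats::setNames(numeric(length(blocks)), blocks)
  k_out <- 1L
  block_draw <- sample.int(length(blocks), iters, replace = TRUE)
  for (it in seq_len(iters)) {
    bl <- blocks[block_draw[it]]
    tries[bl] <- tries[bl] + 1
    a2 <- alpha; b2 <- beta; ls2 <- ls; rho2 <- rho
    lam2 <- lambda; del2 <- delta; kap2 <- kappa
    cache2 <- cache
    if (bl == "alpha") {
      a2 <- alpha + stats::rnorm(2, 0, sc_alpha)
    } else if (bl == "beta") {
      b2 <- beta + stats::rnorm(2, 0, sc_beta)
    } else if (bl == "sigma") {
      ls2 <- ls + stats::rnorm(2, 0, ps$sigma_log)
      rho2 <- rho + stats::rnorm(1, 0, ps$rho)
    } else if (bl == "lambda") {
      lam2 <- lambda + stats::rnorm(1, 0, ps$lambda)
    } else if (bl == "delta") {
      del2 <- delta + stats::rnorm(1, 0, ps$delta)
    } else if (bl == "kappa") {
      kap2 <- kappa + stats::rnorm(1, 0, ps$kappa)
    }
    lp2 <- logprior(a2, b2, ls2, rho2, lam2, del2, kap2)
    if (is.finite(lp2)) {
      if (bl %in% c("lambda", "delta", "kappa")) {
        cache2 <- make_cache(lam2, del2, kap2)
      }
      if (!is.null(cache2)) {
        ll2 <- loglik_cached(cache2, a2, b2, ls2, rho2)
        post2 <- power * ll2 + lp2
        if (is.finite(post2) && log(stats::runif(1)) < post2 - post) {
          alpha <- a2; beta <- b2; ls <- ls2; rho <- rho2
          lambda <- lam2; delta <- del2; kappa <- kap2
          cache <- cache2; ll <- ll2; post <- post2
          acc[bl] <- acc[bl] + 1
        }
      }
    }
    if (k_out <= n_keep && it == keep_at[k_out]) {
      s1 <- exp(2 * ls[1]); s2 <- exp(2 * ls[2])
      samples[k_out, ] <- c(it, alpha, beta, s1, rho * sqrt(s1 * s2), s2,
                            lambda, delta, kappa, ll)
      k_out <- k_out + 1L
    }
  }
  acc_rate <- ifelse(tries > 0, acc / tries, NA)
  if (all(acc == 0)) {
    stop("all proposals rejected; decrease the proposal scales in mcmc_config()")
  }
  list(samples = samples, acceptance = acc_rate, model = model,
       config = config, seed = seed, power = power)
}

#' Bayesian fit of the two-trait Brownian model by MCMC
#'
#' Random-scan Metropolis-Hastings over the root states, directional trends
#' (model B), the evolutionary rate matrix (log standard deviations and
#' correlation) and the lambda transform, with flat priors on bounded
#' supports (lambda uniform on `[0, 1]`; log-uniform rate variances across
#' twelve orders of magnitude around the data scale; uniform correlation;
#' wide normal root states and trends). delta and kappa are fixed at 1 unless
#' freed. Chains start at the profile ML fit; the sample stream is fully
#' reproducible under a fixed seed.
#'
#' @inheritParams bm_loglik
#' @param model `"A"` (random walk) or `"B"` (directional).
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#' @param estimate_delta,estimate_kappa Free the delta/kappa transforms
#'   (defaults fix them at 1).
#' @param lambda Fix lambda at a value instead of sampling it.
#' @return An object of class `bm_mcmc`: `samples` (one row per retained
#'   draw; columns iteration, alpha_cold, alpha_warm, beta_cold, beta_warm,
#'   sigma11, sigma12, sigma22, lambda, delta, kappa, loglik), `acceptance`
#'   rates per block, and the data/tree for downstream reconstruction.
#' @export
fit_mcmc <- function(x, tree, model = c("A", "B"), config = mcmc_config(),
                     seed = 1L, estimate_delta = FALSE,
                     estimate_kappa = FALSE, lambda = NULL) {
  model <- match.arg(model)
  run <- bm_mcmc_kernel(x, tree, model, config, seed, power = 1,
                        estimate_delta = estimate_delta,
                        estimate_kappa = estimate_kappa,
                        lambda_fixed = lambda)
  run$x <- align_traits(x, tree)
  run$tree <- tree
  class(run) <- "bm_mcmc"
  run
}

# Stepping-stone estimate of the log marginal likelihood.
stepping_stone <- function(x, tree, model, config, seed, K = 8) {
  beta_ladder <- (seq(0, K) / K)^3
  iters <- max(2000, ceiling(config$iterations / K))
  sub <- mcmc_config(config$preset, iterations = iters,
                     burn_in = min(config$burn_in, floor(iters / 5)),
                     sample_period = max(1, floor(config$sample_period / 10)))
  logz <- 0
  for (k in seq_len(K)) {
    run <- bm_mcmc_kernel(x, tree, model, sub, seed + k,
                          power = beta_ladder[k])
    ll <- run$samples[, "loglik"]
    dbeta_k <- beta_ladder[k + 1] - beta_ladder[k]
    m <- max(ll)
    logz <- logz + m * dbeta_k + log(mean(exp(dbeta_k * (ll - m))))
  }
  logz
}

#' Posterior ancestral states at interior nodes
#'
#' For each retained posterior draw, the ancestral value at a node is drawn
#' from its conditional normal distribution given the tip data under that
#' draw's parameters (GLS conditional on the transformed covariance extended
#' to interior nodes; node-tip covariances are scaled by the draw's lambda,
#' node variances are not, mirroring the tip-level transform). Summaries are
#' the posterior mean and the 2.5/97.5 percentiles per trait.
#'
#' @param fit A `bm_mcmc` object from [fit_mcmc()].
#' @param nodes Integer IDs of interior nodes (tips are an error).
#' @param max_draws Cap on the number of posterior draws used.
#' @return A data frame with one row per node: posterior mean and 95%
#'   interval for `t_cold` and `t_warm`, plus an `ordered` flag reporting
#'   whether the posterior means respect `t_cold <= t_warm`. The per-draw
#'   samples are attached as attribute `"draws"` (nodes x draws x 2 array).
#' @export
ancestral_states <- function(fit, nodes, max_draws = 1000) {
  stopifnot(inherits(fit, "bm_mcmc"))
  tree <- fit$tree
  n <- ape::Ntip(tree)
  if (any(nodes <= n)) {
    stop("ancestral states are defined for interior nodes only; tip(s): ",
         paste(nodes[nodes <= n], collapse = ", "))
  }
  x <- fit$x
  S <- fit$samples
  n_draw <- min(max_draws, nrow(S))
  pick <- round(seq(1, nrow(S), length.out = n_draw))
  A_cache <- list()
  full_A <- function(delta, kappa) {
    key <- sprintf("%.12g|%.12g", delta, kappa)
    if (is.null(A_cache[[key]])) {
      tk <- tree
      if (kappa != 1) {
        el <- tk$edge.length
        tk$edge.length <- ifelse(el > 0, el^kappa, 0)
      }
      d <- node_depths(tk)
      mr <- ape::mrca(tk, full = TRUE)
      A <- matrix(d[mr], nrow(mr), ncol(mr))
      if (delta != 1) A <- A^delta
      A_cache[[key]] <<- A
    }
    A_cache[[key]]
  }
  draws <- array(NA_real_, c(length(nodes), n_draw, 2))
  set.seed(fit$seed + 77L)
  tip_idx <- seq_len(n)
  for (j in seq_len(n_draw)) {
    s <- S[pick[j], ]
    A <- full_A(s[["delta"]], s[["kappa"]])
    lam <- s[["lambda"]]
    V <- lambda_vcv(A[tip_idx, tip_idx], lam)
    R <- chol(V)
    Sigma <- matrix(c(s[["sigma11"]], s[["sigma12"]],
                      s[["sigma12"]], s[["sigma22"]]), 2)
    alpha <- c(s[["alpha_cold"]], s[["alpha_warm"]])
    beta <- c(s[["beta_cold"]], s[["beta_warm"]])
    depths_tip <- diag(A)[tip_idx]
    E <- x - rep(1, n) %o% alpha - depths_tip %o% beta
    Zx <- backsolve(R, E, transpose = TRUE)
    for (i in seq_along(nodes)) {
      v <- nodes[i]
      cv <- A[v, tip_idx] * lam
      Zc <- backsolve(R, cv, transpose = TRUE)
      mu <- alpha + beta * A[v, v] + drop(crossprod(Zc, Zx))
      sc <- max(A[v, v] - sum(Zc^2), 0)
      cov2 <- Sigma * sc
      z <- stats::rnorm(2)
      Lc <- tryCatch(chol(cov2 + diag(1e-12, 2)), error = function(e) NULL)
      draws[i, j, ] <- if (is.null(Lc)) mu else mu + drop(t(Lc) %*% z)
    }
  }
  out <- data.frame(
    node = nodes,
    t_cold_mean = apply(draws[, , 1, drop = FALSE], 1, mean),
    t_cold_lo = apply(draws[, , 1, drop = FALSE], 1, stats::quantile, 0.025),
    t_cold_hi = apply(draws[, , 1, drop = FALSE], 1, stats::quantile, 0.975),
    t_warm_mean = apply(draws[, , 2, drop = FALSE], 1, mean),
    t_warm_lo = apply(draws[, , 2, drop = FALSE], 1, stats::quantile, 0.025),
    t_warm_hi = apply(draws[, , 2, drop = FALSE], 1, stats::quantile, 0.975))
  out$ordered <- out$t_cold_mean <= out$t_warm_mean
  if (any(!out$ordered)) {
    warning("posterior mean T_cold exceeds T_warm at node(s): ",
            paste(out$node[!out$ordered], collapse = ", "))
  }
  attr(out, "draws") <- draws
  out
}

#' Lambda-recovery simulation experiment
#'
#' Simulates two correlated thermal-tolerance traits under the directional
#' Brownian model on independently simulated 73-tip phylograms with a known
#' generating lambda, refits each replicate by MCMC, and reports per-seed
#' posterior summaries. Used to verify that the inference machinery recovers
#' a strong phylogenetic signal (the published point estimate 0.925) from
#' data of the size and shape of the real tolerance table.
#'
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param n_tips Tips per simulated phylogram.
#' @param lambda_true Generating lambda.
#' @param config An [mcmc_config()].
#' @param alpha,beta,Sigma Generating root states (degC), trends (degC per
#'   subs/site) and rate matrix (degC^2 per subs/site).
#' @return Data frame with one row per seed: posterior means and SDs of
#'   lambda, beta_cold and sigma11, plus the generating values.
#' @export
lambda_recovery_experiment <- function(n_seeds = 10, seed = 1L, n_tips = 73,
                                       lambda_true = 0.925,
                                       config = mcmc_config("desk"),
                                       alpha = c(5, 20),
                                       beta = c(-60, -40),
                                       Sigma = matrix(c(250, 150, 150, 200),
                                                      2)) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + 1000L * i
    st <- sim_tree(n_tips, birth = 0.3, death = 0.1, seed = s, rate_sd = 0.3)
    tr <- sim_bm_traits(st$phylogram, alpha = alpha, beta = beta,
                        Sigma = Sigma, lambda = lambda_true, seed = s + 1L)
    fit <- fit_mcmc(tr$tips, st$phylogram, model = "B", config = config,
                    seed = s + 2L)
    sm <- fit$samples
    rows[[i]] <- data.frame(
      seed = s,
      lambda_mean = mean(sm[, "lambda"]), lambda_sd = stats::sd(sm[, "lambda"]),
      beta_cold_mean = mean(sm[, "beta_cold"]),
      beta_cold_sd = stats::sd(sm[, "beta_cold"]),
      sigma11_mean = mean(sm[, "sigma11"]),
      sigma11_sd = stats::sd(sm[, "sigma11"]))
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(lambda = lambda_true, beta = beta,
                             Sigma = Sigma, alpha = alpha)
  out
}
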