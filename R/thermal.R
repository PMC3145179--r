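#' Phylogenetic variance-covariance matrix of the tips
#'
#' Under Brownian motion the covariance of two tips equals the shared path
#' length from the root to their MRCA; the variance of a tip is its
#' root-to-tip path length. Delegates to [ape::vcv.phylo()]; rows/columns
#' follow `tree$tip.label` order.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric n x n matrix.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  # every parsed newick is interpreted as rooted at its parse root; a basal
  # polytomy is a hard polytomy of that root (a star phylogeny), not an
  # unrooted tree
  ape::vcv.phylo(tree)
}

#' Pagel lambda/delta/kappa transform of a tree's covariance structure
#'
#' The transforms are applied in the fixed order kappa -> delta -> lambda:
#' kappa raises each branch length to the power `kappa` (with `0^0`
#' defined as 0, so zero-length branches stay zero), delta raises shared
#' path lengths (all entries of the covariance matrix, which are MRCA
#' depths) to the power `delta`, and lambda multiplies the off-diagonal
#' entries, leaving tip variances untouched.
#'
#' @param tree A rooted `phylo`.
#' @param lambda Phylogenetic-signal scalar in `[0, 1]`.
#' @param delta Depth-transform exponent (> 0).
#' @param kappa Branch-length exponent (>= 0).
#' @return A list with `V` (transformed tip covariance), `depths` (tip
#'   root-to-tip path lengths on the kappa/delta tree, i.e. the diagonal
#'   before the lambda step; these are the path lengths a directional trend
#'   multiplies) and the parameters used.
#' @export
transform_tree <- function(tree, lambda = 1, delta = 1, kappa = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (delta <= 0) stop("delta must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  tk <- tree
  if (kappa != 1) {
    el <- tk$edge.length
    tk$edge.length <- ifelse(el > 0, el^kappa, 0)
  }
  V <- phylo_vcv(tk)
  if (delta != 1) V <- V^delta
  depths <- diag(V)
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  list(V = V, depths = depths, lambda = lambda, delta = delta, kappa = kappa)
}

# Apply the lambda step to a precomputed covariance (diagonal untouched).
lambda_vcv <- function(V, lambda) {
  d <- diag(V)
  V <- lambda * V
  diag(V) <- d
  V
}

#' Log-likelihood of the two-trait (directional) Brownian model
#'
#' Traits evolve as correlated Brownian motion with evolutionary rate matrix
#' `Sigma` (2 x 2) on the lambda/delta/kappa-transformed tree. Under the
#' directional model (model B) the expected value of trait `j` at tip `i` is
#' `alpha_j + beta_j * depth_i`, where `depth_i` is the root-to-tip path
#' length on the transformed tree; the random-walk model (model A) is the
#' special case `beta = 0`. The joint tip distribution is matrix normal with
#' covariance `kronecker(Sigma, V)`; the density is evaluated through the
#' matrix-normal identity (no Kronecker product is formed).
#'
#' @param x n x 2 matrix of tip values (rows in `tree$tip.label` order, or
#'   with row names that are matched to the tips).
#' @param tree A rooted `phylo` (phylogram for a directional model).
#' @param alpha Length-2 root state.
#' @param beta Length-2 directional trend (per unit transformed path
#'   length); `c(0, 0)` for model A.
#' @param Sigma 2 x 2 positive-definite evolutionary rate matrix.
#' @param lambda,delta,kappa Pagel transforms.
#' @return Log-likelihood (finite scalar; singular covariances are an
#'   error suggesting `lambda < 1`).
#' @export
bm_loglik <- function(x, tree, alpha, beta = c(0, 0), Sigma,
                      lambda = 1, delta = 1, kappa = 1) {
  x <- align_traits(x, tree)
  tf <- transform_tree(tree, lambda, delta, kappa)
  bm_loglik_V(x, tf$V, tf$depths, alpha, beta, Sigma)
}

bm_loglik_V <- function(x, V, depths, alpha, beta, Sigma) {
  n <- nrow(x)
  R <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance; consider lambda < 1 or a small jitter"))
  ldV <- 2 * sum(log(diag(R)))
  ldS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (ldS <= 0) stop("Sigma is not positive definite")
  E <- x - rep(1, n) %o% alpha - depths %o% beta
  Z <- backsolve(R, E, transpose = TRUE)
  M <- crossprod(Z)                      # t(E) V^-1 E, 2 x 2
  Sinv <- solve(Sigma)
  -n * log(2 * pi) - ldV - n / 2 * log(ldS) - 0.5 * sum(Sinv * M)
}

align_traits <- function(x, tree) {
  x <- as.matrix(x)
  if (!is.null(rownames(x)) && all(tree$tip.label %in% rownames(x))) {
    x <- x[tree$tip.label, , drop = FALSE]
  }
  if (nrow(x) != ape::Ntip(tree)) stop("traits do not match the tips")
  if (ncol(x) != 2) stop("expected two trait columns (T_cold, T_warm)")
  storage.mode(x) <- "double"
  x
}

# Profile ML fit: for fixed lambda the GLS estimates of (alpha, beta) and
# Sigma are closed form, so the only numeric optimization is 1-D in lambda.
bm_profile_fit <- function(x, V0, depths, directional, lambda = NULL) {
  n <- nrow(x)
  D <- if (directional) cbind(1, depths) else cbind(rep(1, n))
  prof <- function(lam) {
    V <- lambda_vcv(V0, lam)
    R <- chol(V)
    ldV <- 2 * sum(log(diag(R)))
    Dz <- backsolve(R, D, transpose = TRUE)
    xz <- backsolve(R, x, transpose = TRUE)
    # pivoted QR: a collinear trend column (ultrametric tree) is aliased to
    # zero rather than failing, which collapses model B onto model A
    qd <- qr(Dz, LAPACK = FALSE, tol = 1e-10)
    B <- qr.coef(qd, xz)
    B[is.na(B)] <- 0
    Ez <- xz - Dz %*% B
    S <- crossprod(Ez) / n                          # ML Sigma
    ldS <- S[1, 1] * S[2, 2] - S[1, 2]^2
    ll <- -n * log(2 * pi) - ldV - n / 2 * log(max(ldS, 1e-300)) - n
    list(ll = ll, B = B, S = S)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) -prof(l)$ll, c(0, 1), tol = 1e-8)
    lambda <- opt$minimum
    # check the boundaries too: optimize() can miss a boundary optimum
    for (lb in c(0, 1)) if (prof(lb)$ll > prof(lambda)$ll) lambda <- lb
  }
  p <- prof(lambda)
  alpha <- p$B[1, ]
  beta <- if (directional) p$B[2, ] else c(0, 0)
  list(loglik = p$ll, alpha = alpha, beta = beta, Sigma = p$S,
       lambda = lambda,
       n_par = 2 * ncol(p$B) + 3 + 1)
}

#' Maximum-likelihood fit of the two-trait Brownian model
#'
#' Closed-form GLS profile over `(alpha, beta, Sigma)` with a 1-D numeric
#' profile optimization of `lambda` (delta and kappa fixed at 1 by default;
#' see the methods vignette).
#'
#' @inheritParams bm_loglik
#' @param model `"A"` (random walk) or `"B"` (directional).
#' @param lambda Fix lambda at this value instead of estimating it.
#' @return List with `loglik`, `alpha`, `beta`, `Sigma`, `lambda`, `n_par`.
#' @export
bm_ml_fit <- function(x, tree, model = c("A", "B"), lambda = NULL) {
  model <- match.arg(model)
  x <- align_traits(x, tree)
  tf <- transform_tree(tree, 1, 1, 1)
  if (model == "B" && stats::sd(tf$depths) < 1e-10 * mean(tf$depths)) {
    warning("tree is ultrametric: the directional trend is unidentifiable")
  }
  fit <- bm_profile_fit(x, tf$V, tf$depths, directional = model == "B",
                        lambda = lambda)
  fit$model <- model
  fit
}

#' Compare the random-walk (A) and directional (B) models
#'
#' Likelihood-ratio test of model B against model A (chi-squared with 2
#' degrees of freedom, one per trend parameter) on the ML profile fits, and
#' optionally a stepping-stone estimate of the log Bayes factor from MCMC
#' power posteriors. The default "best" call is the LRT at `alpha = 0.05`.
#'
#' @inheritParams bm_ml_fit
#' @param bayes_factor Also compute a stepping-stone log Bayes factor
#'   (slower; default `FALSE`).
#' @param config MCMC configuration for the stepping-stone chains.
#' @param seed Seed for the stepping-stone chains.
#' @param alpha_level Significance level for the LRT call.
#' @return List with `lrt` (statistic, df, p), `fit_A`, `fit_B`, `best`
#'   (`"A"` or `"B"`), and `log_bf` when requested.
#' @export
compare_models <- function(x, tree, bayes_factor = FALSE,
                           config = mcmc_config("desk", iterations = 2e4),
                           seed = 1L, alpha_level = 0.05) {
  x <- align_traits(x, tree)
  fit_A <- bm_ml_fit(x, tree, "A")
  fit_B <- bm_ml_fit(x, tree, "B")
  stat <- max(0, 2 * (fit_B$loglik - fit_A$loglik))
  df <- 2
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  out <- list(lrt = list(statistic = stat, df = df, p_value = p),
              fit_A = fit_A, fit_B = fit_B,
              best = if (p < alpha_level) "B" else "A")
  if (bayes_factor) {
    zA <- stepping_stone(x, tree, "A", config, seed)
    zB <- stepping_stone(x, tree, "B", config, seed + 1L)
    out$log_bf <- zB - zA
    out$log_marginal <- c(A = zA, B = zB)
  }
  out
}
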