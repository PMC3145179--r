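#' Simulate a birth-death chronogram and a rate-noise phylogram
#'
#' A birth-death chronogram conditioned on `n` extant tips (via
#' [ape::rphylo()]) and a companion phylogram obtained by multiplying every
#' branch by an independent lognormal substitution rate with mean
#' `rate_mean` (substitutions/site/Ma) and lognormal dispersion `rate_sd`,
#' so that root-to-tip path lengths vary across tips (a requirement for
#' identifying a directional trait trend).
#'
#' @param n Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates (`birth > death >= 0`).
#' @param seed Integer seed; identical seeds reproduce identical trees.
#' @param rate_mean Mean substitution rate in subs/site/Ma (7.5e-9 per year
#'   = 0.0075 per Ma).
#' @param rate_sd Lognormal standard deviation (on the log scale) of the
#'   per-branch rate multipliers; 0 gives a clock-like phylogram.
#' @return List with `chronogram` (`length_unit = "Ma"`) and `phylogram`
#'   (`length_unit = "subs_per_site"`), plus the per-branch rates used.
#' @export
sim_tree <- function(n, birth = 0.3, death = 0, seed = 1L,
                     rate_mean = 0.0075, rate_sd = 0.3) {
  if (n < 2) stop("n must be >= 2")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  set.seed(seed)
  chrono <- ape::rphylo(n, birth, death, fossils = FALSE)
  attr(chrono, "length_unit") <- "Ma"
  mult <- exp(stats::rnorm(nrow(chrono$edge), -rate_sd^2 / 2, rate_sd))
  rates <- rate_mean * mult
  phylo <- chrono
  phylo$edge.length <- chrono$edge.length * rates
  attr(phylo, "length_unit") <- "subs_per_site"
  list(chronogram = chrono, phylogram = phylo, branch_rates = rates)
}

#' Simulate correlated two-trait Brownian evolution with known node truth
#'
#' Draws tip and interior-node states jointly from the multivariate normal
#' implied by the lambda/delta/kappa-transformed covariance and the
#' directional mean (root state alpha plus beta times transformed node
#' depth). The root state is alpha exactly; all other node states are
#' returned as ground truth.
#'
#' @param tree A rooted `phylo` (phylogram when `beta != 0`).
#' @param alpha Length-2 root state (cold, warm).
#' @param beta Length-2 directional trend per unit transformed path length.
#' @param Sigma 2 x 2 PSD evolutionary rate matrix.
#' @param lambda,delta,kappa Pagel transforms of the generating process.
#' @param seed Integer seed.
#' @return List with `tips` (n x 2 matrix, rownames = tip labels), `nodes`
#'   (interior-node truths incl. the root), and the generating parameters.
#' @export
sim_bm_traits <- function(tree, alpha = c(0, 10), beta = c(0, 0),
                          Sigma = diag(2), lambda = 1, delta = 1, kappa = 1,
                          seed = 1L) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("Sigma must be positive semi-definite")
  set.seed(seed)
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  root <- n + 1L
  tk <- tree
  if (kappa != 1) {
    el <- tk$edge.length
    tk$edge.length <- ifelse(el > 0, el^kappa, 0)
  }
  d <- node_depths(tk)
  mr <- ape::mrca(tk, full = TRUE)
  A <- matrix(d[mr], n_all, n_all)
  if (delta != 1) A <- A^delta
  depths <- diag(A)
  if (lambda != 1) {
    dd <- diag(A)
    A <- lambda * A
    diag(A) <- dd
  }
  keep <- setdiff(seq_len(n_all), root)   # root is deterministic (= alpha)
  Ak <- A[keep, keep]
  mu <- depths[keep] %o% beta + rep(1, length(keep)) %o% alpha
  # joint draw: kronecker(Sigma, Ak) via the matrix-normal factorization
  Ra <- chol(Ak + diag(1e-10, nrow(Ak)))
  Rs <- chol(Sigma + diag(1e-12, 2))
  Z <- matrix(stats::rnorm(length(keep) * 2), length(keep), 2)
  X <- mu + t(Ra) %*% Z %*% Rs
  all_states <- matrix(NA_real_, n_all, 2)
  all_states[keep, ] <- X
  all_states[root, ] <- alpha
  tips <- all_states[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  colnames(tips) <- c("t_cold", "t_warm")
  nodes <- all_states[(n + 1L):n_all, , drop = FALSE]
  rownames(nodes) <- as.character((n + 1L):n_all)
  colnames(nodes) <- c("t_cold", "t_warm")
  list(tips = tips, nodes = nodes,
       pars = list(alpha = alpha, beta = beta, Sigma = Sigma,
                   lambda = lambda, delta = delta, kappa = kappa))
}

#' Forward-simulate a DEC range history with a known event list
#'
#' Gillespie simulation of anagenetic gains and losses along every branch
#' (rates as in [build_q_matrix()]) with uniformly sampled cladogenetic
#' inheritance scenarios at interior nodes. Every dispersal event is
#' recorded with its branch, time, source area, gained area and route. If
#' the whole clade goes extinct (any tip ends with the null range) the
#' simulation is retried up to `max_retry` times.
#'
#' @param tree Chronogram.
#' @param areas An `area_set`.
#' @param d,e Dispersal and extinction rates (per Ma).
#' @param root_range Character vector of areas occupied at the root.
#' @param cap Maximum range size.
#' @param seed Integer seed.
#' @param max_retry Retry budget before erroring out.
#' @return List with `tip_ranges` (named list), `events` (data frame of true
#'   dispersal events), `node_ranges`, and the parameters.
#' @export
sim_dec_ranges <- function(tree, areas, d = 0.05, e = 0.01,
                           root_range = areas$areas[1], cap = 2, seed = 1L,
                           max_retry = 100) {
  check_unit(tree, "Ma")
  set.seed(seed)
  k <- length(areas$areas)
  mult <- areas$adjacency * 1
  root_idx <- match(root_range, areas$areas)
  if (anyNA(root_idx)) stop("unknown root areas")
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  root <- n + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  ages <- node_ages_chronogram(tree)
  for (try in seq_len(max_retry)) {
    node_range <- vector("list", n_all)
    node_range[[root]] <- sort(root_idx)
    events <- list()
    ok <- TRUE
    # preorder walk
    pre_nodes <- rev(unique(ape::reorder.phylo(tree, "postorder")$edge[, 1]))
    for (v in pre_nodes) {
      s_v <- node_range[[v]]
      if (!length(s_v)) { ok <- FALSE; break }
      sc <- dec_scenarios(s_v)
      pick <- sc[[sample.int(length(sc), 1)]]
      ch <- children[[as.character(v)]]
      inherit <- list(pick$left, pick$right)
      if (length(ch) != 2) {  # polytomy: first child gets the scenario part
        inherit <- c(inherit[1], rep(list(s_v), length(ch) - 1))
      }
      for (j in seq_along(ch)) {
        c_ <- ch[j]
        s <- sort(as.integer(inherit[[j]]))
        t_left <- blen[[as.character(c_)]]
        t_now <- ages[v]
        while (TRUE) {
          if (!length(s)) break
          gain_rates <- rep(0, k)
          if (length(s) < cap) {
            for (a in setdiff(seq_len(k), s)) {
              gain_rates[a] <- d * sum(mult[s, a])
            }
          }
          loss_rate <- e * length(s)
          tot <- sum(gain_rates) + loss_rate
          if (tot <= 0) break
          dt <- stats::rexp(1, tot)
          if (dt > t_left) break
          t_left <- t_left - dt
          t_now <- t_now - dt
          if (stats::runif(1) < sum(gain_rates) / tot) {
            a <- sample.int(k, 1, prob = gain_rates)
            src_pool <- s[mult[s, a] > 0]
            src <- src_pool[sample.int(length(src_pool), 1)]
            events[[length(events) + 1]] <- data.frame(
              parent_node = v, child_node = c_, time_ma = t_now,
              source_area = areas$areas[src], gained_area = areas$areas[a],
              route = areas$routes[src, a])
            s <- sort(c(s, a))
          } else {
            s <- setdiff(s, s[sample.int(length(s), 1)])
          }
        }
        node_range[[c_]] <- s
      }
    }
    if (ok && all(lengths(node_range[seq_len(n)]) > 0)) {
      tip_ranges <- lapply(seq_len(n), function(i) {
        areas$areas[node_range[[i]]]
      })
      names(tip_ranges) <- tree$tip.label
      ev <- if (length(events)) do.call(rbind, events) else
        data.frame(parent_node = integer(0), child_node = integer(0),
                   time_ma = numeric(0), source_area = character(0),
                   gained_area = character(0), route = character(0))
      return(list(tip_ranges = tip_ranges, events = ev,
                  node_ranges = lapply(node_range, function(s) areas$areas[s]),
                  pars = list(d = d, e = e, cap = cap,
                              root_range = root_range, seed = seed)))
    }
  }
  stop("whole-clade range extinction in every retry; ",
       "lower e or raise max_retry")
}

#' Simulate a cooling delta-18O series
#'
#' A linear trend in expectation from `start_permil` at `age_max` Ma to
#' `end_permil` at 0 Ma (benthic delta-18O rises as climate cools) plus
#' white Gaussian noise, on an evenly spaced age grid.
#'
#' @param n_samples Number of samples (>= 100).
#' @param start_permil Value at the old end (`age_max` Ma).
#' @param end_permil Value at the recent end (0 Ma).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param age_max Oldest age (Ma).
#' @param seed Integer seed.
#' @return Data frame (`age_ma`, `d18o_permil`) sorted by increasing age.
#' @export
sim_delta18o <- function(n_samples = 300, start_permil = 2.0,
                         end_permil = 4.2, noise_sd = 0.08, age_max = 14,
                         seed = 1L) {
  if (n_samples < 100) stop("n_samples must be >= 100")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  age <- seq(0, age_max, length.out = n_samples)
  trend <- end_permil + (start_permil - end_permil) * age / age_max
  data.frame(age_ma = age,
             d18o_permil = trend + stats::rnorm(n_samples, 0, noise_sd))
}
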