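# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# All ancestors of a node (walking the edge matrix), node included.
oracle_ancestors <- function(tree, node) {
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  out <- node
  while (par[node] != 0) {
    node <- par[node]
    out <- c(out, node)
  }
  out
}

# MRCA by intersecting ancestor sets and taking the deepest element.
oracle_mrca <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  common <- Reduce(intersect, lapply(idx, function(i) oracle_ancestors(tree, i)))
  depth <- ape::node.depth.edgelength(tree)
  common[which.max(depth[common])]
}

# Tip covariance by explicit path intersection: sum of branch lengths shared
# by the two root-to-tip paths.
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- lapply(seq_len(n), function(i) oracle_ancestors(tree, i))
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      shared <- setdiff(shared, n + 1L)   # root carries no branch
      V[i, j] <- sum(elen[shared])
    }
  }
  V
}

# Dense bivariate-trait multivariate-normal log density via the explicit
# 2n x 2n Kronecker covariance.
oracle_mvn_loglik <- function(x, V, depths, alpha, beta, Sigma) {
  n <- nrow(x)
  mu <- c(alpha[1] + beta[1] * depths, alpha[2] + beta[2] * depths)
  K <- kronecker(Sigma, V)
  xv <- c(x[, 1], x[, 2])
  R <- chol(K)
  z <- backsolve(R, xv - mu, transpose = TRUE)
  -(2 * n) / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Unit-cost parsimony score and MPR sets by exhaustive enumeration over all
# internal-node state assignments.
oracle_sankoff <- function(tree, states) {
  lv <- sort(unique(as.character(states)))
  n <- ape::Ntip(tree)
  n_int <- tree$Nnode
  tip_state <- match(states[tree$tip.label], lv)
  combs <- expand.grid(rep(list(seq_along(lv)), n_int))
  cost_of <- function(assign_int) {
    st <- c(tip_state, as.integer(assign_int))
    sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
  }
  costs <- apply(combs, 1, cost_of)
  score <- min(costs)
  best <- combs[costs == score, , drop = FALSE]
  sets <- lapply(seq_len(n_int), function(k) sort(unique(lv[best[[k]]])))
  names(sets) <- as.character(n + seq_len(n_int))
  list(score = score, node_states = sets)
}

# Independent DEC oracle: explicit Q assembly from the process definition,
# matrix exponentials by eigendecomposition, and plain unscaled recursion.
oracle_dec_loglik <- function(tree, tip_ranges, areas, d, e, cap) {
  k <- length(areas$areas)
  subsets <- list(integer(0))
  for (sz in seq_len(cap)) subsets <- c(subsets, utils::combn(k, sz, simplify = FALSE))
  S <- length(subsets)
  find_state <- function(s) {
    s <- sort(s)
    for (i in seq_len(S)) if (identical(subsets[[i]], as.integer(s))) return(i)
    stop("state not found")
  }
  adj <- areas$adjacency
  Q <- matrix(0, S, S)
  for (i in 2:S) {
    s <- subsets[[i]]
    if (length(s) < cap) {
      for (a in setdiff(seq_len(k), s)) {
        rate <- d * sum(adj[s, a])
        if (rate > 0) Q[i, find_state(c(s, a))] <- Q[i, find_state(c(s, a))] + rate
      }
    }
    for (a in s) Q[i, find_state(setdiff(s, a))] <- Q[i, find_state(setdiff(s, a))] + e
  }
  diag(Q) <- -rowSums(Q)
  pmat <- function(t) {
    eg <- eigen(Q)
    Re(eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors))
  }
  scen <- function(s) {
    if (length(s) <= 1) return(list(list(l = s, r = s)))
    out <- list(); seen <- character(0)
    for (a in s) {
      rest <- setdiff(s, a)
      for (pr in list(list(l = a, r = rest), list(l = rest, r = a),
                      list(l = a, r = s), list(l = s, r = a))) {
        key <- paste(paste(sort(pr$l), collapse = "."), "|",
                     paste(sort(pr$r), collapse = "."))
        if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1]] <- pr }
      }
    }
    out
  }
  n <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  clik <- function(v, si) {
    s <- subsets[[si]]
    if (v <= n) {
      obs <- sort(match(tip_ranges[[tree$tip.label[v]]], areas$areas))
      return(as.numeric(identical(as.integer(obs), subsets[[si]])))
    }
    ch <- children[[as.character(v)]]
    scs <- scen(s)
    tot <- 0
    for (sc in scs) {
      tot <- tot + blik(ch[1], find_state(sc$l)) * blik(ch[2], find_state(sc$r))
    }
    tot / length(scs)
  }
  blik <- function(v, xi) {
    P <- pmat(blen[[as.character(v)]])
    sum(vapply(seq_len(S), function(yi) P[xi, yi] * clik(v, yi), numeric(1)))
  }
  connected <- function(s) {
    if (length(s) <= 1) return(TRUE)
    seen <- s[1]
    repeat {
      add <- s[!(s %in% seen) & vapply(s, function(a) any(adj[a, seen]), logical(1))]
      if (!length(add)) break
      seen <- c(seen, add)
    }
    length(seen) == length(s)
  }
  allowed <- which(vapply(subsets, function(s) length(s) > 0 && connected(s),
                          logical(1)))
  root <- n + 1L
  log(mean(vapply(allowed, function(si) clik(root, si), numeric(1))))
}

# Batch-means Monte Carlo standard error for an MCMC sample vector.
mcse <- function(x, n_batch = 25) {
  bs <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# Small random area system used by DEC tests.
toy_areas3 <- function() {
  beringia:::make_area_set(
    c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               route = c("land", "sea")))
}

rand_tree_ma <- function(n, seed) {
  sim_tree(n, birth = 0.4, death = 0, seed = seed)$chronogram
}
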