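#' Fit DEC rates and reconstruct ancestral ranges
#'
#' Maximum-likelihood estimation of the dispersal and extinction rates by
#' bounded Nelder-Mead on log rates (multi-start), followed by marginal
#' ancestral-range reconstruction from combined inside (pruning) and outside
#' (re-rooted conditional) passes, and read-off of dispersal events along the
#' most-likely joint path: for every branch, the minimal anagenetic
#' gain/loss path from the state inherited at the parent's most likely
#' cladogenetic scenario to the child's most likely state, each gain
#' annotated with its source area and dispersal route.
#'
#' @inheritParams dec_loglik
#' @param starts Matrix of optimizer starts in log(d), log(e); sensible
#'   defaults are provided.
#' @param bounds Lower/upper bounds on the rates (per Ma).
#' @return An object of class `dec_recon`: fitted `d`, `e`, `loglik`,
#'   `node_states` (per-node most likely range and its relative likelihood),
#'   `marginals` (states x nodes matrix of relative likelihoods, columns sum
#'   to 1), and `events` (one row per inferred dispersal event: branch child
#'   node, source area, gained area, route, age in Ma at the parent node).
#' @export
dec_fit <- function(tree, tip_ranges, areas, cap = 2,
                    starts = rbind(c(-3, -3), c(-1.5, -4), c(-4.5, -2)),
                    bounds = c(1e-8, 50)) {
  ws <- dec_workspace(tree, tip_ranges, areas, cap)
  nll <- function(par) {
    d <- exp(par[1]); e <- exp(par[2])
    if (d < bounds[1] || d > bounds[2] || e < bounds[1] || e > bounds[2]) {
      return(1e10)
    }
    -dec_prune(ws, d, e)$loglik
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("DEC optimization failed to converge; best objective: ",
         if (is.null(best)) NA else best$value)
  }
  d <- exp(best$par[1]); e <- exp(best$par[2])
  recon <- dec_reconstruct(ws, d, e)
  recon$loglik <- -best$value
  recon
}

# Outside ("G") pass + marginals + event read-off for fixed rates.
dec_reconstruct <- function(ws, d, e) {
  pr <- dec_prune(ws, d, e)
  tree <- ws$tree
  n <- ws$n; S <- ws$S
  n_all <- n + tree$Nnode
  root <- n + 1L
  G <- matrix(0, S, n_all)
  G[ws$root_allowed, root] <- 1 / length(ws$root_allowed)
  # preorder over internal nodes (root first)
  pre <- rev(ws$post_nodes)
  for (v in pre) {
    ch <- ws$children[[as.character(v)]]
    H <- matrix(0, S, 2)
    for (si in seq_len(S)[-1]) {
      gv <- G[si, v]
      if (gv == 0) next
      idx <- ws$scen_idx[[si]]
      w <- gv / nrow(idx)
      for (r in seq_len(nrow(idx))) {
        H[idx[r, 1], 1] <- H[idx[r, 1], 1] + w * pr$D[idx[r, 2], ch[2]]
        H[idx[r, 2], 2] <- H[idx[r, 2], 2] + w * pr$D[idx[r, 1], ch[1]]
      }
    }
    for (j in 1:2) {
      c_ <- ch[j]
      G[, c_] <- crossprod(pr$P[[c_]], H[, j])
      s <- sum(G[, c_])
      if (s > 0) G[, c_] <- G[, c_] / s   # rescale; marginals renormalized
    }
  }
  marg <- G * pr$L
  cs <- colSums(marg)
  cs[cs == 0] <- 1
  marg <- sweep(marg, 2, cs, "/")
  ml_state <- apply(marg, 2, which.max)
  ages <- node_ages_chronogram(tree)
  joint <- dec_joint_path(ws, pr)
  events <- dec_events(ws, joint, ages)
  structure(list(tree = tree, areas = ws$areas, cap = ws$cap,
                 d = d, e = e, loglik = pr$loglik,
                 marginals = marg,
                 node_states = data.frame(
                   node = seq_len(n_all),
                   state = names(ws$states)[ml_state],
                   rel_lik = marg[cbind(ml_state, seq_len(n_all))],
                   joint_state = names(ws$states)[joint$node_state]),
                 events = events),
            class = "dec_recon")
}

# Joint maximum-likelihood history (max-product over node states and
# cladogenetic scenarios, Viterbi-style in log space). Returns the chosen
# state at every node and the inherited state at the top of every branch.
dec_joint_path <- function(ws, pr) {
  S <- ws$S; n <- ws$n
  tree <- ws$tree
  n_all <- n + tree$Nnode
  NEG <- -1e300
  logC <- matrix(NEG, S, n_all)     # best log-lik of subtree given node state
  logM <- matrix(NEG, S, n_all)     # ... given state at top of branch to node
  best_y <- matrix(NA_integer_, S, n_all)   # argmax node state per top state
  best_sc <- matrix(NA_integer_, S, n_all)  # argmax scenario per node state
  for (i in seq_len(n)) logC[ws$tip_state[i], i] <- 0
  branch_nodes <- as.integer(names(ws$branch_len))
  update_M <- function(c_) {
    lp <- log(pmax(pr$P[[c_]], 0))
    W <- lp + matrix(logC[, c_], S, S, byrow = TRUE)   # W[x, y]
    best_y[, c_] <<- max.col(W, ties.method = "first")
    logM[, c_] <<- W[cbind(seq_len(S), best_y[, c_])]
  }
  for (v in ws$post_nodes) {
    ch <- ws$children[[as.character(v)]]
    for (c_ in ch) update_M(c_)
    for (si in seq_len(S)[-1]) {
      idx <- ws$scen_idx[[si]]
      vals <- logM[idx[, 1], ch[1]] + logM[idx[, 2], ch[2]] - log(nrow(idx))
      j <- which.max(vals)
      best_sc[si, v] <- j
      logC[si, v] <- vals[j]
    }
  }
  root <- n + 1L
  root_scores <- rep(NEG, S)
  root_scores[ws$root_allowed] <- logC[ws$root_allowed, root] -
    log(length(ws$root_allowed))
  node_state <- integer(n_all)
  top_state <- integer(n_all)       # inherited state at top of branch
  node_state[root] <- which.max(root_scores)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) { node_state[v] <- ws$tip_state[v]; next }
    si <- node_state[v]
    ch <- ws$children[[as.character(v)]]
    pair <- ws$scen_idx[[si]][best_sc[si, v], ]
    for (j in 1:2) {
      c_ <- ch[j]
      top_state[c_] <- pair[j]
      node_state[c_] <- if (c_ <= n) ws$tip_state[c_] else
        best_y[pair[j], c_]
      stack <- c(stack, c_)
    }
  }
  list(node_state = node_state, top_state = top_state)
}

# Minimal-event anagenetic paths along each branch of the ML joint scenario.
dec_events <- function(ws, joint, ages) {
  S <- ws$S
  # state-graph edges for BFS (unit cost per anagenetic event)
  edges_from <- vector("list", S)
  if (!is.null(ws$tr$gains)) {
    for (r in seq_len(nrow(ws$tr$gains))) {
      g <- ws$tr$gains[r, ]
      edges_from[[g$from]] <- rbind(edges_from[[g$from]],
        data.frame(to = g$to, kind = "gain", gained = g$gained,
                   source = g$source, route = g$route))
    }
  }
  for (r in seq_len(nrow(ws$tr$losses))) {
    l <- ws$tr$losses[r, ]
    edges_from[[l$from]] <- rbind(edges_from[[l$from]],
      data.frame(to = l$to, kind = "loss", gained = NA_integer_,
                 source = NA_integer_, route = NA_character_))
  }
  shortest_path <- function(a, b) {
    if (a == b) return(NULL)
    prev <- rep(NA_integer_, S); prev_edge <- vector("list", S)
    visited <- rep(FALSE, S); visited[a] <- TRUE
    frontier <- a
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        ef <- edges_from[[u]]
        if (is.null(ef)) next
        for (r in seq_len(nrow(ef))) {
          v <- ef$to[r]
          if (!visited[v]) {
            visited[v] <- TRUE; prev[v] <- u; prev_edge[[v]] <- ef[r, ]
            nxt <- c(nxt, v)
          }
        }
      }
      if (visited[b]) break
      frontier <- nxt
    }
    if (!visited[b]) return(NA)
    path <- list(); v <- b
    while (v != a) {
      path[[length(path) + 1]] <- prev_edge[[v]]
      v <- prev[v]
    }
    rev(path)
  }
  out <- list()
  for (v in ws$post_nodes) {
    ch <- ws$children[[as.character(v)]]
    for (c_ in ch) {
      path <- shortest_path(joint$top_state[c_], joint$node_state[c_])
      if (is.null(path) || !is.list(path)) next
      for (step in path) {
        if (step$kind != "gain") next
        out[[length(out) + 1]] <- data.frame(
          parent_node = v, child_node = c_,
          child_label = node_label(ws$tree, c_),
          age_ma = ages[v],
          source_area = ws$areas$areas[step$source],
          gained_area = ws$areas$areas[step$gained],
          route = step$route)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(parent_node = integer(0), child_node = integer(0),
                      child_label = character(0), age_ma = numeric(0),
                      source_area = character(0), gained_area = character(0),
                      route = character(0)))
  }
  do.call(rbind, out)
}

#' Count dispersal events between two area groups
#'
#' Filters the inferred dispersal events of a [dec_fit()] reconstruction to
#' those whose source area lies in `from_group` and whose gained area lies in
#' `to_group` (e.g. Old World to New World crossings).
#'
#' @param recon A `dec_recon` object (or any list with an `events` data
#'   frame in the same format).
#' @param from_group,to_group Character vectors of area names (non-empty).
#' @return A list with `count` and `events` (the matching rows).
#' @export
count_crossings <- function(recon, from_group, to_group) {
  if (!length(from_group) || !length(to_group)) {
    stop("area groups must be non-empty")
  }
  ev <- recon$events
  hit <- ev$source_area %in% from_group & ev$gained_area %in% to_group
  list(count = sum(hit), events = ev[hit, , drop = FALSE])
}

#' Old World and New World area groups
#'
#' Convenience constants for crossing counts over the ten-area system.
#' @return A list with `old_world` and `new_world` character vectors.
#' @export
world_groups <- function() {
  list(
    old_world = c("EastPalaearctic", "WestPalaearctic", "Oriental",
                  "Africa", "Australia"),
    new_world = c("WestNearctic", "EastNearctic",
                  "CentralAmerica-Caribbean", "NorthernSouthAmerica",
                  "SouthernSouthAmerica"))
}
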