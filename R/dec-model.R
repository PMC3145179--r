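#' The ten-area biogeographic system with dispersal routes
#'
#' Areas (fixed order): Africa, Australia, CentralAmerica-Caribbean,
#' EastNearctic, EastPalaearctic, NorthernSouthAmerica, Oriental,
#' SouthernSouthAmerica, WestNearctic, WestPalaearctic. Dispersal is allowed
#' between land neighbours plus two transoceanic routes: EastPalaearctic <->
#' WestNearctic (`north_pacific`, i.e. Beringia) and WestPalaearctic <->
#' EastNearctic (`north_atlantic`).
#'
#' @param africa_oriental Allow the Africa <-> Oriental land connection
#'   (default `TRUE`).
#' @param edges Optional data frame (`from`, `to`, `route`) replacing the
#'   default adjacency entirely; `route` is free text but `"north_pacific"`
#'   and `"north_atlantic"` are the tags used by crossing counts.
#' @return A list (class `area_set`) with `areas` (character vector),
#'   `adjacency` (symmetric logical matrix, zero diagonal) and `routes`
#'   (character matrix; `NA` where no route exists).
#' @export
default_areas <- function(africa_oriental = TRUE, edges = NULL) {
  areas <- c("Africa", "Australia", "CentralAmerica-Caribbean",
             "EastNearctic", "EastPalaearctic", "NorthernSouthAmerica",
             "Oriental", "SouthernSouthAmerica", "WestNearctic",
             "WestPalaearctic")
  if (is.null(edges)) {
    edges <- data.frame(
      from = c("WestPalaearctic", "WestPalaearctic", "EastPalaearctic",
               "Oriental", "WestNearctic", "WestNearctic", "EastNearctic",
               "CentralAmerica-Caribbean", "NorthernSouthAmerica",
               "EastPalaearctic", "WestPalaearctic"),
      to = c("EastPalaearctic", "Africa", "Oriental", "Australia",
             "EastNearctic", "CentralAmerica-Caribbean",
             "CentralAmerica-Caribbean", "NorthernSouthAmerica",
             "SouthernSouthAmerica", "WestNearctic", "EastNearctic"),
      route = c(rep("land", 9), "north_pacific", "north_atlantic"),
      stringsAsFactors = FALSE)
    if (africa_oriental) {
      edges <- rbind(edges, data.frame(from = "Africa", to = "Oriental",
                                       route = "land"))
    }
  } else {
    areas <- sort(unique(c(edges$from, edges$to, areas[0])))
  }
  bad <- setdiff(c(edges$from, edges$to), areas)
  if (length(bad)) stop("unknown areas in adjacency: ", paste(bad, collapse = ", "))
  k <- length(areas)
  adjacency <- matrix(FALSE, k, k, dimnames = list(areas, areas))
  routes <- matrix(NA_character_, k, k, dimnames = list(areas, areas))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (a == b) stop("self-adjacency is not allowed: ", a)
    adjacency[a, b] <- adjacency[b, a] <- TRUE
    routes[a, b] <- routes[b, a] <- edges$route[i]
  }
  structure(list(areas = areas, adjacency = adjacency, routes = routes),
            class = "area_set")
}

# A small bespoke area system (for tests/simulations on fewer areas).
make_area_set <- function(names, edges) {
  k <- length(names)
  adjacency <- matrix(FALSE, k, k, dimnames = list(names, names))
  routes <- matrix(NA_character_, k, k, dimnames = list(names, names))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adjacency[a, b] <- adjacency[b, a] <- TRUE
    r <- if ("route" %in% names(edges)) edges$route[i] else "land"
    routes[a, b] <- routes[b, a] <- r
  }
  structure(list(areas = names, adjacency = adjacency, routes = routes),
            class = "area_set")
}

# Enumerate range states: state 1 is the null (empty, absorbing) range,
# followed by all non-empty subsets of size <= cap ordered by size then
# lexicographically. Each state is an integer vector of area indices; names
# are "+"-joined area names ("0" for the null range).
enumerate_ranges <- function(areas, cap) {
  k <- length(areas$areas)
  if (cap < 1 || cap > k) stop("max_range_size must be between 1 and ", k)
  states <- list(integer(0))
  for (size in seq_len(cap)) {
    states <- c(states, utils::combn(k, size, simplify = FALSE))
  }
  names(states) <- vapply(states, function(s) {
    if (!length(s)) "0" else paste(areas$areas[s], collapse = "+")
  }, character(1))
  states
}

state_key <- function(s) {
  if (!length(s)) return("null")
  paste(sort(s), collapse = ",")
}

state_lookup <- function(states) {
  keys <- vapply(states, state_key, character(1))
  stats::setNames(seq_along(states), keys)
}

range_state_index <- function(states, range_areas, areas) {
  idx <- match(range_areas, areas$areas)
  if (anyNA(idx)) stop("unknown area(s): ",
                       paste(range_areas[is.na(idx)], collapse = ", "))
  pos <- state_lookup(states)[state_key(idx)]
  if (is.na(pos)) stop("range exceeds max_range_size: ",
                       paste(range_areas, collapse = "+"))
  unname(pos)
}

# Precomputed anagenetic transition structure for a (areas, cap, multiplier)
# triple: rows of gains (from-state, to-state, multiplier sum, gained area,
# best source area, route) and losses (from-state, to-state).
dec_transitions <- function(areas, cap, multiplier = NULL) {
  states <- enumerate_ranges(areas, cap)
  if (is.null(multiplier)) multiplier <- areas$adjacency * 1
  if (any(multiplier[!areas$adjacency] != 0)) {
    stop("multiplier must be zero for non-adjacent area pairs")
  }
  lookup <- state_lookup(states)
  k <- length(areas$areas)
  gains <- list(); losses <- list()
  for (i in seq_along(states)[-1]) {
    s <- states[[i]]
    if (length(s) < cap) {
      for (a in setdiff(seq_len(k), s)) {
        m <- sum(multiplier[s, a])
        if (m > 0) {
          j <- unname(lookup[state_key(c(s, a))])
          src <- s[which.max(multiplier[s, a])]
          gains[[length(gains) + 1]] <-
            data.frame(from = i, to = j, mult = m, gained = a, source = src,
                       route = areas$routes[src, a])
        }
      }
    }
    for (a in s) {
      j <- unname(lookup[state_key(setdiff(s, a))])
      losses[[length(losses) + 1]] <- data.frame(from = i, to = j, lost = a)
    }
  }
  list(states = states, lookup = lookup,
       gains = do.call(rbind, gains), losses = do.call(rbind, losses),
       multiplier = multiplier)
}

#' Anagenetic DEC rate matrix over range states
#'
#' Builds the generator of the dispersal-extinction process: a range `R`
#' expands to `R + {a}` at rate `d * sum over b in R of m[b, a]` where `m` is
#' the dispersal multiplier (1 for an allowed route, 0 otherwise), and
#' contracts to `R - {a}` at rate `e` per occupied area; a single-area range
#' contracts to the absorbing null range. Rows sum to zero.
#'
#' @param areas An `area_set` from [default_areas()].
#' @param d,e Dispersal and extinction rates (events per Ma, >= 0).
#' @param cap Maximum range size (default 2).
#' @param multiplier Optional dispersal multiplier matrix; defaults to the
#'   0/1 matrix implied by the adjacency.
#' @return A dense square rate matrix named by range states ("0" = null).
#' @export
build_q_matrix <- function(areas, d, e, cap = 2, multiplier = NULL) {
  stopifnot(d >= 0, e >= 0)
  tr <- dec_transitions(areas, cap, multiplier)
  Q <- q_from_transitions(tr, d, e)
  attr(Q, "states") <- tr$states
  Q
}

q_from_transitions <- function(tr, d, e) {
  S <- length(tr$states)
  Q <- matrix(0, S, S, dimnames = list(names(tr$states), names(tr$states)))
  if (!is.null(tr$gains)) {
    for (r in seq_len(nrow(tr$gains))) {
      Q[tr$gains$from[r], tr$gains$to[r]] <-
        Q[tr$gains$from[r], tr$gains$to[r]] + d * tr$gains$mult[r]
    }
  }
  for (r in seq_len(nrow(tr$losses))) {
    Q[tr$losses$from[r], tr$losses$to[r]] <-
      Q[tr$losses$from[r], tr$losses$to[r]] + e
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Transition-probability matrix over a branch of duration t (Ma); Pade
# scaling-and-squaring via Matrix::expm.
dec_pmatrix <- function(Q, t) {
  if (t == 0) {
    P <- diag(nrow(Q)); dimnames(P) <- dimnames(Q); return(P)
  }
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# Cladogenetic inheritance scenarios for a range `s` at a binary node:
# identical inheritance for single-area ranges; for multi-area ranges the
# classic DEC set of unique ordered (left, right) pairs -- allopatric splits
# ({a}, s \ {a}) and sympatric-subset splits ({a}, s) in both orders -- with
# equal weights.
dec_scenarios <- function(s) {
  if (length(s) <= 1) return(list(list(left = s, right = s)))
  out <- list(); seen <- character(0)
  add <- function(l, r) {
    key <- paste(state_key(l), "|", state_key(r))
    if (!(key %in% seen)) {
      seen <<- c(seen, key)
      out[[length(out) + 1]] <<- list(left = l, right = r)
    }
  }
  for (a in s) {
    rest <- setdiff(s, a)
    add(a, rest); add(rest, a)   # allopatric (vicariance)
    add(a, s);    add(s, a)      # sympatric subset
  }
  out
}

# Is a range connected under the adjacency graph (single areas count)?
# Disconnected ranges are unreachable by stepwise dispersal, so they are
# excluded from the root prior (they would otherwise soak up posterior mass
# through cladogenetic inheritance without any dispersal event).
range_connected <- function(s, adjacency) {
  if (length(s) <= 1) return(TRUE)
  seen <- s[1]
  repeat {
    grow <- s[!(s %in% seen) &
                vapply(s, function(a) any(adjacency[a, seen]), logical(1))]
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == length(s)
}

as_range_list <- function(tip_ranges) {
  if (is.data.frame(tip_ranges)) {
    out <- lapply(strsplit(as.character(tip_ranges$areas), ";", fixed = TRUE),
                  trimws)
    names(out) <- as.character(tip_ranges$taxon)
    return(out)
  }
  tip_ranges
}

# Pruning workspace: everything that does not depend on (d, e).
dec_workspace <- function(tree, tip_ranges, areas, cap = 2) {
  check_unit(tree, "Ma")
  tip_ranges <- as_range_list(tip_ranges)
  if (!ape::is.binary.phylo(tree)) {
    # zero-length binary resolution; cladogenetic scenarios then apply at
    # each resolved node (likelihood-equivalent for binary trees)
    tree2 <- ape::multi2di(tree, random = FALSE)
    tree2$edge.length[is.na(tree2$edge.length)] <- 0
    attr(tree2, "length_unit") <- "Ma"
    tree <- tree2
  }
  miss <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(miss)) stop("tips without range coding: ",
                         paste(miss, collapse = ", "))
  if (any(vapply(tip_ranges, length, 1L) == 0)) stop("empty tip range")
  tr <- dec_transitions(areas, cap)
  states <- tr$states
  S <- length(states)
  scen <- lapply(states, dec_scenarios)
  lookup <- tr$lookup
  scen_idx <- lapply(scen, function(sc) {
    t(vapply(sc, function(x) c(unname(lookup[state_key(x$left)]),
                               unname(lookup[state_key(x$right)])),
             numeric(2)))
  })
  n <- ape::Ntip(tree)
  tip_state <- vapply(tree$tip.label, function(lb) {
    range_state_index(states, tip_ranges[[lb]], areas)
  }, numeric(1))
  post_edges <- ape::reorder.phylo(tree, "postorder")$edge
  root_allowed <- which(vapply(states, function(s) {
    length(s) > 0 && range_connected(s, areas$adjacency)
  }, logical(1)))
  list(tree = tree, areas = areas, cap = cap, tr = tr, states = states,
       S = S, scen_idx = scen_idx, n = n, tip_state = tip_state,
       root_allowed = root_allowed,
       post_nodes = unique(post_edges[, 1]),
       children = split(tree$edge[, 2], tree$edge[, 1]),
       branch_len = stats::setNames(tree$edge.length, tree$edge[, 2]))
}

# Pruning pass for given (d, e); returns loglik plus per-node conditionals.
dec_prune <- function(ws, d, e) {
  Q <- q_from_transitions(ws$tr, d, e)
  S <- ws$S; n <- ws$n
  n_all <- n + ws$tree$Nnode
  P <- vector("list", n_all)
  for (ch in as.integer(names(ws$branch_len))) {
    P[[ch]] <- dec_pmatrix(Q, ws$branch_len[[as.character(ch)]])
  }
  L <- matrix(0, S, n_all)
  D <- matrix(0, S, n_all)
  logscale <- numeric(n_all)
  for (i in seq_len(n)) L[ws$tip_state[i], i] <- 1
  for (v in ws$post_nodes) {
    ch <- ws$children[[as.character(v)]]
    for (c_ in ch) D[, c_] <- P[[c_]] %*% L[, c_]
    lv <- numeric(S)
    for (si in seq_len(S)[-1]) {
      idx <- ws$scen_idx[[si]]
      lv[si] <- mean(D[idx[, 1], ch[1]] * D[idx[, 2], ch[2]])
    }
    mx <- max(lv)
    if (mx <= 0) stop("zero likelihood at node ", v)
    L[, v] <- lv / mx
    logscale[v] <- log(mx) + sum(logscale[ch])
  }
  root <- n + 1L
  ll <- log(mean(L[ws$root_allowed, root])) + logscale[root]
  list(loglik = ll, L = L, D = D, logscale = logscale, P = P, Q = Q)
}

#' DEC log-likelihood of tip ranges on a chronogram
#'
#' Felsenstein pruning over the anagenetic process of [build_q_matrix()],
#' with classic DEC cladogenetic scenarios (equal weights) at interior nodes
#' and a uniform root prior over adjacency-connected non-null ranges
#' (disconnected subsets are unreachable by stepwise dispersal and are
#' excluded from the prior). Polytomies are
#' resolved internally with zero-length branches before pruning.
#'
#' @param tree Chronogram (`length_unit == "Ma"`).
#' @param tip_ranges Named list of area-name vectors, or a data frame with
#'   columns `taxon` and `areas` (semicolon-separated area names).
#' @param areas An `area_set`.
#' @param d,e Dispersal and extinction rates (per Ma).
#' @param cap Maximum range size.
#' @return The log-likelihood.
#' @export
dec_loglik <- function(tree, tip_ranges, areas, d, e, cap = 2) {
  ws <- dec_workspace(tree, tip_ranges, areas, cap)
  dec_prune(ws, d, e)$loglik
}
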