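#' Exact permutation trend test for colonization events
#'
#' Tests whether younger colonization events have colder-adapted ancestors:
#' the observed statistic is the Pearson (or Spearman) correlation between
#' event age and the chosen tolerance character, and the one-sided p-value is
#' the fraction of permutations of the character values whose correlation is
#' at least the observed one (alternative: positive correlation, i.e.
#' "younger implies colder"). With n events at most 7 the permutation null is
#' exhaustive (all n! orderings); a t-test alternative is also available. A
#' constant character yields p = 1 with a warning.
#'
#' @param events Data frame with columns `age_ma` and the tolerance columns
#'   `t_cold`, `t_warm` (from the pipeline) or any numeric column named by
#'   `character`.
#' @param character `"cold"`, `"warm"` or `"range_width"` (warm - cold).
#' @param method `"exact_permutation"` (default), `"t_test"`, or
#'   `"posterior_beta"` (requires `beta_samples`).
#' @param rank_based Use Spearman rank correlation instead of Pearson.
#' @param beta_samples Posterior draws of the trend parameter (for
#'   `"posterior_beta"`: p is the posterior probability that the trend is
#'   >= 0, i.e. against cooling adaptation).
#' @return List of class `trend_result`: `statistic`, `p_value`, `method`.
#' @export
tolerance_trend_test <- function(events,
                                 character = c("cold", "warm", "range_width"),
                                 method = c("exact_permutation", "t_test",
                                            "posterior_beta"),
                                 rank_based = FALSE, beta_samples = NULL) {
  character <- match.arg(character)
  method <- match.arg(method)
  if (method == "posterior_beta") {
    if (is.null(beta_samples)) stop("posterior_beta requires beta_samples")
    p <- mean(beta_samples >= 0)
    return(structure(list(statistic = mean(beta_samples), p_value = p,
                          method = method), class = "trend_result"))
  }
  age <- events$age_ma
  val <- switch(character,
                cold = events$t_cold,
                warm = events$t_warm,
                range_width = events$t_warm - events$t_cold)
  if (length(age) < 3 || length(unique(age)) < 3) {
    stop("at least 3 events with distinct ages are required")
  }
  if (stats::sd(val) == 0) {
    warning("tolerance character is constant; correlation undefined, p = 1")
    return(structure(list(statistic = NA_real_, p_value = 1, method = method),
                     class = "trend_result"))
  }
  if (rank_based) { age <- rank(age); val <- rank(val) }
  r_obs <- stats::cor(age, val)
  if (method == "t_test") {
    ct <- stats::cor.test(age, val, alternative = "greater",
                          method = if (rank_based) "spearman" else "pearson",
                          exact = FALSE)
    return(structure(list(statistic = unname(ct$estimate),
                          p_value = ct$p.value, method = method),
                     class = "trend_result"))
  }
  n <- length(age)
  if (n > 7) stop("exhaustive permutation test supports at most 7 events")
  pm <- all_permutations(n)
  r_perm <- apply(pm, 1, function(ix) stats::cor(age, val[ix]))
  p <- mean(r_perm >= r_obs - 1e-12)
  structure(list(statistic = r_obs, p_value = p, method = method,
                 n_permutations = nrow(pm)), class = "trend_result")
}

# All permutations of 1..n as a matrix (n! rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[i, ]
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

#' Match ancestral tolerance ranges against the Beringian paleocurve
#'
#' For each colonization event, evaluates the Beringian temperature at the
#' event age and reports whether it lies within the ancestor's tolerance
#' interval `[t_cold - margin, t_warm + margin]`, together with the distance
#' to the interval (0 when inside), so near-misses stay visible.
#'
#' @param events Data frame with `clade` (or `label`), `age_ma`, `t_cold`,
#'   `t_warm`.
#' @param curve A `paleo_curve`.
#' @param margin Tolerance margin in degC (default 0).
#' @return Data frame with the Beringian temperature, the interval, a
#'   `match` flag and `distance_c`.
#' @export
beringia_match <- function(events, curve, margin = 0) {
  span <- range(curve$age_ma)
  out_of_span <- events$age_ma < span[1] | events$age_ma > span[2]
  if (any(out_of_span)) {
    lab <- if ("clade" %in% names(events)) events$clade else
      as.character(seq_len(nrow(events)))
    stop("event age outside the paleocurve span: ",
         paste(lab[out_of_span], collapse = ", "))
  }
  bt <- temp_at(curve, events$age_ma)
  lo <- events$t_cold - margin
  hi <- events$t_warm + margin
  dist <- pmax(lo - bt, bt - hi, 0)
  data.frame(events,
             beringia_temp_c = bt,
             match = bt >= lo & bt <= hi,
             distance_c = dist)
}

#' Maximum-parsimony ancestral states for an unordered character
#'
#' Unit-cost (Fitch) parsimony on a rooted tree, possibly with polytomies:
#' a dynamic program over the observed states gives the minimal change count,
#' and a second top-down pass yields, for every node, the full set of states
#' that occur in at least one globally most-parsimonious reconstruction (the
#' MPR set).
#'
#' @param tree A rooted `phylo`.
#' @param states Named character vector of tip states (all tips coded).
#' @param nodes Optional node IDs to report (default: all interior nodes).
#' @return List with `score` (minimal number of changes) and `node_states`
#'   (named list of MPR state sets per requested node).
#' @export
fitch_mp <- function(tree, states, nodes = NULL) {
  n <- ape::Ntip(tree)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("uncoded tips: ", paste(miss, collapse = ", "))
  lv <- sort(unique(as.character(states)))
  k <- length(lv)
  n_all <- n + tree$Nnode
  INF <- 1e9
  cost <- matrix(INF, k, n_all)
  for (i in seq_len(n)) {
    cost[match(states[[tree$tip.label[i]]], lv), i] <- 0
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  # child -> parent transition cost: min over child states of
  # cost(child state) + [state change]
  up_contrib <- matrix(0, k, n_all)
  for (v in post) {
    acc <- numeric(k)
    for (c_ in children[[as.character(v)]]) {
      mn <- min(cost[, c_])
      up_contrib[, c_] <- pmin(cost[, c_], mn + 1)
      acc <- acc + up_contrib[, c_]
    }
    cost[, v] <- acc
  }
  root <- n + 1L
  score <- min(cost[, root])
  # top-down: best achievable total cost when node v is fixed at state s
  down <- matrix(INF, k, n_all)
  down[, root] <- 0
  pre <- rev(post)
  for (v in pre) {
    for (c_ in children[[as.character(v)]]) {
      sib <- setdiff(children[[as.character(v)]], c_)
      above <- down[, v]
      for (s_ in sib) above <- above + up_contrib[, s_]
      # cost of the rest of the tree if child c_ has state t:
      # min over parent state s of above(s) + [s != t]
      best_any <- min(above)
      down[, c_] <- pmin(above, best_any + 1)
    }
  }
  total <- down + cost
  if (is.null(nodes)) nodes <- (n + 1L):n_all
  node_states <- lapply(nodes, function(v) lv[total[, v] <= score + 1e-9])
  names(node_states) <- as.character(nodes)
  list(score = score, node_states = node_states, levels = lv)
}
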