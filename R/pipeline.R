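#' Validate a pipeline input bundle
#'
#' Cross-checks every input against the tree before anything runs: taxa in
#' the traits/ranges/hostplant tables must match the tips, branch-length
#' units must be what each stage expects, and the delta-18O series must
#' cover the calibration anchors. All problems are collected and reported
#' together rather than failing at the first one.
#'
#' @param inputs A named list with (any of) `chronogram`, `phylogram`,
#'   `tolerances` (data frame `taxon`, `t_cold`, `t_warm`), `tip_ranges`
#'   (named list or `taxon`/`areas` data frame), `hostplants` (named
#'   character), `d18o` (data frame `age_ma`, `d18o_permil`), `anchors`.
#' @return List with `ok` (logical) and `errors` (character vector; empty
#'   when valid).
#' @export
validate_inputs <- function(inputs) {
  errs <- character(0)
  tree <- inputs$chronogram
  if (is.null(tree)) tree <- inputs$phylogram
  if (is.null(tree)) {
    errs <- c(errs, "no tree provided (chronogram or phylogram)")
  } else {
    tips <- tree$tip.label
    if (!is.null(inputs$chronogram) &&
        !identical(length_unit(inputs$chronogram), "Ma")) {
      errs <- c(errs, "chronogram branch lengths are not tagged as Ma")
    }
    if (!is.null(inputs$phylogram) &&
        !identical(length_unit(inputs$phylogram), "subs_per_site")) {
      errs <- c(errs, "phylogram branch lengths are not tagged as subs_per_site")
    }
    if (!is.null(inputs$chronogram) && !is.null(inputs$phylogram) &&
        !setequal(inputs$chronogram$tip.label, inputs$phylogram$tip.label)) {
      errs <- c(errs, "chronogram and phylogram tips differ")
    }
    check_taxa <- function(keys, what) {
      miss <- setdiff(tips, keys)
      extra <- setdiff(keys, tips)
      out <- character(0)
      if (length(miss)) {
        out <- c(out, paste0(what, " missing taxa: ",
                             paste(miss, collapse = ", ")))
      }
      if (length(extra)) {
        out <- c(out, paste0(what, " has unknown taxa: ",
                             paste(extra, collapse = ", ")))
      }
      out
    }
    if (!is.null(inputs$tolerances)) {
      errs <- c(errs, check_taxa(inputs$tolerances$taxon, "tolerance table"))
      bad <- inputs$tolerances$t_cold > inputs$tolerances$t_warm
      if (any(bad)) {
        errs <- c(errs, paste0("t_cold > t_warm for: ",
          paste(inputs$tolerances$taxon[bad], collapse = ", ")))
      }
    }
    if (!is.null(inputs$tip_ranges)) {
      rl <- as_range_list(inputs$tip_ranges)
      errs <- c(errs, check_taxa(names(rl), "range table"))
      if (any(lengths(rl) == 0)) errs <- c(errs, "empty range coding")
    }
    if (!is.null(inputs$hostplants)) {
      errs <- c(errs, check_taxa(names(inputs$hostplants), "hostplant table"))
    }
  }
  if (!is.null(inputs$d18o)) {
    anchors <- if (is.null(inputs$anchors)) default_anchors() else inputs$anchors
    sp <- range(inputs$d18o$age_ma)
    if (any(anchors$age_ma < sp[1] | anchors$age_ma > sp[2])) {
      errs <- c(errs, "calibration anchors outside the delta-18O age span")
    }
  }
  list(ok = length(errs) == 0, errors = errs)
}

#' Run the full colonization-analysis pipeline
#'
#' Executes the stages in dependency order — dating, DEC ancestral ranges
#' (with Old World to New World crossing detection), thermal-tolerance MCMC
#' with ancestral reconstruction at the colonization nodes, paleocurve
#' calibration, and the gateway tests (cooling trend, tolerance/paleoclimate
#' match, hostplant parsimony) — and writes `events.csv`, `trend.json`,
#' `match.csv`, `ages.csv` and `manifest.json` under `out_dir`. Rerunning
#' with the same inputs and seed reproduces identical outputs.
#'
#' @param inputs As for [validate_inputs()]; `chronogram`, `tip_ranges`,
#'   `tolerances`, `hostplants` and `d18o` are required by the stages that
#'   use them.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; the gateway stage
#'   refuses to run without its upstream dependencies.
#' @param seed Integer seed for every stochastic stage.
#' @param mcmc An [mcmc_config()] for the thermal stage.
#' @param age_source `"clock_grid"` dates the phylogram over the
#'   method-by-rate grid and uses mean ages; `"chronogram"` reads node ages
#'   directly off the input chronogram.
#' @param cap,anchors,smoothing_window Stage parameters.
#' @return A list with the stage results and the manifest (invisibly
#'   written as JSON).
#' @export
run_pipeline <- function(inputs, out_dir,
                         stages = c("dating", "dec", "thermal", "paleo",
                                    "gateway"),
                         seed = 1L, mcmc = mcmc_config("desk"),
                         age_source = c("chronogram", "clock_grid"),
                         cap = 2, anchors = default_anchors(),
                         smoothing_window = 50) {
  age_source <- match.arg(age_source)
  val <- validate_inputs(inputs)
  if (!val$ok) {
    stop("invalid inputs:\n  - ", paste(val$errors, collapse = "\n  - "))
  }
  if ("gateway" %in% stages) {
    need <- c("dec", "thermal", "paleo")
    if (age_source == "clock_grid") need <- c("dating", need)
    lack <- setdiff(need, stages)
    if (length(lack)) {
      stop("gateway stage requires upstream stage(s): ",
           paste(lack, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)
  chrono <- inputs$chronogram
  groups <- world_groups()

  if ("dating" %in% stages) {
    if (is.null(inputs$phylogram)) stop("dating stage requires a phylogram")
    res$dating <- clock_grid(inputs$phylogram, seed = seed)
  }
  if ("dec" %in% stages) {
    res$dec <- dec_fit(chrono, inputs$tip_ranges,
                       if (is.null(inputs$areas)) default_areas() else
                         inputs$areas, cap = cap)
    res$crossings <- count_crossings(res$dec, groups$old_world,
                                     groups$new_world)
  }
  if ("thermal" %in% stages) {
    tr_tree <- if (is.null(inputs$phylogram)) chrono else inputs$phylogram
    xm <- as.matrix(inputs$tolerances[, c("t_cold", "t_warm")])
    rownames(xm) <- inputs$tolerances$taxon
    res$thermal_compare <- compare_models(xm, tr_tree)
    res$thermal <- fit_mcmc(xm, tr_tree,
                            model = res$thermal_compare$best,
                            config = mcmc, seed = seed)
  }
  if ("paleo" %in% stages) {
    sm <- running_mean(inputs$d18o, smoothing_window)
    res$curve <- calibrate_paleocurve(sm, anchors)
  }

  if ("gateway" %in% stages) {
    ev <- res$crossings$events
    if (!nrow(ev)) stop("gateway stage: no Old World -> New World crossings")
    # colonization node = child node of the branch carrying the crossing
    # (the first node established on the far side)
    col_nodes <- ev$child_node
    ages_tab <- if (age_source == "chronogram") {
      a <- node_ages_chronogram(chrono)
      data.frame(node = seq_along(a), mean_age_ma = a)
    } else {
      mean_ages(res$dating, sort(unique(col_nodes)))
    }
    anc <- ancestral_states(res$thermal, sort(unique(col_nodes)))
    events <- data.frame(
      clade = ev$child_label,
      node = col_nodes,
      age_ma = ages_tab$mean_age_ma[match(col_nodes, ages_tab$node)],
      t_cold = anc$t_cold_mean[match(col_nodes, anc$node)],
      t_warm = anc$t_warm_mean[match(col_nodes, anc$node)],
      route = ev$route)
    events <- events[order(-events$age_ma), ]
    rownames(events) <- NULL
    res$events <- events
    res$trend <- tolerance_trend_test(events, "cold")
    res$match <- beringia_match(events, res$curve)
    if (!is.null(inputs$hostplants)) {
      res$hostplant <- fitch_mp(chrono, inputs$hostplants,
                                nodes = sort(unique(col_nodes)))
    }
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(statistic = res$trend$statistic, p_value = res$trend$p_value,
           method = res$trend$method),
      file.path(out_dir, "trend.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(res$match, file.path(out_dir, "match.csv"),
                     row.names = FALSE)
  }
  if ("dating" %in% stages) {
    n_all <- ape::Ntip(inputs$phylogram) + inputs$phylogram$Nnode
    ages_all <- mean_ages(res$dating,
                          (ape::Ntip(inputs$phylogram) + 1L):n_all)
    utils::write.csv(ages_all, file.path(out_dir, "ages.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("beringia")),
    seed = seed,
    stages = stages,
    age_source = age_source,
    mcmc = mcmc[c("iterations", "burn_in", "sample_period", "preset")],
    outputs = list())
  for (f in list.files(out_dir, pattern = "\\.(csv|json)$")) {
    if (f == "manifest.json") next
    manifest$outputs[[f]] <-
      unname(tools::md5sum(file.path(out_dir, f)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
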