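# Event-driven (next-event) forward simulation of the linear birth-death
# process, with piecewise-constant extinction pulses. Serves two roles:
# the Monte Carlo oracle for the closed forms in bd-moments.R, and the
# synthetic-data generator for pipeline tests.
#
# Time conventions: the process runs forward from the founder(s) at 0 to the
# horizon; ages (stem, crown, pulse bounds) are reported backward from the
# present (= end of horizon) in Ma, matching chronogram conventions.

#' Birth-death simulation scenario
#'
#' @param lambda Speciation rate per lineage per Myr (>= 0).
#' @param mu Background extinction rate per lineage per Myr (>= 0).
#' @param horizon Total simulated time span, Myr (> 0). This is the stem age
#'   of the simulated clade.
#' @param pulses Optional episodic extinction pulses emulating aridification
#'   waves: a data frame (or 3-column matrix) with columns `older_ma`,
#'   `younger_ma`, `mu` giving, for each pulse, its bounds in Ma before
#'   present and the extinction rate that replaces `mu` inside it. Intervals
#'   must lie within `[0, horizon]` and not overlap.
#' @param condition Survival conditioning, implemented by rejection:
#'   `"none"` (one founder, no conditioning), `"stem_survival"` (one founder,
#'   at least one extant descendant), or `"crown_survival"` (two founders,
#'   both with extant descendants).
#' @param seed Optional integer seed; identical seed + scenario gives an
#'   identical result sequence.
#' @param max_lineages Population cap guarding against runaway growth.
#' @param max_rejections Cap on rejection-sampling attempts per conditioned
#'   draw; exceeding it is an explicit error, never a silent retry.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(lambda, mu = 0, horizon, pulses = NULL,
                         condition = c("none", "stem_survival", "crown_survival"),
                         seed = NULL, max_lineages = 1e5, max_rejections = 1e6) {
  condition <- match.arg(condition)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    .stop_domain("'lambda' must be a single non-negative rate")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    .stop_domain("'mu' must be a single non-negative rate")
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) || horizon <= 0)
    .stop_domain("'horizon' must be a single positive time span in Myr")
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses)
    if (ncol(pulses) != 3L)
      .stop_domain("'pulses' needs columns older_ma, younger_ma, mu")
    names(pulses) <- c("older_ma", "younger_ma", "mu")
    swap <- pulses$older_ma < pulses$younger_ma
    if (any(swap)) pulses[swap, 1:2] <- pulses[swap, 2:1]
    if (any(pulses$younger_ma < 0) || any(pulses$older_ma > horizon))
      .stop_domain("pulse intervals must lie within [0, horizon] Ma")
    if (any(pulses$mu < 0)) .stop_domain("pulse extinction rates must be >= 0")
    o <- order(pulses$older_ma, decreasing = TRUE)
    pulses <- pulses[o, , drop = FALSE]
    if (nrow(pulses) > 1L &&
        any(pulses$older_ma[-1L] > pulses$younger_ma[-nrow(pulses)]))
      .stop_domain("pulse intervals must not overlap")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(lambda = lambda, mu = mu, horizon = horizon, pulses = pulses,
                 condition = condition, seed = seed,
                 max_lineages = max_lineages, max_rejections = max_rejections),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Birth-death scenario: lambda = %g, mu = %g, horizon = %g Myr, condition = %s\n",
              x$lambda, x$mu, x$horizon, x$condition))
  if (!is.null(x$pulses)) {
    cat("Extinction pulses (Ma before present):\n")
    print(x$pulses)
  }
  invisible(x)
}

# forward-time epochs (start, end, mu) from backward-age pulses
.build_epochs <- function(scn) {
  h <- scn$horizon
  if (is.null(scn$pulses) || nrow(scn$pulses) == 0L)
    return(data.frame(start = 0, end = h, mu = scn$mu))
  breaks <- sort(unique(c(0, h, h - scn$pulses$older_ma, h - scn$pulses$younger_ma)))
  start <- breaks[-length(breaks)]
  end <- breaks[-1L]
  mid_ma <- h - (start + end) / 2
  mu <- rep(scn$mu, length(start))
  for (i in seq_len(nrow(scn$pulses))) {
    inside <- mid_ma < scn$pulses$older_ma[i] & mid_ma > scn$pulses$younger_ma[i]
    mu[inside] <- scn$pulses$mu[i]
  }
  data.frame(start = start, end = end, mu = mu)
}

# fast counts-only realisation: per-founder extant counts at the horizon
.sim_counts <- function(lambda, epochs, founders, max_lineages) {
  k <- rep(1L, founders)
  for (e in seq_len(nrow(epochs))) {
    t <- epochs$start[e]; t_end <- epochs$end[e]; mu <- epochs$mu[e]
    tot <- lambda + mu
    repeat {
      K <- sum(k)
      if (K == 0L) return(k)
      if (tot == 0) break
      t <- t + stats::rexp(1L, K * tot)
      if (t >= t_end) break
      i <- if (founders == 1L) 1L else sample.int(founders, 1L, prob = k)
      if (stats::runif(1L) * tot < lambda) {
        k[i] <- k[i] + 1L
        if (K + 1L > max_lineages)
          .stop_domain("population exceeded max_lineages = %g", max_lineages)
      } else {
        k[i] <- k[i] - 1L
      }
    }
  }
  k
}

# full realisation with genealogy bookkeeping; children always get larger ids
# than their parent, which the post-processing sweeps rely on
.sim_tree <- function(lambda, epochs, founders, max_lineages) {
  cap <- 64L
  parent <- integer(cap); child1 <- integer(cap); child2 <- integer(cap)
  t_birth <- numeric(cap); t_end <- numeric(cap)
  n_nodes <- founders
  parent[seq_len(founders)] <- 0L
  t_birth[seq_len(founders)] <- 0
  active <- seq_len(founders)
  grow <- function() {
    parent <<- c(parent, integer(cap)); child1 <<- c(child1, integer(cap))
    child2 <<- c(child2, integer(cap)); t_birth <<- c(t_birth, numeric(cap))
    t_end <<- c(t_end, numeric(cap)); cap <<- 2L * cap
  }
  horizon <- epochs$end[nrow(epochs)]
  for (e in seq_len(nrow(epochs))) {
    t <- epochs$start[e]; te <- epochs$end[e]; mu <- epochs$mu[e]
    tot <- lambda + mu
    repeat {
      K <- length(active)
      if (K == 0L) break
      if (tot == 0) break
      t <- t + stats::rexp(1L, K * tot)
      if (t >= te) break
      j <- if (K == 1L) 1L else sample.int(K, 1L)
      i <- active[j]
      if (stats::runif(1L) * tot < lambda) {
        if (n_nodes + 2L > length(parent)) grow()
        c1 <- n_nodes + 1L; c2 <- n_nodes + 2L; n_nodes <- n_nodes + 2L
        parent[c1] <- i; parent[c2] <- i
        t_birth[c1] <- t; t_birth[c2] <- t
        child1[i] <- c1; child2[i] <- c2; t_end[i] <- t
        active[j] <- c1; active <- c(active, c2)
        if (length(active) > max_lineages)
          .stop_domain("population exceeded max_lineages = %g", max_lineages)
      } else {
        t_end[i] <- t
        active <- active[-j]
      }
    }
    if (length(active) == 0L) break
  }
  t_end[active] <- horizon
  list(n_nodes = n_nodes, parent = parent[seq_len(n_nodes)],
       child1 = child1[seq_len(n_nodes)], child2 = child2[seq_len(n_nodes)],
       t_birth = t_birth[seq_len(n_nodes)], t_end = t_end[seq_len(n_nodes)],
       survivors = active, founders = founders, horizon = horizon)
}

# surviving-descendant counts per node (children have larger ids)
.surv_counts <- function(sim) {
  ns <- integer(sim$n_nodes)
  ns[sim$survivors] <- 1L
  for (i in rev(seq_len(sim$n_nodes)))
    if (sim$parent[i] > 0L) ns[sim$parent[i]] <- ns[sim$parent[i]] + ns[i]
  ns
}

# forward time of the MRCA of the survivors (NA if < 2 survivors)
.crown_time <- function(sim, ns) {
  if (length(sim$survivors) < 2L) return(NA_real_)
  if (sim$founders == 2L && ns[1L] > 0L && ns[2L] > 0L) return(0)
  i <- if (sim$founders == 2L) which(ns[1:2] > 0L) else 1L
  repeat {
    c1 <- sim$child1[i]
    if (c1 == 0L) return(NA_real_)  # unreachable when >= 2 survivors below i
    c2 <- sim$child2[i]
    if (ns[c1] > 0L && ns[c2] > 0L) return(sim$t_birth[c1])
    i <- if (ns[c1] > 0L) c1 else c2
  }
}

# newick for the subtree rooted in lineage i, survivors only, branches spliced
# through extinct side-branches; `start` is the forward time the stem of the
# returned clade begins
.newick_pruned <- function(sim, ns, i, start) {
  repeat {
    c1 <- sim$child1[i]
    if (c1 == 0L)
      return(sprintf("t%d:%.15g", i, sim$t_end[i] - start))
    c2 <- sim$child2[i]
    if (ns[c1] > 0L && ns[c2] > 0L)
      return(sprintf("(%s,%s):%.15g",
                     .newick_pruned(sim, ns, c1, sim$t_end[i]),
                     .newick_pruned(sim, ns, c2, sim$t_end[i]),
                     sim$t_end[i] - start))
    i <- if (ns[c1] > 0L) c1 else c2
  }
}

# newick with extinct lineages retained
.newick_full <- function(sim, i, start) {
  c1 <- sim$child1[i]
  if (c1 == 0L) {
    lab <- if (sim$t_end[i] >= sim$horizon) "t%d" else "x%d"
    return(sprintf(paste0(lab, ":%.15g"), i, sim$t_end[i] - start))
  }
  sprintf("(%s,%s):%.15g",
          .newick_full(sim, sim$child1[i], sim$t_end[i]),
          .newick_full(sim, sim$child2[i], sim$t_end[i]),
          sim$t_end[i] - start)
}

.sim_to_tree <- function(sim, ns, keep_extinct = FALSE) {
  if (keep_extinct) {
    roots <- seq_len(sim$founders)
    parts <- vapply(roots, function(i) .newick_full(sim, i, 0), character(1))
  } else {
    roots <- which(ns[seq_len(sim$founders)] > 0L)
    n_tips_total <- sum(ns[roots])
    if (n_tips_total < 2L) return(NULL)
    parts <- vapply(roots, function(i) .newick_pruned(sim, ns, i, 0), character(1))
  }
  txt <- if (length(parts) == 1L) paste0(parts, ";")
         else paste0("(", paste(parts, collapse = ","), ");")
  ape::read.tree(text = txt)
}

.meets_condition <- function(condition, k_by_founder) {
  switch(condition,
         none = TRUE,
         stem_survival = sum(k_by_founder) > 0L,
         crown_survival = all(k_by_founder > 0L))
}

.founders_for <- function(condition) if (condition == "crown_survival") 2L else 1L

# one conditioned draw; mode = "counts" | "ages" | "tree"
.draw <- function(scn, mode, keep_extinct = FALSE) {
  epochs <- .build_epochs(scn)
  founders <- .founders_for(scn$condition)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > scn$max_rejections)
      .stop_domain("survival condition '%s' not met within max_rejections = %g attempts",
                   scn$condition, scn$max_rejections)
    if (mode == "counts") {
      k <- .sim_counts(scn$lambda, epochs, founders, scn$max_lineages)
      if (.meets_condition(scn$condition, k))
        return(list(extant_count = sum(k), crown_age = NA_real_,
                    tree = NULL, attempts = attempts))
    } else {
      sim <- .sim_tree(scn$lambda, epochs, founders, scn$max_lineages)
      ns <- .surv_counts(sim)
      if (.meets_condition(scn$condition, ns[seq_len(founders)])) {
        tc <- .crown_time(sim, ns)
        tree <- if (mode == "tree") .sim_to_tree(sim, ns, keep_extinct) else NULL
        return(list(extant_count = length(sim$survivors),
                    crown_age = if (is.na(tc)) NA_real_ else scn$horizon - tc,
                    tree = tree, attempts = attempts))
      }
    }
  }
}

#' Simulate one birth-death clade
#'
#' Exact stochastic (next-event) simulation of a linear birth-death process
#' from one founder (or two, under crown conditioning) across the scenario
#' horizon, with piecewise-constant extinction given the scenario's pulses.
#' Pulse boundaries are handled as rate change-points, never by discretised
#' time steps. Conditioning is implemented by rejection with an explicit cap.
#'
#' @param scenario A [sim_scenario()].
#' @param keep_tree Build the survivor tree (an ultrametric `ape::phylo` with
#'   branch lengths in Myr)? `NULL` is returned when fewer than two tips
#'   survive.
#' @param keep_extinct Retain extinct lineages in the returned tree (tips
#'   labelled `x<id>`)? Default prunes them.
#' @return An object of class `"sim_result"`: list with `extant_count`,
#'   `tree` (or `NULL`), `crown_age` (Ma; the deepest split among survivors,
#'   `NA` with fewer than two survivors), `stem_age` (= horizon, Ma), and
#'   `attempts` (rejection-sampling draws used).
#' @examples
#' scn <- sim_scenario(0.3, 0.15, horizon = 10,
#'                     condition = "stem_survival", seed = 1)
#' simulate_clade(scn)
#' @export
simulate_clade <- function(scenario, keep_tree = TRUE, keep_extinct = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  d <- .draw(scenario, mode = if (keep_tree) "tree" else "ages",
             keep_extinct = keep_extinct)
  structure(list(extant_count = d$extant_count, tree = d$tree,
                 crown_age = d$crown_age, stem_age = scenario$horizon,
                 attempts = d$attempts),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Birth-death clade: %d extant lineages, stem age %g Ma, crown age %s Ma\n",
              x$extant_count, x$stem_age,
              if (is.na(x$crown_age)) "NA" else format(x$crown_age, digits = 4)))
  if (!is.null(x$tree)) cat(sprintf("  survivor tree with %d tips attached\n",
                                    length(x$tree$tip.label)))
  invisible(x)
}

#' Simulate an ensemble of birth-death clades
#'
#' Independent conditioned draws from one scenario, streamed through a single
#' seeded random stream, with summary statistics computed exactly over the
#' drawn sample.
#'
#' @param scenario A [sim_scenario()]; its `seed` (if any) initialises the
#'   stream once, so the whole ensemble is reproducible.
#' @param reps Number of replicates (>= 1).
#' @param probe_sizes Optional integer clade sizes at which to report the
#'   empirical tail `P(N >= n)`.
#' @param track `"counts"` records extant counts only (fast);
#'   `"ages"` additionally records crown ages.
#' @return An object of class `"sim_ensemble"`: list with `counts` (integer
#'   vector of length `reps`), `crown_ages` (if tracked), and `summary`
#'   (list: `mean`, `var`, `tail` named by probe size).
#' @examples
#' scn <- sim_scenario(0.2, 0, horizon = 5, seed = 42)
#' simulate_ensemble(scn, 100, probe_sizes = c(2, 5))$summary
#' @export
simulate_ensemble <- function(scenario, reps, probe_sizes = NULL,
                              track = c("counts", "ages")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  track <- match.arg(track)
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1)
    .stop_domain("'reps' must be >= 1")
  reps <- as.integer(reps)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  counts <- integer(reps)
  crown_ages <- if (track == "ages") numeric(reps) else NULL
  for (i in seq_len(reps)) {
    d <- .draw(scenario, mode = track)
    counts[i] <- d$extant_count
    if (track == "ages") crown_ages[i] <- d$crown_age
  }
  tail <- if (!is.null(probe_sizes))
    stats::setNames(vapply(probe_sizes, function(nn) mean(counts >= nn),
                           numeric(1)),
                    paste0("n", probe_sizes))
  structure(list(counts = counts, crown_ages = crown_ages,
                 summary = list(mean = mean(counts),
                                var = if (reps > 1L) stats::var(counts) else 0,
                                tail = tail),
                 scenario = scenario, reps = reps),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("Birth-death ensemble: %d replicates, mean extant count %.3f (var %.3f)\n",
              x$reps, x$summary$mean, x$summary$var))
  if (!is.null(x$summary$tail)) {
    cat("Empirical tail P(N >= n):\n"); print(x$summary$tail)
  }
  invisible(x)
}

#' Stem-crown gap distribution under a scenario
#'
#' Distribution of `stem_age - crown_age` (Ma) across simulated clades, a
#' diagnostic for episodic extinction: pulses that strike deep lineages leave
#' surviving clades with shallow crowns and hence wide stem-crown gaps.
#' Replicates with fewer than two survivors carry no crown age and are
#' dropped.
#'
#' @inheritParams simulate_ensemble
#' @return Numeric vector of gaps (one per replicate with a defined crown
#'   age); zero usable replicates yields a zero-length vector with a warning.
#' @examples
#' scn <- sim_scenario(0.3, 0, horizon = 10,
#'                     condition = "stem_survival", seed = 7)
#' mean(stem_crown_gap_distribution(scn, 50))
#' @export
stem_crown_gap_distribution <- function(scenario, reps) {
  ens <- simulate_ensemble(scenario, reps, track = "ages")
  gaps <- scenario$horizon - ens$crown_ages
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0L)
    warning("no replicate left >= 2 survivors: empty gap distribution",
            call. = FALSE)
  gaps
}
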