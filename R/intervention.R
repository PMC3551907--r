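# Immunization experiment harness: rank nodes by a centrality strategy,
# immunize the top i% at the moment rho% of the network is percolated,
# and measure the time from intervention to percolation saturation,
# censoring at a fixed post-intervention cutoff.

#' Rank candidate nodes for immunization
#'
#' Candidates are the non-percolated nodes (state < 1).  Strategies:
#' `"pc"` and `"bc"` rank descending by [percolation_centrality()] /
#' [betweenness_centrality()]; `"hop"` ranks ascending by
#' [hop_distance()] (ring vaccination: closest to the contagion first),
#' excluding hop-distance-0 nodes.  Ties break stably by graph node
#' order.
#'
#' @param graph A simple `igraph` graph.
#' @param states Current node states.
#' @param strategy `"pc"`, `"bc"`, or `"hop"`.
#' @return Character vector of candidate nodes, best-to-immunize first
#'   (empty if every node is percolated).
#' @export
rank_for_immunization <- function(graph, states, strategy = c("pc", "bc", "hop")) {
  strategy <- match.arg(strategy)
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  cand <- which(x < 1)
  if (!length(cand)) return(character(0))
  if (strategy == "hop") {
    h <- as.numeric(hop_distance(graph, states, threshold = 1))
    cand <- cand[h[cand] > 0]            # drop already-percolated sources
    ord <- cand[order(h[cand], cand)]    # ascending distance, stable
  } else {
    sc <- if (strategy == "pc") {
      as.numeric(percolation_centrality(graph, states))
    } else {
      as.numeric(betweenness_centrality(graph))
    }
    ord <- cand[order(-sc[cand], cand)]  # descending score, stable
  }
  nodes[ord]
}

# One replicate: spread to the rho% threshold, intervene, spread on until
# saturation or the cutoff.  Runs inside the caller's RNG state; the
# stepping is draw-for-draw identical to simulate_spread() so that an
# i_percent = 0 intervention reproduces the uninterrupted trajectory.
#' @noRd
intervention_replicate <- function(graph, tA, nodes, seed_node, beta,
                                   rho, i_percent, strategy,
                                   saturation_fraction, post_cutoff,
                                   max_pre_steps, static_scores = NULL) {
  n <- length(nodes)
  infected <- logical(n)
  infected[match(seed_node, nodes)] <- TRUE
  inf_time <- rep(Inf, n)
  inf_time[infected] <- 1
  immune_mask <- logical(n)
  pre_target <- ceiling(rho / 100 * n)
  sat_target <- saturation_fraction * n
  t <- 1L
  while (sum(infected) < pre_target) {
    if (t >= max_pre_steps ||
        !any(!infected & !immune_mask & as.numeric(tA %*% infected) > 0)) {
      return(list(ok = FALSE))           # spread died before reaching rho%
    }
    new <- si_step(tA, infected, immune_mask, beta)
    t <- t + 1L
    infected[new] <- TRUE
    inf_time[new] <- t
  }
  t_int <- t
  n_imm <- floor(i_percent / 100 * n)
  if (n_imm > 0L) {
    ranking <- if (strategy == "bc" && !is.null(static_scores)) {
      cand <- which(!infected)
      nodes[cand[order(-static_scores[cand], cand)]]
    } else {
      rank_for_immunization(graph, stats::setNames(as.numeric(infected), nodes),
                            strategy)
    }
    imm <- utils::head(ranking, min(n_imm, length(ranking)))
    immune_mask[match(imm, nodes)] <- TRUE
  }
  steps_post <- 0L
  censored <- FALSE
  time <- NA_real_
  repeat {
    if (sum(infected) >= sat_target) {
      time <- steps_post
      break
    }
    if (steps_post >= post_cutoff ||
        !any(!infected & !immune_mask & as.numeric(tA %*% infected) > 0)) {
      censored <- TRUE
      time <- post_cutoff                # aborted runs enter at the cutoff
      break
    }
    new <- si_step(tA, infected, immune_mask, beta)
    steps_post <- steps_post + 1L
    infected[new] <- TRUE
    inf_time[new] <- t_int + steps_post
  }
  list(ok = TRUE, time = time, censored = censored, t_intervention = t_int,
       infection_time = stats::setNames(inf_time, nodes),
       immune = nodes[immune_mask])
}

#' Run a targeted immunization experiment
#'
#' For each replicate: simulate SI spread from the seed until at least
#' `rho`% of nodes are fully percolated; compute the chosen strategy's
#' ranking on the current states; immunize the top
#' \eqn{\lfloor i\% \cdot N \rfloor} candidates (state permanently zero,
#' never transmit); continue simulating; and record the number of steps
#' from intervention until the fully percolated count reaches
#' `saturation_fraction * N`.  Runs that never saturate are censored at
#' `post_cutoff` steps and recorded at that value.  Replicates where the
#' spread dies out before reaching `rho`% are redrawn with a fresh seed,
#' up to `retry_budget` attempts each.
#'
#' @param graph A simple `igraph` graph.
#' @param rho Percent of nodes percolated before intervention,
#'   \eqn{0 < \rho < 100}.
#' @param i_percent Percent of nodes immunized, \eqn{[0, 100]}.  With 0
#'   the trajectory is identical, draw for draw, to
#'   [simulate_spread()] under the same replicate seed.
#' @param strategy `"pc"`, `"bc"`, or `"hop"`.
#' @param beta Transmission probability.
#' @param seed_node Seed node name, or `NULL` to sample one uniformly per
#'   replicate.
#' @param saturation_fraction Fraction of nodes defining saturation
#'   (default 0.9).
#' @param post_cutoff Censoring cutoff in steps after immunization
#'   (default 30).
#' @param replicates Number of replicates.
#' @param rng_seed Master seed; all replicate seeds derive from it.
#' @param replicate_seeds Optional explicit integer vector of per-replicate
#'   seeds (overrides `rng_seed` derivation); used to pair replicates
#'   across strategies.
#' @param max_pre_steps Safety bound on pre-intervention steps.
#' @param retry_budget Redraw attempts per replicate when the spread dies
#'   early.
#' @param keep_traces Keep per-replicate infection times (attribute
#'   `traces`).
#' @return A data frame with one row per replicate: `replicate`,
#'   `seed_node`, `t_intervention`, `time` (steps from intervention to
#'   saturation, `post_cutoff` if censored), `censored`, `attempts`.
#'   Attributes: `replicate_seeds` (the seeds actually used) and,
#'   if requested, `traces`.
#' @export
run_intervention <- function(graph, rho, i_percent, strategy, beta,
                             seed_node = NULL, saturation_fraction = 0.9,
                             post_cutoff = 30L, replicates = 1L,
                             rng_seed = NULL, replicate_seeds = NULL,
                             max_pre_steps = 1000L, retry_budget = 20L,
                             keep_traces = FALSE) {
  graph <- check_graph(graph)
  strategy <- match.arg(strategy, c("pc", "bc", "hop"))
  assert_scalar_number(rho, "rho", lo = 1e-12, hi = 100 - 1e-12)
  assert_scalar_number(i_percent, "i_percent", lo = 0, hi = 100)
  assert_scalar_number(beta, "beta", lo = 0, hi = 1)
  assert_scalar_number(saturation_fraction, "saturation_fraction",
                       lo = 1e-12, hi = 1)
  nodes <- node_names(graph)
  if (!is.null(seed_node) && !seed_node %in% nodes) {
    stop("seed_node is not in the graph", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.null(replicate_seeds)) {
    draw <- function() sample.int(.Machine$integer.max - 1L, replicates)
    replicate_seeds <- if (is.null(rng_seed)) draw() else {
      withr::with_seed(as.integer(rng_seed), draw())
    }
  } else {
    replicate_seeds <- as.integer(replicate_seeds)
    if (length(replicate_seeds) != replicates) {
      stop("replicate_seeds must have one seed per replicate", call. = FALSE)
    }
  }
  tA <- spread_matrix(graph)
  static_bc <- if (strategy == "bc") as.numeric(betweenness_centrality(graph)) else NULL
  rows <- vector("list", replicates)
  traces <- if (keep_traces) vector("list", replicates) else NULL
  for (k in seq_len(replicates)) {
    res <- NULL
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > retry_budget) {
        stop(sprintf("replicate %d: spread died out before reaching rho%% in every one of %d attempts",
                     k, retry_budget), call. = FALSE)
      }
      # retries perturb the seed deterministically
      seed_k <- (replicate_seeds[k] - 1L + (attempts - 1L) * 7919L) %%
        (.Machine$integer.max - 1L) + 1L
      res <- withr::with_seed(seed_k, {
        sn <- seed_node %||% sample(nodes, 1L)
        r <- intervention_replicate(graph, tA, nodes, sn, beta, rho, i_percent,
                                    strategy, saturation_fraction, post_cutoff,
                                    max_pre_steps, static_scores = static_bc)
        r$seed_node <- sn
        r
      })
      if (res$ok) break
    }
    rows[[k]] <- data.frame(replicate = k, seed_node = res$seed_node,
                            t_intervention = res$t_intervention,
                            time = res$time, censored = res$censored,
                            attempts = attempts, stringsAsFactors = FALSE)
    if (keep_traces) {
      traces[[k]] <- list(infection_time = res$infection_time,
                          immune = res$immune)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicate_seeds") <- replicate_seeds
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Saturation-time grid over (rho, i) and strategies
#'
#' Full factorial sweep of [run_intervention()] over percolated-fraction
#' and immunized-fraction levels for each strategy, with replicate seeds
#' shared across cells and strategies (paired comparisons).  Censored
#' replicates enter the cell means at `post_cutoff`.  The per-cell winner
#' is the strategy with the maximum mean saturation time (a longer delay
#' means a more effective intervention); exact ties are recorded as ties.
#'
#' @param graph A simple `igraph` graph, or a list of graphs cycled over
#'   replicates.
#' @param rho Numeric vector of percolated-percentage levels.
#' @param i_percent Numeric vector of immunized-percentage levels.
#' @param strategies Subset of `c("pc", "bc", "hop")`.
#' @inheritParams run_intervention
#' @return An object of class `saturation_table`: list with `cells`
#'   (data frame `rho,i_percent,strategy,mean_time,censored,n`),
#'   `winners` (data frame `rho,i_percent,winner`, ties as
#'   `"tie:a+b"`), and `replicates` (the long per-replicate data frame).
#' @export
experiment_grid <- function(graph, rho, i_percent,
                            strategies = c("pc", "bc", "hop"), beta,
                            seed_node = NULL, saturation_fraction = 0.9,
                            post_cutoff = 30L, replicates = 5L,
                            rng_seed = NULL, retry_budget = 20L) {
  strategies <- match.arg(strategies, c("pc", "bc", "hop"), several.ok = TRUE)
  graphs <- if (igraph::is_igraph(graph)) list(graph) else graph
  replicates <- as.integer(replicates)
  draw <- function() sample.int(.Machine$integer.max - 1L, replicates)
  seeds <- if (is.null(rng_seed)) draw() else withr::with_seed(as.integer(rng_seed), draw())
  long <- list()
  for (r in rho) {
    for (ip in i_percent) {
      for (st in strategies) {
        df <- if (length(graphs) == 1L) {
          # single graph: one call per cell so static rankings amortize
          run_intervention(graphs[[1L]], rho = r, i_percent = ip,
                           strategy = st, beta = beta, seed_node = seed_node,
                           saturation_fraction = saturation_fraction,
                           post_cutoff = post_cutoff, replicates = replicates,
                           replicate_seeds = seeds,
                           retry_budget = retry_budget)
        } else {
          per_rep <- lapply(seq_len(replicates), function(k) {
            g <- graphs[[(k - 1L) %% length(graphs) + 1L]]
            run_intervention(g, rho = r, i_percent = ip, strategy = st,
                             beta = beta, seed_node = seed_node,
                             saturation_fraction = saturation_fraction,
                             post_cutoff = post_cutoff, replicates = 1L,
                             replicate_seeds = seeds[k],
                             retry_budget = retry_budget)
          })
          out <- do.call(rbind, per_rep)
          out$replicate <- seq_len(replicates)
          out
        }
        df$rho <- r; df$i_percent <- ip; df$strategy <- st
        long[[length(long) + 1L]] <- df
      }
    }
  }
  long <- do.call(rbind, long)
  agg <- do.call(rbind, lapply(split(long, long[c("rho", "i_percent", "strategy")], drop = TRUE),
    function(d) data.frame(rho = d$rho[1L], i_percent = d$i_percent[1L],
                           strategy = d$strategy[1L],
                           mean_time = mean(d$time),
                           censored = sum(d$censored),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  winners <- do.call(rbind, lapply(split(agg, agg[c("rho", "i_percent")], drop = TRUE),
    function(d) {
      best <- d$strategy[d$mean_time == max(d$mean_time)]
      data.frame(rho = d$rho[1L], i_percent = d$i_percent[1L],
                 winner = if (length(best) > 1L) {
                   paste0("tie:", paste(sort(best), collapse = "+"))
                 } else best,
                 stringsAsFactors = FALSE)
    }))
  rownames(winners) <- NULL
  structure(list(cells = agg, winners = winners, replicates = long),
            class = "saturation_table")
}

#' @exportS3Method base::print
print.saturation_table <- function(x, ...) {
  cat(sprintf("<saturation_table> %d cells x %d strategies, %d replicates each\n",
              nrow(x$winners), length(unique(x$cells$strategy)),
              x$cells$n[1L]))
  print(x$cells, ...)
  invisible(x)
}
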