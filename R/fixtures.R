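#' Benchmark configuration
#'
#' Bundles the parameters of the synthetic benchmark protocol: tree sizes,
#' 50 discrete + 50 continuous traits, and a trait matrix matching 90% of
#' the tips in the tree (the defaults).
#'
#' @param tree_sizes Integer vector of tree sizes (each >= 3).
#' @param n_discrete Number of discrete trait columns (states `"A".."E"`).
#' @param n_continuous Number of continuous trait columns (standard normal).
#' @param match_fraction Fraction of tips given a table row, in (0, 1].
#' @param replicates Number of timing replicates (>= 1).
#' @param seed Integer seed for the generator and harness.
#' @return A `"benchmark_config"` list.
#' @export
benchmark_config <- function(tree_sizes = c(10L, 40L, 100L),
                             n_discrete = 50L,
                             n_continuous = 50L,
                             match_fraction = 0.9,
                             replicates = 5L,
                             seed = 1L) {
  if (length(tree_sizes) < 1L || any(tree_sizes < 3)) {
    stop_validation("'tree_sizes' must all be >= 3")
  }
  if (n_discrete < 0 || n_continuous < 0 || n_discrete + n_continuous < 1) {
    stop_validation("need at least one trait column")
  }
  if (match_fraction <= 0 || match_fraction > 1) {
    stop_validation("'match_fraction' must be in (0, 1]")
  }
  if (replicates < 1) stop_validation("'replicates' must be >= 1")
  structure(
    list(
      tree_sizes = as.integer(tree_sizes),
      n_discrete = as.integer(n_discrete),
      n_continuous = as.integer(n_continuous),
      match_fraction = as.numeric(match_fraction),
      replicates = as.integer(replicates),
      seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

#' Generate a random tree and matching trait matrix
#'
#' Emulates the benchmark protocol: a random tree of `n_tips` tips (see
#' [simulate_tree()]) and a character matrix whose rows cover a uniform
#' random subset of `round(match_fraction * n_tips)` tip labels, with
#' `n_discrete` discrete columns (`Disc1..`, states sampled uniformly from
#' `"A".."E"`) and `n_continuous` continuous columns (`Cont1..`, standard
#' normal draws).  Deterministic for a given seed.
#'
#' @param n_tips Number of tips (>= 3 so the matched subset has >= 2 taxa).
#' @param cfg A [benchmark_config()] supplying trait counts and
#'   `match_fraction`.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with elements `tree` (a `"phylo"`) and `data` (a
#'   `data.table` with label column `species` first).
#' @examples
#' fx <- generate_benchmark_data(10, seed = 1)
#' dim(fx$data)  # 9 rows x 101 columns
#' @export
generate_benchmark_data <- function(n_tips, cfg = benchmark_config(),
                                    seed = cfg$seed) {
  if (!inherits(cfg, "benchmark_config")) {
    stop_validation("'cfg' must come from benchmark_config()")
  }
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 3) {
    stop_validation("'n_tips' must be a single integer >= 3")
  }
  n_tips <- as.integer(n_tips)
  m <- as.integer(round(cfg$match_fraction * n_tips))
  if (m < 2L) {
    stop_validation("match_fraction * n_tips rounds below 2 rows")
  }
  with_seed(seed, {
    tree <- ape::rtree(n_tips)
    labs <- sample(tree$tip.label, m)
    dat <- data.table::data.table(species = labs)
    for (k in seq_len(cfg$n_discrete)) {
      dat[, (paste0("Disc", k)) := sample(LETTERS[1:5], m, replace = TRUE)]
    }
    for (k in seq_len(cfg$n_continuous)) {
      dat[, (paste0("Cont", k)) := stats::rnorm(m)]
    }
    data.table::setattr(dat, "label", "species")
    list(tree = tree, data = dat)
  })
}

#' Time coupled operations against a table-only baseline
#'
#' For each tree size in `cfg`, times (over `cfg$replicates` runs) the
#' initial tree/data match, the coupled filter + grouped-aggregation query
#' (`Disc1 == "A"`, sum/mean of two continuous traits by `Disc10`), and the
#' same query on the bare `data.table`.  Reports median and lower/upper
#' quartiles in milliseconds.  Absolute timings are hardware-dependent and
#' for inspection only.
#'
#' @param cfg A [benchmark_config()].
#' @return A data.frame with columns `operation`, `n_tips`, `lq_ms`,
#'   `median_ms`, `uq_ms`.
#' @export
run_benchmark <- function(cfg = benchmark_config()) {
  if (!inherits(cfg, "benchmark_config")) {
    stop_validation("'cfg' must come from benchmark_config()")
  }
  if (cfg$n_discrete < 10L || cfg$n_continuous < 3L) {
    stop_validation("the benchmark query needs Disc1, Disc10, Cont2 and Cont3")
  }
  time_ms <- function(f) {
    vapply(seq_len(cfg$replicates), function(i) {
      t0 <- proc.time()[["elapsed"]]
      f()
      (proc.time()[["elapsed"]] - t0) * 1000
    }, numeric(1L))
  }
  rows <- list()
  for (s in seq_along(cfg$tree_sizes)) {
    n <- cfg$tree_sizes[s]
    fx <- generate_benchmark_data(n, cfg, seed = cfg$seed + s - 1L)
    td <- as_phylotable(fx$tree, fx$data, label_column = "species")
    bare <- data.table::copy(ptb_dat(td))
    timings <- list(
      match = time_ms(function() {
        as_phylotable(fx$tree, fx$data, label_column = "species")
      }),
      coupled_query = time_ms(function() {
        suppressWarnings(
          td[Disc1 == "A", .(sum_c2 = sum(Cont2), mean_c3 = mean(Cont3)),
             by = Disc10]
        )
      }),
      table_query = time_ms(function() {
        bare[Disc1 == "A", .(sum_c2 = sum(Cont2), mean_c3 = mean(Cont3)),
             by = Disc10]
      })
    )
    for (op in names(timings)) {
      q <- stats::quantile(timings[[op]], c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        operation = op, n_tips = n,
        lq_ms = q[1L], median_ms = q[2L], uq_ms = q[3L]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
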