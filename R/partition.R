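#' Enumerate all set partitions of a set of cells
#'
#' Generates every partition of `n` items by restricted-growth-string
#' enumeration: item 1 is always in block 1, and each later item joins an
#' existing block or opens the next one. The count equals the Bell number
#' of `n`. Enumeration is guarded to `n <= 10` (Bell(10) = 115,975).
#'
#' @param n Number of items (condition cells), 1 to 10.
#' @return A list of integer vectors; element `i` of a vector is the block
#'   index (1-based, first-occurrence order) of item `i`.
#' @export
#' @examples
#' length(enumerate_partitions(4))  # Bell(4) = 15
enumerate_partitions <- function(n) {
  stopifnot(n >= 1)
  if (n > 10) stop("partition enumeration is guarded to 10 cells (Bell numbers grow too fast)")
  out <- list()
  rec <- function(prefix, maxblock) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1L)) {
      rec(c(prefix, b), max(maxblock, b))
    }
  }
  rec(integer(0), 0L)
  out
}

#' Score one partition of the condition cells
#'
#' Gaussian likelihood of the standardized subjective indicator with one
#' pooled mean per block and a single shared variance, refit on the
#' underlying observations: `BIC = -2 loglik + (#blocks + 1) log n`. The
#' finest partition reproduces the cell-means family of the network search
#' exactly; coarser partitions trade likelihood for fewer parameters.
#'
#' @param assignment Integer vector mapping each cell to its block.
#' @param values Numeric vector of observations (standardized indicator).
#' @param cells Factor (or vector) of the same length assigning each
#'   observation to a condition cell; its levels must match
#'   `length(assignment)`.
#' @return A list: `assignment`, `block_means`, `sigma2`, `loglik`, `k`,
#'   `bic`.
#' @export
score_partition <- function(assignment, values, cells) {
  cells <- as.factor(cells)
  if (nlevels(cells) != length(assignment)) {
    stop("assignment length must equal the number of cells")
  }
  counts <- tabulate(cells, nbins = nlevels(cells))
  if (any(counts == 0)) stop("every cell must be non-empty")
  n <- length(values)
  blocks <- assignment[as.integer(cells)]
  nb <- max(assignment)
  bn <- tabulate(blocks, nbins = nb)
  bsum <- vapply(seq_len(nb), function(b) sum(values[blocks == b]), numeric(1))
  bmean <- bsum / bn
  sse <- sum(values^2) - sum(bsum^2 / bn)
  if (sse < 1e-10) stop("zero residual variance")
  s2 <- sse / n
  loglik <- -n / 2 * (log(2 * pi * s2) + 1)
  k <- nb + 1L
  list(assignment = assignment, block_means = bmean, sigma2 = s2,
       loglik = loglik, k = k, bic = -2 * loglik + k * log(n))
}

#' BIC-based cluster analysis of condition-cell means
#'
#' Enumerates every set partition of the condition cells, refits the pooled
#' Gaussian means model for each, and ranks partitions by BIC (ascending).
#' The best partition groups experimental conditions that produced an
#' equivalent level of the indicator; differences to the best are graded on
#' the Raftery scale.
#'
#' @param values Numeric observations (standardized subjective indicator,
#'   non-collision trials).
#' @param cells Cell assignment of each observation (factor; levels are the
#'   condition cells, e.g. `"Margin=1.5 m & Order=First"`).
#' @return A `mean_clustering` object: `ranking` (data.frame `partition`,
#'   `n_blocks`, `bic`, `delta_bic`, `grade`), `best` (score list of the
#'   best partition with labelled block means), `cell_means`, `n`.
#' @export
best_partition <- function(values, cells) {
  cells <- as.factor(cells)
  parts <- enumerate_partitions(nlevels(cells))
  scores <- lapply(parts, score_partition, values = values, cells = cells)
  bic <- vapply(scores, `[[`, numeric(1), "bic")
  ord <- order(bic, seq_along(bic))
  lab <- vapply(parts, function(a) {
    paste(vapply(seq_len(max(a)), function(b) {
      paste0("{", paste(levels(cells)[a == b], collapse = ", "), "}")
    }, character(1)), collapse = " ")
  }, character(1))
  ranking <- data.frame(
    partition = lab[ord],
    n_blocks = vapply(parts, max, integer(1))[ord],
    bic = bic[ord],
    stringsAsFactors = FALSE
  )
  ranking$delta_bic <- ranking$bic - ranking$bic[1]
  ranking$grade <- raftery_grade(ranking$delta_bic)
  best <- scores[[ord[1]]]
  names(best$block_means) <- vapply(seq_len(max(best$assignment)), function(b) {
    paste(levels(cells)[best$assignment == b], collapse = " & ")
  }, character(1))
  cm <- tapply(values, cells, mean)
  structure(list(ranking = ranking, best = best,
                 cell_means = cm, n = length(values)),
            class = "mean_clustering")
}

#' @export
print.mean_clustering <- function(x, top = 5, ...) {
  cat(sprintf("Cluster analysis of %d cell means on n = %d observations\n",
              length(x$cell_means), x$n))
  cat(sprintf("Best partition: %d blocks, BIC = %.2f\n",
              max(x$best$assignment), x$best$bic))
  print(round(x$best$block_means, 3))
  invisible(x)
}

#' Cluster the condition cells of the best network
#'
#' Convenience bridge from the network search to the cluster analysis:
#' takes the best structure's subjective parent set, labels each
#' non-collision record by its factor-level cell, and runs
#' [best_partition()] on the standardized subjective indicator.
#'
#' @param search A `network_search` result.
#' @param data The transformed indicator table the search was run on.
#' @return A `mean_clustering` object, or `NULL` when the best network has
#'   no subjective parents (a single cell cannot be partitioned further).
#' @export
cluster_best_network <- function(search, data) {
  if ("is_collision" %in% names(data)) data <- data[!data$is_collision, ]
  cols <- pair_columns(search$pair)
  spar <- search$best$sa_parents
  if (identical(spar, "(none)")) return(NULL)
  fac <- strsplit(spar, ",")[[1]]
  specs <- factor_specs()
  labels <- lapply(fac, function(f) {
    i <- match(f, specs$name)
    paste0(f, "=", ifelse(data[[f]] > 0, specs$level_high[i], specs$level_low[i]))
  })
  cells <- factor(do.call(paste, c(labels, sep = " & ")))
  best_partition(data[[cols["sa"]]], cells)
}
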