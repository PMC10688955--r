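# shared fixtures and independent oracles, built in code at test time

# ground truth with every effect removed: flat cell means, no coupling
null_truth <- function(pair = "dynamics") {
  gt <- default_ground_truth(pair)
  gt$cell_means_std[] <- 0
  gt$sa_scale <- 1
  gt$scr_slope <- 0
  gt
}

null_truth_both <- function() {
  list(dynamics = null_truth("dynamics"), maxima = null_truth("maxima"))
}

# balanced Gaussian cell draws around planted means
sim_cells_acc <- function(means, n_per, seed, sd = 1) {
  riskbn:::with_seed(seed, {
    cells <- factor(rep(seq_along(means), each = n_per))
    data.frame(cells = cells, y = rnorm(length(cells), means[cells], sd))
  })
}

# Bell numbers by the standard binomial recurrence (independent oracle)
bell_numbers <- function(nmax) {
  b <- numeric(nmax + 1)
  b[1] <- 1
  for (n in seq_len(nmax)) {
    b[n + 1] <- sum(choose(n - 1, 0:(n - 1)) * b[1:n])
  }
  b[-1]
}

# non-decomposed BIC oracle: evaluates the joint log-likelihood of a fitted
# structure record by record from the cached family parameters, rather than
# summing the families' own loglik fields
monolithic_bic <- function(structure, data, pair, cache) {
  factors <- factor_specs()$name
  cols <- riskbn:::pair_columns(pair)
  parse_set <- function(s) {
    if (identical(s, "(none)")) integer(0) else match(strsplit(s, ",")[[1]], factors)
  }
  sa_idx <- parse_set(structure$sa_parents)
  scr_idx <- parse_set(structure$scr_parents)
  n <- nrow(data)

  sa_key <- paste0("sa|", riskbn:::subset_key(sa_idx), "|", structure$edge == "scr_to_sa")
  scr_key <- paste0("scr|", riskbn:::subset_key(scr_idx), "|", structure$edge == "sa_to_scr")
  saf <- cache[[sa_key]]; scrf <- cache[[scr_key]]

  cells <- riskbn:::make_cells(data, factors, sa_idx)
  M <- if (is.null(cells)) matrix(1, n, 1) else stats::model.matrix(~ 0 + cells)
  if (structure$edge == "scr_to_sa") M <- cbind(M, data[[cols["scr"]]])
  mu_sa <- drop(M %*% saf$coef)
  ll_sa <- sum(dnorm(data[[cols["sa"]]], mu_sa, sqrt(saf$sigma2), log = TRUE))

  X <- riskbn:::make_dummies(data, factors, scr_idx,
                             if (structure$edge == "sa_to_scr") data[[cols["sa"]]] else NULL)
  mu_scr <- exp(drop(X %*% scrf$fit$coefficients))
  ll_scr <- sum(tw_log_density(data[[cols["scr"]]], mu_scr, scrf$fit$phi, scrf$fit$p))

  ll_factors <- -n * length(factors) * log(2)
  k <- saf$k + scrf$k
  -2 * (ll_sa + ll_scr + ll_factors) + k * log(n)
}
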