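#' Default ground truth for one indicator pair
#'
#' The generative model used by the synthetic-data generator. Subjective
#' indicators are Gaussian on their skewness-corrected (power-transformed)
#' scale, with condition-cell means driven by the factors that the analysis
#' of the experiment retained, and SCR indicators follow a compound
#' Poisson-gamma law whose log-mean is linear in the standardized subjective
#' indicator.
#'
#' Two pairs are modelled. The *dynamics* pair (iSA, nSCR): cell means over
#' Margin x Order with an Order contrast of 0.98 at the 1.5 m margin and
#' 0.72 at 2.5 m on the standardized scale, and a log-link slope of 0.14 of
#' nSCR on standardized iSA. The *maxima* pair (mSA, mSCR): cell means over
#' Margin x Order x Orientation with an Order contrast of 1 when the
#' pedestrian turns its back and 0.23 when facing (both margins, cumulative
#' 1.0 margin effect), and a log-link slope of 0.2 of mSCR on standardized
#' mSA. The two intermediate dynamics cells are planted equal (three distinct
#' levels over four cells); the maxima cells take five distinct levels over
#' eight cells.
#'
#' Cell means are stated on the standardized scale and internally rescaled
#' by `sa_scale = 1/sqrt(1 - var(cell means))` so that after per-participant
#' standardization (which divides by the total within-participant standard
#' deviation) the planted contrasts are recovered at their stated values.
#'
#' @param pair `"dynamics"` for (iSA, nSCR) or `"maxima"` for (mSA, mSCR).
#' @return A `ground_truth` list: `pair`, `sa_parents`, `cell_means_std`
#'   (named by coded parent levels, low level = -1), `sa_scale`, `sa_sd`,
#'   `sa_baseline`, `participant_sd`, `scr_intercept`, `scr_slope`,
#'   `scr_phi`, `scr_p`, `scr_participant_sdlog`.
#' @export
#' @examples
#' gt <- default_ground_truth("dynamics")
#' gt$cell_means_std
default_ground_truth <- function(pair = c("dynamics", "maxima")) {
  pair <- match.arg(pair)
  if (pair == "dynamics") {
    # cells Margin x Order, coded "<Margin>|<Order>" with 1.5 m = -1, First = -1
    cm <- c("-1|-1" = 0.915, "-1|1" = -0.065, "1|-1" = -0.065, "1|1" = -0.785)
    sa_parents <- c("Margin", "Order")
    scr_intercept <- log(2)    # about two skin-conductance responses per trial
    scr_slope <- 0.14
  } else {
    # cells Margin x Order x Orientation, Face = -1, Back = +1
    cm <- c("-1|-1|-1" = 0.8075, "-1|-1|1" = 0.8075,
            "-1|1|-1" = 0.5775, "-1|1|1" = -0.1925,
            "1|-1|-1" = -0.1925, "1|-1|1" = -0.1925,
            "1|1|-1" = -0.4225, "1|1|1" = -1.1925)
    sa_parents <- c("Margin", "Order", "Orientation")
    scr_intercept <- log(0.5)  # typical peak response amplitude ~0.5 microsiemens
    scr_slope <- 0.2
  }
  vc <- mean(cm^2)  # cells are balanced, so this is the cell-mean variance
  structure(list(
    pair = pair,
    sa_parents = sa_parents,
    cell_means_std = cm,
    sa_scale = 1 / sqrt(1 - vc),
    sa_sd = 1,
    sa_baseline = 6,
    participant_sd = 0.5,
    scr_intercept = scr_intercept,
    scr_slope = scr_slope,
    scr_phi = 1,
    scr_p = 1.5,
    scr_participant_sdlog = 0.3
  ), class = "ground_truth")
}

## standardized-scale cell mean for each row of a coded condition table
truth_cell_mean <- function(truth, cond) {
  key <- do.call(paste, c(lapply(truth$sa_parents, function(f) cond[[f]]),
                          sep = "|"))
  unname(truth$cell_means_std[key])
}

#' Simulate a per-trial indicator table
#'
#' Generates the full flat table of one synthetic experiment: for each
#' participant a randomised trial plan, and for each non-collision trial the
#' four raw-scale indicators. Subjective indicators are drawn as Gaussians
#' on the transformed scale (baseline + participant offset + cell mean +
#' noise) and mapped back to the raw scale by the inverse skewness
#' correction (square for iSA, cube for mSA); SCR indicators are compound
#' Poisson-gamma draws whose log-mean is linear in the per-participant
#' standardized subjective indicator (the value the downstream models see),
#' times a participant-specific multiplicative level.
#' Collision trials are flagged and filled with saturated placeholder values;
#' they are excluded from all model fitting.
#'
#' @param design A `design_matrix`, by default the 32-run fraction.
#' @param n_participants Number of participants (>= 2); the experiment used 27.
#' @param truth List with elements `dynamics` and `maxima`, each a
#'   [default_ground_truth()] object.
#' @param seed Master integer seed; sub-streams are derived per participant,
#'   so any participant subset is reproducible independently.
#' @return A data.frame with columns `participant_id`, `rank`,
#'   `is_collision`, the seven coded factor columns, and raw-scale `iSA`,
#'   `mSA`, `nSCR`, `mSCR`.
#' @export
#' @examples
#' tab <- simulate_indicator_table(n_participants = 3, seed = 1)
#' nrow(tab)  # 3 x 36
simulate_indicator_table <- function(design = build_fractional_design(),
                                     n_participants = 27,
                                     truth = list(dynamics = default_ground_truth("dynamics"),
                                                  maxima = default_ground_truth("maxima")),
                                     seed = 1L) {
  stopifnot(n_participants >= 2)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    plan <- make_trial_plan(design, pid, derive_seed(seed, p, 1L))
    nc <- !plan$is_collision
    cond <- plan[nc, colnames(design), drop = FALSE]
    out <- plan[, c("participant_id", "rank", "is_collision", colnames(design))]
    out$iSA <- out$mSA <- out$nSCR <- out$mSCR <- NA_real_
    with_seed(derive_seed(seed, p, 2L), {
      for (ind in c("dynamics", "maxima")) {
        gt <- truth[[ind]]
        off <- rnorm(1, 0, gt$participant_sd)
        scr_level <- exp(rnorm(1, 0, gt$scr_participant_sdlog))
        cm <- truth_cell_mean(gt, cond) * gt$sa_scale
        tval <- gt$sa_baseline + cm + off + rnorm(sum(nc), 0, gt$sa_sd)
        tval <- pmax(tval, 0.01)  # transformed scales are non-negative
        # the SCR law is driven by the standardized subjective indicator,
        # i.e. the per-participant centred/reduced value the models see
        x_std <- (tval - mean(tval)) / sd(tval)
        y <- scr_level *
          rtweedie_cpg(sum(nc), exp(gt$scr_intercept + gt$scr_slope * x_std),
                       gt$scr_phi, gt$scr_p)
        if (ind == "dynamics") {
          out$iSA[nc] <- tval^2
          out$nSCR[nc] <- y
          out$iSA[!nc] <- (gt$sa_baseline + 4)^2
          out$nSCR[!nc] <- scr_level * 4 * exp(gt$scr_intercept)
        } else {
          out$mSA[nc] <- tval^3
          out$mSCR[nc] <- y
          out$mSA[!nc] <- (gt$sa_baseline + 4)^3
          out$mSCR[!nc] <- scr_level * 4 * exp(gt$scr_intercept)
        }
      }
    })
    rows[[p]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate standardized (subjective, SCR) indicator pairs
#'
#' Draws pairs directly at the level the regression model sees: a standard
#' normal subjective indicator and a compound Poisson-gamma SCR indicator
#' with `log mu = scr_intercept + scr_slope * subjective`. Used for
#' coefficient-recovery studies of the Tweedie regression.
#'
#' @param n Number of pairs.
#' @param truth A [default_ground_truth()] object.
#' @param seed Integer seed.
#' @return A data.frame with columns `subjective` and `scr`.
#' @export
simulate_indicator_pairs <- function(n, truth = default_ground_truth("maxima"),
                                     seed = 1L) {
  with_seed(seed, {
    x <- rnorm(n)
    y <- rtweedie_cpg(n, exp(truth$scr_intercept + truth$scr_slope * x),
                      truth$scr_phi, truth$scr_p)
    data.frame(subjective = x, scr = y)
  })
}

#' Trial timing of one crossing situation
#'
#' @param start Time (s) at which the pedestrian begins to cross.
#' @param pass Time (s) at which the pedestrian passes the vehicle.
#' @param total Total trace duration (s); trials are about 20 s apart.
#' @return A list with `start`, `pass`, `end` (pass + 3 s response-latency
#'   allowance) and `total`.
#' @export
trial_timing <- function(start = 4, pass = 12, total = 20) {
  stopifnot(total >= 10, start < pass, pass + 3 <= total)
  list(start = start, pass = pass, end = pass + 3, total = total)
}

#' Simulate a subjective risk-assessment trace
#'
#' Produces the 20 Hz potentiometer series of one trial: a smooth unimodal
#' bump rising from the moment the pedestrian starts to cross, peaking at the
#' closest approach and relaxing back to the low stop, with peak height an
#' increasing (logistic) function of the condition's ground-truth mean. The
#' trace is zero outside the interaction window and bounded in [0, 1].
#'
#' @param condition_mean Standardized-scale cell mean of the condition.
#' @param participant_offset Additive participant offset (same scale).
#' @param timing A [trial_timing()] list.
#' @param noise_sd Trial-to-trial Gaussian jitter of the peak height on the
#'   latent scale; 0 gives the deterministic template.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed (ignored when `noise_sd = 0`).
#' @return A data.frame with columns `t` (seconds) and `value` (0-1).
#' @export
simulate_sa_trace <- function(condition_mean, participant_offset = 0,
                              timing = trial_timing(), noise_sd = 0,
                              rate = 20, seed = 1L) {
  tt <- seq(0, timing$total, by = 1 / rate)
  jitter <- if (noise_sd > 0) with_seed(seed, rnorm(1, 0, noise_sd)) else 0
  h <- stats::plogis(condition_mean + participant_offset + jitter)
  relax_end <- min(timing$pass + 2, timing$total)
  v <- numeric(length(tt))
  up <- tt >= timing$start & tt <= timing$pass
  v[up] <- h * 0.5 * (1 - cos(pi * (tt[up] - timing$start) /
                                (timing$pass - timing$start)))
  down <- tt > timing$pass & tt <= relax_end
  v[down] <- h * 0.5 * (1 + cos(pi * (tt[down] - timing$pass) /
                                  (relax_end - timing$pass)))
  data.frame(t = tt, value = pmin(pmax(v, 0), 1))
}

#' Simulate skin-conductance response events for one trial
#'
#' Event-level counterpart of the indicator-level compound Poisson-gamma
#' law: the number of responses is Poisson with the rate implied by
#' `(mu, phi, p)`, amplitudes are the corresponding i.i.d. gamma marks, and
#' onsets fall uniformly in the trial window (crossing start to 3 s after
#' the pass). Its windowed zero-response fraction therefore equals the
#' Tweedie zero mass.
#'
#' @param mu Tweedie mean of the trial's SCR indicator.
#' @param truth A [default_ground_truth()] object supplying `scr_phi`, `scr_p`.
#' @param timing A [trial_timing()] list.
#' @param seed Integer seed.
#' @return A data.frame of events sorted by onset: `onset` (s), `amplitude`
#'   (microsiemens, > 0); zero rows when no response occurred.
#' @export
simulate_scr_events <- function(mu, truth = default_ground_truth("dynamics"),
                                timing = trial_timing(), seed = 1L) {
  cp <- tw_compound_poisson(mu, truth$scr_phi, truth$scr_p)
  with_seed(seed, {
    n <- rpois(1, cp$lambda)
    if (n == 0) {
      data.frame(onset = numeric(0), amplitude = numeric(0))
    } else {
      data.frame(onset = sort(runif(n, timing$start, timing$end)),
                 amplitude = rgamma(n, shape = cp$shape, scale = cp$scale))
    }
  })
}
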