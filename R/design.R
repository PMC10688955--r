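#' The seven manipulated crossing-situation factors
#'
#' Returns the factor table of the experiment: seven two-level factors
#' describing how a pedestrian crosses in front of the passenger's vehicle.
#' `Side` and `Orientation` fix the pedestrian's initial condition, `vSpeed`,
#' `pSpeed` and `Angle` the relative motion, and `Order` and `Margin` the
#' relative position at close proximity. The first-listed level of each
#' factor is coded -1, the second +1.
#'
#' @return A data.frame with columns `name`, `level_low` (coded -1) and
#'   `level_high` (coded +1).
#' @export
#' @examples
#' factor_specs()
factor_specs <- function() {
  data.frame(
    name = c("Side", "Orientation", "vSpeed", "pSpeed", "Angle",
             "Order", "Margin"),
    level_low = c("Left", "Face", "20 kph", "5.5 kph", "pi/6",
                  "First", "1.5 m"),
    level_high = c("Right", "Back", "30 kph", "7 kph", "pi/3",
                   "Second", "2.5 m"),
    stringsAsFactors = FALSE
  )
}

## parse a defining word such as "ABCD" into base-factor indices
parse_word <- function(word, n_base) {
  idx <- match(strsplit(toupper(word), "")[[1]], LETTERS)
  if (anyNA(idx) || any(idx > n_base) || anyDuplicated(idx)) {
    stop("generator '", word, "' must be a product of distinct base-factor letters")
  }
  idx
}

#' Build a two-level (fractional) factorial design
#'
#' Constructs a `2^(k-p)` regular fraction: the first `k - p` factors form a
#' full factorial and each remaining factor is aliased to a product of base
#' factors given by a defining word. The default generators for the 7-factor
#' case are the minimum-aberration resolution-IV pair `F = ABCD`,
#' `G = ABDE`, which yields 32 runs balanced through third-order
#' interactions. With no generators the full `2^k` factorial is returned.
#'
#' @param factors Factor specification data.frame, as [factor_specs()].
#' @param generators Character vector of defining words, one per aliased
#'   factor (the last `length(generators)` factors). `NULL` gives the full
#'   factorial.
#' @return A `design_matrix`: integer matrix of -1/+1 levels, one column per
#'   factor, with attribute `resolution`.
#' @export
#' @examples
#' d <- build_fractional_design()
#' nrow(d)        # 32 runs
#' check_balance(d, order = 3)
build_fractional_design <- function(factors = factor_specs(),
                                    generators = c("ABCD", "ABDE")) {
  n_fac <- nrow(factors)
  n_gen <- length(generators)
  n_base <- n_fac - n_gen
  if (n_base < 1) stop("more generators than factors")
  base <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n_base))[, n_base:1, drop = FALSE])
  words <- lapply(generators, parse_word, n_base = n_base)
  gen_cols <- vapply(words, function(w) {
    apply(base[, w, drop = FALSE], 1, prod)
  }, numeric(nrow(base)))
  design <- cbind(base, gen_cols)
  colnames(design) <- factors$name
  storage.mode(design) <- "integer"

  if (anyDuplicated(design)) stop("generators yield duplicate runs")
  resolution <- Inf
  if (n_gen > 0) {
    # defining contrast subgroup: all products of the defining words
    # I = (word)(new letter); word length = resolution bound
    full_words <- lapply(seq_len(n_gen), function(i) {
      bits <- rep(FALSE, n_fac)
      bits[words[[i]]] <- TRUE
      bits[n_base + i] <- TRUE
      bits
    })
    lens <- integer(0)
    for (mask in 1:(2^n_gen - 1)) {
      w <- rep(FALSE, n_fac)
      for (i in seq_len(n_gen)) {
        if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) w <- xor(w, full_words[[i]])
      }
      lens <- c(lens, sum(w))
    }
    resolution <- min(lens)
    if (resolution < 4) {
      stop("generators give resolution ", resolution,
           " (< IV): main effects would be aliased with two-factor interactions")
    }
  }
  structure(design, resolution = resolution, class = c("design_matrix", "matrix"))
}

#' Check interaction balance of a two-level design
#'
#' A design is balanced up to a given order when every product of up to
#' `order` distinct factor columns sums to zero over the runs, i.e. each
#' interaction contrast has both signs equally often.
#'
#' @param design A -1/+1 design matrix.
#' @param order Highest interaction order to check (1 to number of factors).
#' @return A data.frame of unbalanced interaction columns (`interaction`,
#'   `order`, `sum`); zero rows when the design is balanced.
#' @export
check_balance <- function(design, order = 3L) {
  stopifnot(order >= 1, order <= ncol(design))
  out <- list()
  for (k in seq_len(order)) {
    combs <- utils::combn(ncol(design), k)
    for (j in seq_len(ncol(combs))) {
      s <- sum(apply(design[, combs[, j], drop = FALSE], 1, prod))
      if (s != 0) {
        out[[length(out) + 1L]] <- data.frame(
          interaction = paste(colnames(design)[combs[, j]], collapse = ":"),
          order = k, sum = s, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    data.frame(interaction = character(0), order = integer(0), sum = integer(0))
  } else {
    do.call(rbind, out)
  }
}

## ranks at which the four deliberate collision trials are inserted
collision_ranks <- function() c(7L, 14L, 21L, 28L)

#' Build one participant's randomised trial plan
#'
#' Shuffles the 32 design runs into a participant-specific order and inserts
#' the four deliberate collision trials at the fixed ranks 7, 14, 21 and 28.
#' Collision trials carry no factorial condition; they are annotated with the
#' collision kinematics (pedestrian at 7.5 kph, vehicle at 30 kph) and
#' flagged for exclusion from all model fitting.
#'
#' @param design A `design_matrix` from [build_fractional_design()].
#' @param participant_id Identifier recorded in the plan.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `trial_plan` data.frame: `participant_id`, `rank`,
#'   `is_collision`, one -1/+1 column per factor (NA on collision rows), and
#'   annotation columns `collision_p_speed`, `collision_v_speed`.
#' @export
make_trial_plan <- function(design, participant_id, seed) {
  n_runs <- nrow(design)
  ranks_coll <- collision_ranks()
  n_tot <- n_runs + length(ranks_coll)
  perm <- with_seed(seed, sample.int(n_runs))
  cond <- matrix(NA_integer_, n_tot, ncol(design),
                 dimnames = list(NULL, colnames(design)))
  cond[-ranks_coll, ] <- design[perm, ]
  plan <- data.frame(
    participant_id = participant_id,
    rank = seq_len(n_tot),
    is_collision = seq_len(n_tot) %in% ranks_coll,
    cond,
    collision_p_speed = ifelse(seq_len(n_tot) %in% ranks_coll, 7.5, NA_real_),
    collision_v_speed = ifelse(seq_len(n_tot) %in% ranks_coll, 30, NA_real_),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("trial_plan", "data.frame")
  plan
}

#' Translate coded levels to the factor labels
#'
#' @param plan A `trial_plan` or coded design matrix/data.frame with -1/+1
#'   factor columns.
#' @param factors Factor specification, as [factor_specs()].
#' @return The same object with factor columns as character labels.
#' @export
design_to_labels <- function(plan, factors = factor_specs()) {
  out <- as.data.frame(plan, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(factors))) {
    nm <- factors$name[i]
    if (nm %in% names(out)) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          ifelse(out[[nm]] > 0, factors$level_high[i],
                                 factors$level_low[i]))
    }
  }
  out
}

#' Translate factor labels back to -1/+1 codes
#' @inheritParams design_to_labels
#' @export
labels_to_design <- function(plan, factors = factor_specs()) {
  out <- as.data.frame(plan, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(factors))) {
    nm <- factors$name[i]
    if (nm %in% names(out) && is.character(out[[nm]])) {
      code <- ifelse(out[[nm]] == factors$level_high[i], 1L,
                     ifelse(out[[nm]] == factors$level_low[i], -1L, NA_integer_))
      if (any(is.na(code) & !is.na(out[[nm]]))) {
        stop("unknown level label in column ", nm)
      }
      out[[nm]] <- code
    }
  }
  out
}
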