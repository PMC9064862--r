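#' Serial-dilution parameters
#'
#' @param od_to_cells_per_ml Conversion factor from OD600 to cells/ml
#'   (default 8e8, the value under which an OD600 of 0.25e-5 corresponds to
#'   2000 cells/ml).
#' @param pool_size Clones per pool (default 2000).
#' @param target_frequency Frequency of the target clone in the pool
#'   (default `1/pool_size`).
#' @param poisson If TRUE, the number of cells per tube is Poisson with the
#'   expected mean; if FALSE (default) it is the rounded expectation, per
#'   the deterministic "approximately N cells" reading.
#' @param false_negative_rate Probability that a tube containing the target
#'   is missed by the PCR screen (default 0: perfect detection).
#' @return A list of class `dilution_params`.
#' @export
dilution_params <- function(od_to_cells_per_ml = 8e8, pool_size = 2000,
                            target_frequency = 1 / pool_size,
                            poisson = FALSE, false_negative_rate = 0) {
  stopifnot(od_to_cells_per_ml > 0, pool_size >= 1,
            target_frequency > 0, target_frequency <= 1,
            false_negative_rate >= 0, false_negative_rate < 1)
  structure(list(od_to_cells_per_ml = od_to_cells_per_ml,
                 pool_size = as.integer(pool_size),
                 target_frequency = target_frequency,
                 poisson = isTRUE(poisson),
                 false_negative_rate = false_negative_rate),
            class = "dilution_params")
}

#' Convert an OD600 reading to a cell density
#'
#' @param od600 Optical density at 600 nm (>= 0).
#' @param params A [dilution_params()] object.
#' @return Cells per ml (`od600 * od_to_cells_per_ml`).
#' @export
od_to_cell_density <- function(od600, params = dilution_params()) {
  if (any(od600 < 0)) stop("od600 must be >= 0", call. = FALSE)
  od600 * params$od_to_cells_per_ml
}

#' Plan one serial-dilution round
#'
#' With `c = cells_per_ml * volume_ml` expected cells per tube and target
#' frequency `f`, a tube is positive with probability `1 - (1 - f)^round(c)`
#' (exact binomial-sampling model) and the round succeeds — at least one
#' positive tube — with probability `1 - (1 - p_tube)^n_tubes`.
#'
#' @param cells_per_ml Cell density of the diluted pool.
#' @param volume_ml Inoculum volume per tube in ml.
#' @param n_tubes Number of tubes in the round (the protocol uses 16-32).
#' @param params A [dilution_params()] object.
#' @return A list of class `round_plan` with `cells_per_ml`,
#'   `inoculum_volume_ml`, `n_tubes`, `expected_cells_per_tube`,
#'   `p_tube_positive`, `p_round_success`.
#' @export
plan_round <- function(cells_per_ml, volume_ml, n_tubes = 16,
                       params = dilution_params()) {
  stopifnot(cells_per_ml > 0, volume_ml > 0)
  if (n_tubes < 1) stop("n_tubes must be >= 1", call. = FALSE)
  c_exp <- cells_per_ml * volume_ml
  f <- params$target_frequency
  p_tube <- 1 - (1 - f)^round(c_exp)
  p_round <- 1 - (1 - p_tube)^n_tubes
  structure(list(cells_per_ml = cells_per_ml, inoculum_volume_ml = volume_ml,
                 n_tubes = as.integer(n_tubes),
                 expected_cells_per_tube = c_exp,
                 p_tube_positive = p_tube, p_round_success = p_round),
            class = "round_plan")
}

#' @export
print.round_plan <- function(x, ...) {
  cat(sprintf(
    "Dilution round: %.4g cells/ml x %.3g ml = %.4g cells/tube over %d tubes\n",
    x$cells_per_ml, x$inoculum_volume_ml, x$expected_cells_per_tube, x$n_tubes))
  cat(sprintf("  P(tube positive) = %.4f; P(round succeeds) = %.4f\n",
              x$p_tube_positive, x$p_round_success))
  invisible(x)
}

#' Build the standard two-round dilution plan
#'
#' Round 1: 2000 cells/ml, 100 ul per tube (~200 cells); round 2: 200
#' cells/ml, 200 ul per tube (~40 cells); then plating at a 1e-7 dilution.
#'
#' @param n_tubes Tubes per round (single value or length-2 vector).
#' @param params A [dilution_params()] object.
#' @return A list of two [plan_round()] objects.
#' @export
standard_dilution_plan <- function(n_tubes = 16, params = dilution_params()) {
  n_tubes <- rep(n_tubes, length.out = 2)
  list(plan_round(od_to_cell_density(0.25e-5, params), 0.1, n_tubes[1], params),
       plan_round(od_to_cell_density(0.25e-6, params), 0.2, n_tubes[2], params))
}

#' Simulate serial-dilution recovery of a single clone
#'
#' Stochastic twin of the dilution arithmetic: each round distributes
#' target and background cells into tubes (binomial per tube at the current
#' target frequency), carries the composition of one positive tube forward,
#' and finally plates single colonies. Reproducible given a seed.
#'
#' @param plans A list of [plan_round()] objects, in order.
#' @param params A [dilution_params()] object.
#' @param seed Integer seed.
#' @param n_colonies Colonies screened after plating (default 16).
#' @return A list of class `recovery_outcome`: `rounds_executed`,
#'   `isolated`, `trajectory` (per-round positive-tube counts),
#'   `final_frequency`, `seed`.
#' @export
simulate_recovery <- function(plans, params = dilution_params(), seed = 1L,
                              n_colonies = 16) {
  set.seed(seed)
  f <- params$target_frequency
  trajectory <- integer(length(plans))
  freqs <- numeric(length(plans))
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    n_cells <- if (params$poisson) {
      stats::rpois(p$n_tubes, p$expected_cells_per_tube)
    } else {
      rep(round(p$expected_cells_per_tube), p$n_tubes)
    }
    targets <- stats::rbinom(p$n_tubes, n_cells, f)
    detected <- targets > 0
    if (params$false_negative_rate > 0) {
      detected <- detected &
        stats::runif(p$n_tubes) >= params$false_negative_rate
    }
    trajectory[i] <- sum(detected)
    if (!any(detected)) {
      return(structure(list(rounds_executed = i, isolated = FALSE,
                            trajectory = trajectory[seq_len(i)],
                            final_frequency = f, seed = seed),
                       class = "recovery_outcome"))
    }
    # carry the most enriched detected tube forward
    pick <- which(detected)[which.max(targets[detected])]
    f <- targets[pick] / max(1L, n_cells[pick])
    freqs[i] <- f
  }
  hit <- stats::rbinom(1, n_colonies, f) > 0
  structure(list(rounds_executed = length(plans), isolated = hit,
                 trajectory = trajectory, final_frequency = f, seed = seed),
            class = "recovery_outcome")
}

#' @export
print.recovery_outcome <- function(x, ...) {
  cat(sprintf(
    "Serial-dilution recovery: %d round(s), positive tubes %s, target frequency %.4g -> %s\n",
    x$rounds_executed, paste(x$trajectory, collapse = "/"),
    x$final_frequency, if (x$isolated) "clone isolated" else "not isolated"))
  invisible(x)
}
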