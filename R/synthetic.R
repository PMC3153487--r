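#' Scenario for a synthetic well-growth plate assay
#'
#' Describes the layout of a plate-growth experiment: a set of conditions
#' (rows of `conditions`, each with a condition label and a per-well
#' growth probability) and the number of wells per condition (default 24,
#' the usual one-plate count for each combination). The growth
#' probability can be supplied directly or derived from a simulation via
#' [growth_probability()].
#'
#' @param conditions a data frame with a `condition` column (labels) and
#'   a `p_growth` column (probabilities in `[0, 1]`); any further columns
#'   (inoculum size, arrangement, sucrose_mM, ...) are carried through.
#' @param n_wells wells per condition.
#' @param seed integer seed making the generated table reproducible.
#' @return an object of class `plate_scenario`.
#' @export
plate_scenario <- function(conditions, n_wells = 24, seed = 1) {
  if (!is.data.frame(conditions) ||
      !all(c("condition", "p_growth") %in% names(conditions)))
    stop("conditions must be a data frame with 'condition' and 'p_growth'",
         call. = FALSE)
  if (any(!is.finite(conditions$p_growth)) ||
      any(conditions$p_growth < 0) || any(conditions$p_growth > 1))
    stop("p_growth must lie in [0, 1]", call. = FALSE)
  if (any(!nzchar(as.character(conditions$condition))))
    stop("condition labels must be non-empty", call. = FALSE)
  if (n_wells < 1) stop("n_wells must be >= 1", call. = FALSE)
  structure(list(conditions = conditions, n_wells = n_wells,
                 seed = as.integer(seed)),
            class = "plate_scenario")
}

#' Generate a synthetic well-growth table
#'
#' Draws independent Bernoulli growth outcomes for every well of every
#' condition of a [plate_scenario()]. Deterministic for a fixed scenario
#' seed.
#'
#' @param scenario a [plate_scenario()].
#' @return a data frame of per-well records (`condition`, carried-through
#'   condition columns, `well`, `grew`), suitable for
#'   [growth_fraction_summary()].
#' @export
gen_plate <- function(scenario) {
  stopifnot(inherits(scenario, "plate_scenario"))
  with_seed(scenario$seed, {
    rows <- lapply(seq_len(nrow(scenario$conditions)), function(i) {
      cond <- scenario$conditions[i, , drop = FALSE]
      grew <- runif(scenario$n_wells) < cond$p_growth
      cbind(cond[rep(1, scenario$n_wells),
                 setdiff(names(cond), "p_growth"), drop = FALSE],
            data.frame(well = seq_len(scenario$n_wells), grew = grew))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Map simulated intake to a well-growth probability
#'
#' Links the simulator's deterministic intake to a stochastic well
#' outcome with a logistic curve in log-intake centered on the growth
#' threshold: `plogis(steepness * log(intake / min_growth_intake))`.
#' The default steepness makes the outcome nearly deterministic away
#' from the threshold while allowing partial growth fractions near it,
#' as observed at marginal sugar concentrations.
#'
#' @param intake glucose intake (molecules/s), e.g. from
#'   [run_simulation()].
#' @param params a [kinetic_params()] object (supplies the threshold).
#' @param steepness logistic steepness on the log-intake scale.
#' @return probability of visible growth in a well.
#' @export
growth_probability <- function(intake, params = kinetic_params(),
                               steepness = 25) {
  check_nonneg(intake, "intake")
  plogis(steepness * log(pmax(intake, .Machine$double.xmin) /
                           params$min_growth_intake))
}

#' Scenario for a synthetic two-genotype competition
#'
#' Producer (invertase-expressing) and non-producer cells are inoculated
#' in equal numbers and grow exponentially for `duration_h` hours; the
#' producer pays a relative growth-rate cost (default 0.35%, the measured
#' cost of forced invertase expression). Each well is then profiled by
#' counting up to `sampling_depth` cells, with binomial sampling of the
#' two genotypes at their final frequencies. Half the wells are labelled
#' with each color assignment (dye swap).
#'
#' @param n_wells number of wells (default 24 per color set).
#' @param inoculum starting cells of each genotype (default 60).
#' @param growth_rate non-producer growth rate (per hour).
#' @param cost relative growth-rate cost of producing invertase.
#' @param duration_h competition time (hours, default 72).
#' @param sampling_depth maximum cells counted per well (default 1e5).
#' @param seed integer seed.
#' @return an object of class `competition_scenario`.
#' @export
competition_scenario <- function(n_wells = 24, inoculum = 60,
                                 growth_rate = 0.35, cost = 0.0035,
                                 duration_h = 72, sampling_depth = 1e5,
                                 seed = 1) {
  if (cost < 0 || cost >= 1) stop("cost must lie in [0, 1)", call. = FALSE)
  if (inoculum <= 0) stop("inoculum must be positive", call. = FALSE)
  if (n_wells < 2) stop("n_wells must be >= 2", call. = FALSE)
  if (growth_rate <= 0 || duration_h < 0 || sampling_depth < 1)
    stop("growth_rate, duration_h and sampling_depth must be positive",
         call. = FALSE)
  structure(list(n_wells = as.integer(n_wells), inoculum = inoculum,
                 growth_rate = growth_rate, cost = cost,
                 duration_h = duration_h, sampling_depth = sampling_depth,
                 seed = as.integer(seed)),
            class = "competition_scenario")
}

#' Expected competition log-ratio of a scenario
#'
#' Under deterministic exponential growth with equal inocula, the
#' expected statistic is `(r_p - r_n) * t = -cost * growth_rate *
#' duration_h`.
#'
#' @param scenario a [competition_scenario()].
#' @return the expected value of the per-well log-ratio.
#' @export
competition_expected_log_ratio <- function(scenario) {
  stopifnot(inherits(scenario, "competition_scenario"))
  -scenario$cost * scenario$growth_rate * scenario$duration_h
}

#' Generate synthetic competition counts
#'
#' Grows both genotypes deterministically, then subsamples each well at
#' the scenario's sampling depth: the producer count is a binomial draw
#' of `depth` cells at the final producer frequency, and the non-producer
#' count is the remainder. Deterministic under a fixed scenario seed.
#'
#' @param scenario a [competition_scenario()].
#' @return a data frame with one row per well: `well`,
#'   `color_assignment` (`"producer-citrine"` or `"producer-cherry"`),
#'   `producer_count`, `nonproducer_count`; suitable for
#'   [competition_advantage()].
#' @export
gen_competition <- function(scenario) {
  stopifnot(inherits(scenario, "competition_scenario"))
  r_n <- scenario$growth_rate
  r_p <- r_n * (1 - scenario$cost)
  n_p <- scenario$inoculum * exp(r_p * scenario$duration_h)
  n_n <- scenario$inoculum * exp(r_n * scenario$duration_h)
  freq_p <- n_p / (n_p + n_n)
  census <- scenario$sampling_depth >= n_p + n_n
  depth <- round(min(scenario$sampling_depth, n_p + n_n))
  with_seed(scenario$seed, {
    # counting the whole well is a census with no subsampling noise
    x <- if (census) rep(round(n_p), scenario$n_wells)
         else rbinom(scenario$n_wells, size = depth, prob = freq_p)
    data.frame(well = seq_len(scenario$n_wells),
               color_assignment = rep(c("producer-citrine",
                                        "producer-cherry"),
                                      length.out = scenario$n_wells),
               producer_count = x, nonproducer_count = depth - x)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
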