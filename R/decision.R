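#' @name decision_model
#' @title Belief initialization, appraisal and the evacuation decision rule
#'
#' @description
#' Each agent carries five belief constructs on \[0, 1\]: perceived severity
#' and susceptibility (jointly, perceived threat), self-efficacy and response
#' efficacy (jointly, perceived efficacy), and subjective norm. Beliefs are
#' initialized from the agent's demographic and geospatial profile with
#' seeded Beta-distributed individual noise, shifted deterministically by a
#' message's construct profile, and fed into an appraisal gate plus a
#' logistic propensity rule with threshold-based action selection. The
#' decision step itself is deterministic: population-level variability comes
#' entirely from agent heterogeneity, never from choice noise.
NULL

BELIEF_NAMES <- c("severity", "susceptibility", "self_efficacy",
                  "response_efficacy", "subjective_norm")

#' Default belief-initialization settings
#'
#' Baselines and deterministic shifts mapping agent attributes to expected
#' belief levels, plus the Beta noise concentration. Flood-zone residence
#' raises susceptibility; prior hurricane experience raises severity; higher
#' income and education bands raise self-efficacy (linearly in band rank);
#' shelter distance lowers response efficacy. With noise enabled each
#' component is drawn from a Beta distribution whose mean is the shifted
#' baseline and whose concentration is `noise_kappa` (larger = tighter).
#'
#' @return A list of initialization settings.
#' @export
default_belief_init <- function() {
  list(
    baselines = c(severity = 0.35, susceptibility = 0.30,
                  self_efficacy = 0.30, response_efficacy = 0.55,
                  subjective_norm = 0.30),
    prior_hurricane_severity_shift = 0.10,
    flood_zone_susceptibility_shift = 0.15,
    income_self_efficacy_shift = 0.15,     # full shift at the top band
    education_self_efficacy_shift = 0.10,  # full shift at the top band
    distance_response_efficacy_slope = 0.01,  # per km of shelter distance
    noise = TRUE,
    noise_kappa = 16
  )
}

#' Default constraint weights
#'
#' Weight of each contextual constraint flag in the constraint score
#' C = min(1, sum of active weights). Mobility limitation and lack of a
#' vehicle are the strongest barriers to leaving; pets the weakest.
#'
#' @return Named numeric vector of weights in \[0, 1\].
#' @export
default_constraint_weights <- function() {
  c(mobility_limited = 0.30, no_vehicle = 0.25, financial_barrier = 0.20,
    pets = 0.10, caregiving = 0.15)
}

#' Expected (noise-free) belief levels for agents
#'
#' The deterministic part of belief initialization: baselines plus
#' attribute-driven shifts, clipped to \[0, 1\]. These are the Beta means
#' used when noise is enabled and the exact values when it is disabled.
#'
#' @param agents Agent data frame from [generate_population()].
#' @param init Initialization settings, see [default_belief_init()].
#' @return Numeric matrix, one row per agent, columns
#'   `severity, susceptibility, self_efficacy, response_efficacy,
#'   subjective_norm`.
#' @export
belief_expectations <- function(agents, init = default_belief_init()) {
  n <- nrow(agents)
  mu <- matrix(rep(init$baselines[BELIEF_NAMES], each = n), nrow = n,
               dimnames = list(NULL, BELIEF_NAMES))
  if (n == 0) return(mu)
  mu[, "severity"] <- mu[, "severity"] +
    init$prior_hurricane_severity_shift * agents$prior_hurricane_experience
  mu[, "susceptibility"] <- mu[, "susceptibility"] +
    init$flood_zone_susceptibility_shift * agents$in_flood_zone
  mu[, "self_efficacy"] <- mu[, "self_efficacy"] +
    init$income_self_efficacy_shift * band_rank(agents$income_band) +
    init$education_self_efficacy_shift * band_rank(agents$education_level)
  mu[, "response_efficacy"] <- mu[, "response_efficacy"] -
    init$distance_response_efficacy_slope * agents$shelter_distance_km
  clip01(mu)
}

# Rank of an ordered band label scaled to [0, 1] (0 = lowest band).
band_rank <- function(x) {
  orders <- list(
    income = c("under_25k", "25k_50k", "50k_75k", "75k_125k", "over_125k"),
    education = c("less_than_hs", "high_school", "some_college", "bachelor",
                  "graduate")
  )
  for (ord in orders) {
    if (all(x %in% ord)) {
      return((match(x, ord) - 1) / (length(ord) - 1))
    }
  }
  # unknown band sets: fall back to alphabetical rank within observed labels
  lev <- sort(unique(x))
  if (length(lev) == 1) return(rep(0, length(x)))
  (match(x, lev) - 1) / (length(lev) - 1)
}

#' Initialize agent beliefs
#'
#' Draws each agent's five belief components. The expected level of each
#' component is [belief_expectations()]; with `init$noise = TRUE` the actual
#' value is Beta-distributed around that expectation with concentration
#' `init$noise_kappa`, giving seeded individual heterogeneity. With noise
#' disabled the expectations are returned exactly.
#'
#' @inheritParams belief_expectations
#' @param seed Optional integer; when supplied, [set.seed()] is called first
#'   so the draw is reproducible in isolation. When `NULL` the current RNG
#'   stream is used (as inside the simulation engine, which seeds per
#'   replication).
#' @return Numeric matrix of beliefs in \[0, 1\], one row per agent.
#' @export
initialize_beliefs <- function(agents, init = default_belief_init(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- belief_expectations(agents, init)
  if (!isTRUE(init$noise) || nrow(mu) == 0) return(mu)
  kappa <- init$noise_kappa
  eps <- 1e-6
  out <- mu
  for (j in seq_len(ncol(mu))) {
    m <- pmin(1 - eps, pmax(eps, mu[, j]))
    out[, j] <- stats::rbeta(nrow(mu), m * kappa, (1 - m) * kappa)
  }
  clip01(out)
}

#' Apply a message's construct profile to beliefs
#'
#' Pure, deterministic belief update: the threat delta raises severity and
#' susceptibility, the efficacy delta raises self-efficacy and response
#' efficacy, the norm delta raises subjective norm; all components are
#' clipped to \[0, 1\]. The input is not modified.
#'
#' @param beliefs Belief matrix (or single named vector) as produced by
#'   [initialize_beliefs()].
#' @param profile Construct profile from [profile_for()] or a catalog row.
#' @return Updated belief matrix (or vector) of the same shape.
#' @export
apply_message <- function(beliefs, profile) {
  if (is.data.frame(profile)) {
    profile <- c(delta_threat = profile$delta_threat[1],
                 delta_efficacy = profile$delta_efficacy[1],
                 delta_norm = profile$delta_norm[1])
  }
  vec <- is.null(dim(beliefs))
  b <- if (vec) matrix(beliefs, nrow = 1, dimnames = list(NULL, names(beliefs)))
       else beliefs
  b[, "severity"] <- b[, "severity"] + profile[["delta_threat"]]
  b[, "susceptibility"] <- b[, "susceptibility"] + profile[["delta_threat"]]
  b[, "self_efficacy"] <- b[, "self_efficacy"] + profile[["delta_efficacy"]]
  b[, "response_efficacy"] <- b[, "response_efficacy"] + profile[["delta_efficacy"]]
  b[, "subjective_norm"] <- b[, "subjective_norm"] + profile[["delta_norm"]]
  b <- clip01(b)
  if (vec) b[1, ] else b
}

#' Aggregate beliefs into the three decision constructs
#'
#' Perceived threat T is the mean of severity and susceptibility, perceived
#' efficacy E the mean of self-efficacy and response efficacy, and perceived
#' subjective norm N the subjective-norm component itself. Alternative
#' compositions (`"min"`, `"product"`) are offered for sensitivity analysis.
#'
#' @inheritParams apply_message
#' @param method Composition of the two parent components: `"mean"`
#'   (default), `"min"` or `"product"`.
#' @return A list with numeric vectors `threat`, `efficacy`, `norm`.
#' @export
aggregate_constructs <- function(beliefs, method = c("mean", "min", "product")) {
  method <- match.arg(method)
  vec <- is.null(dim(beliefs))
  b <- if (vec) matrix(beliefs, nrow = 1, dimnames = list(NULL, names(beliefs)))
       else beliefs
  comb <- switch(method,
    mean = function(x, y) (x + y) / 2,
    min = pmin,
    product = function(x, y) x * y)
  list(threat = unname(comb(b[, "severity"], b[, "susceptibility"])),
       efficacy = unname(comb(b[, "self_efficacy"], b[, "response_efficacy"])),
       norm = unname(b[, "subjective_norm"]))
}

#' Constraint score
#'
#' C = min(1, sum of the active constraint flags' weights).
#'
#' @param agents Agent data frame carrying the logical constraint columns.
#' @param weights Named constraint weights, see
#'   [default_constraint_weights()].
#' @return Numeric vector of constraint scores in \[0, 1\].
#' @export
constraint_score <- function(agents, weights = default_constraint_weights()) {
  stopifnot(all(weights >= 0 & weights <= 1))
  if (nrow(agents) == 0) return(numeric(0))
  s <- rep(0, nrow(agents))
  for (f in names(weights)) {
    if (!is.null(agents[[f]])) s <- s + weights[[f]] * agents[[f]]
  }
  pmin(1, s)
}

#' Decision weights and thresholds
#'
#' Constructor for the parameter set of the evacuation decision rule:
#' propensity weights `alpha` (threat), `beta` (efficacy), `gamma`
#' (subjective norm) and `delta` (constraints), the logistic `intercept` and
#' `logistic_scale`, the action threshold `tau`, and the appraisal-gate
#' thresholds `theta_threat` / `theta_efficacy` (plus the optional
#' no-response floor `theta_threat_low`, unused at its default of 0).
#'
#' @param alpha,beta,gamma,delta Nonnegative propensity weights.
#' @param tau Action threshold in (0, 1): evacuate when propensity >= tau.
#' @param intercept Logistic intercept subtracted from the weighted sum.
#' @param logistic_scale Positive slope multiplier of the logistic.
#' @param theta_threat,theta_efficacy Appraisal thresholds in (0, 1).
#' @param theta_threat_low Threat floor below which the appraisal returns
#'   `no_response`; 0 disables the branch.
#' @return A `decision_weights` list.
#' @export
decision_weights <- function(alpha, beta, gamma, delta, tau = 0.5,
                             intercept = 0, logistic_scale = 1,
                             theta_threat = 0.6, theta_efficacy = 0.4,
                             theta_threat_low = 0) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            tau = tau, intercept = intercept,
            logistic_scale = logistic_scale, theta_threat = theta_threat,
            theta_efficacy = theta_efficacy,
            theta_threat_low = theta_threat_low)
  validate_weights(w)
  structure(w, class = c("decision_weights", "list"))
}

validate_weights <- function(w) {
  for (k in c("alpha", "beta", "gamma", "delta")) {
    if (is.null(w[[k]]) || w[[k]] < 0) {
      stop(sprintf("weight '%s' must be nonnegative", k), call. = FALSE)
    }
  }
  if (w$tau <= 0 || w$tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  if (w$logistic_scale <= 0) stop("logistic_scale must be positive", call. = FALSE)
  for (k in c("theta_threat", "theta_efficacy")) {
    if (w[[k]] <= 0 || w[[k]] >= 1) {
      stop(sprintf("'%s' must lie in (0, 1)", k), call. = FALSE)
    }
  }
  invisible(w)
}

#' EPPM appraisal gate
#'
#' Classifies each (threat, efficacy) pair into an appraisal branch:
#' `fear_control` when perceived threat is high (>= `theta_threat`) but
#' perceived efficacy is low (< `theta_efficacy`) — the maladaptive branch
#' where agents deny or avoid rather than act; `no_response` when threat is
#' below the optional floor `theta_threat_low` (disabled by default); and
#' `danger_control` otherwise, the adaptive branch in which the propensity
#' rule decides.
#'
#' @param threat,efficacy Numeric vectors in \[0, 1\].
#' @param weights A [decision_weights()] object.
#' @return Character vector of branches.
#' @export
appraise <- function(threat, efficacy, weights = default_weights()) {
  stopifnot(length(threat) == length(efficacy))
  branch <- rep("danger_control", length(threat))
  branch[threat >= weights$theta_threat &
           efficacy < weights$theta_efficacy] <- "fear_control"
  branch[threat < weights$theta_threat_low] <- "no_response"
  branch
}

#' Evacuation propensity
#'
#' The logistic decision rule
#' P(evacuate) = sigma(scale * (alpha*T + beta*E + gamma*N - delta*C - intercept)),
#' strictly increasing in threat, efficacy and norm and strictly decreasing
#' in the constraint score.
#'
#' @param threat,efficacy,norm,constraint Numeric vectors in \[0, 1\].
#' @param weights A [decision_weights()] object.
#' @return Propensities in (0, 1).
#' @export
evacuation_propensity <- function(threat, efficacy, norm, constraint,
                                  weights = default_weights()) {
  lin <- weights$alpha * threat + weights$beta * efficacy +
    weights$gamma * norm - weights$delta * constraint - weights$intercept
  stats::plogis(weights$logistic_scale * lin)
}

#' Threshold-based evacuation decision
#'
#' Deterministic action selection: agents in the `fear_control` or
#' `no_response` appraisal branch stay; agents in `danger_control` evacuate
#' exactly when their propensity reaches the threshold `tau` (ties resolve
#' toward evacuating). No randomness enters this step.
#'
#' @inheritParams apply_message
#' @param constraint Constraint scores from [constraint_score()].
#' @param weights A [decision_weights()] object.
#' @param construct_method Passed to [aggregate_constructs()].
#' @return Character vector, `"evacuate"` or `"stay"`, one per agent.
#' @export
decide <- function(beliefs, constraint, weights = default_weights(),
                   construct_method = "mean") {
  g <- aggregate_constructs(beliefs, method = construct_method)
  branch <- appraise(g$threat, g$efficacy, weights)
  p <- evacuation_propensity(g$threat, g$efficacy, g$norm, constraint, weights)
  ifelse(branch == "danger_control" & p >= weights$tau, "evacuate", "stay")
}
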