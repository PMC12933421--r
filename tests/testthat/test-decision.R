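no_noise_init <- function(zero_shifts = FALSE) {
  init <- default_belief_init()
  init$noise <- FALSE
  if (zero_shifts) {
    init$prior_hurricane_severity_shift <- 0
    init$flood_zone_susceptibility_shift <- 0
    init$income_self_efficacy_shift <- 0
    init$education_self_efficacy_shift <- 0
    init$distance_response_efficacy_slope <- 0
  }
  init
}

test_that("belief initialization reflects geospatial and demographic context", {
  init <- no_noise_init()
  hi <- initialize_beliefs(one_agent(in_flood = TRUE), init)
  lo <- initialize_beliefs(one_agent(in_flood = FALSE), init)
  expect_gt(hi[, "susceptibility"], lo[, "susceptibility"])
  expect_equal(hi[, "severity"], lo[, "severity"])
  exp_sev <- initialize_beliefs(one_agent(prior = TRUE), init)[, "severity"]
  expect_gt(exp_sev, initialize_beliefs(one_agent(), init)[, "severity"])
  rich <- one_agent(income = "over_125k", edu = "graduate")
  expect_gt(initialize_beliefs(rich, init)[, "self_efficacy"],
            initialize_beliefs(one_agent(), init)[, "self_efficacy"])
  near <- one_agent(dist = 2); far <- one_agent(dist = 30)
  expect_gt(initialize_beliefs(near, init)[, "response_efficacy"],
            initialize_beliefs(far, init)[, "response_efficacy"])
})

test_that("identity configuration returns the configured baselines exactly", {
  init <- no_noise_init(zero_shifts = TRUE)
  b <- initialize_beliefs(one_agent(in_flood = TRUE, prior = TRUE), init)
  expect_equal(b[1, ], init$baselines[colnames(b)])
})

test_that("Beta noise is centered on the configured expectations", {
  pop <- generate_population(default_population_config(n_agents = 5000,
                                                       seed = 21))
  mu <- belief_expectations(pop)
  b <- initialize_beliefs(pop, seed = 22)
  expect_true(all(b >= 0 & b <= 1))
  expect_lt(max(abs(colMeans(b) - colMeans(mu))), 0.02)
  # reproducible in isolation via the seed argument
  expect_identical(b, initialize_beliefs(pop, seed = 22))
})

test_that("message application shifts exactly the named constructs and clips", {
  b <- belief_matrix(c(0.2, 0.9), c(0.4, 0.4), c(0.1, 0.1))
  expect_identical(apply_message(b, profile_for("control")), b)
  fear <- apply_message(b, profile_for("fear"))
  expect_equal(fear[, "severity"], c(0.55, 1.0))  # second row clipped at 1
  expect_identical(fear[, c("self_efficacy", "response_efficacy",
                            "subjective_norm")],
                   b[, c("self_efficacy", "response_efficacy",
                         "subjective_norm")])
  # single named-vector state round-trips
  v <- b[1, ]
  out <- apply_message(v, profile_for("norm"))
  expect_equal(out[["subjective_norm"]], 0.35)
  expect_equal(v, b[1, ])  # input untouched
})

test_that("belief components stay in [0,1] under arbitrary message sequences", {
  set.seed(31)
  b <- matrix(stats::runif(50 * 5), 50,
              dimnames = list(NULL, c("severity", "susceptibility",
                                      "self_efficacy", "response_efficacy",
                                      "subjective_norm")))
  for (i in 1:40) {
    cc <- sample(message_categories(), 1)
    b <- apply_message(b, profile_for(cc))
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("construct aggregation is the mean of the parent components", {
  z <- belief_matrix(0, 0, 0)
  expect_equal(unlist(aggregate_constructs(z)), c(threat = 0, efficacy = 0,
                                                  norm = 0))
  b <- cbind(severity = 1, susceptibility = 0, self_efficacy = 0.5,
             response_efficacy = 0.5, subjective_norm = 0.3)
  g <- aggregate_constructs(b)
  expect_equal(c(g$threat, g$efficacy, g$norm), c(0.5, 0.5, 0.3))
  # each aggregate bounded by its parents, all compositions
  set.seed(17)
  r <- matrix(stats::runif(1000 * 5), 1000,
              dimnames = list(NULL, colnames(b)))
  for (m in c("mean", "min", "product")) {
    g <- aggregate_constructs(r, method = m)
    expect_true(all(g$threat <= pmax(r[, 1], r[, 2]) + 1e-12 &
                      g$threat >= pmin(r[, 1], r[, 2]) * ifelse(m == "product", 0, 1)))
    expect_true(all(g$efficacy <= pmax(r[, 3], r[, 4]) + 1e-12))
    expect_identical(g$norm, r[, "subjective_norm"])
  }
})

test_that("appraisal gate separates danger control from fear control", {
  w <- default_weights()
  expect_equal(appraise(0.9, 0.1, w), "fear_control")
  expect_equal(appraise(0.9, 0.9, w), "danger_control")
  expect_equal(appraise(0, 0, w), "danger_control")
  # near-zero propensity downstream of the low-threat danger-control branch
  expect_lt(evacuation_propensity(0, 0, 0, 0, w), w$tau)
  # the optional no-response floor activates when configured
  w2 <- decision_weights(1, 1, 1, 1, theta_threat_low = 0.2)
  expect_equal(appraise(c(0.1, 0.5), c(0.9, 0.9), w2),
               c("no_response", "danger_control"))
})

test_that("the logistic propensity matches its closed form and monotonicity", {
  w0 <- decision_weights(alpha = 2, beta = 2, gamma = 2, delta = 1,
                         intercept = 0)
  expect_equal(evacuation_propensity(0, 0, 0, 0, w0), 0.5)
  expect_equal(evacuation_propensity(1, 1, 1, 0, w0), 1 / (1 + exp(-6)),
               tolerance = 1e-12)
  p <- evacuation_propensity(0.5, 0.5, 0.5, seq(0, 1, 0.1), w0)
  expect_true(all(diff(p) < 0))
  for (arg in 1:3) {
    vals <- lapply(list(0.5, 0.5, 0.5), rep, 11)
    vals[[arg]] <- seq(0, 1, 0.1)
    p <- evacuation_propensity(vals[[1]], vals[[2]], vals[[3]], 0.2, w0)
    expect_true(all(diff(p) > 0))
  }
})

test_that("decide matches an exhaustive brute-force oracle over the grid", {
  w <- default_weights()
  grid <- expand.grid(t = seq(0, 1, 0.05), e = seq(0, 1, 0.05),
                      n = seq(0, 1, 0.05), c = seq(0, 1, 0.05))
  got <- decide(belief_matrix(grid$t, grid$e, grid$n), grid$c, w)
  # independent re-statement of the rule
  sigma <- function(x) 1 / (1 + exp(-x))
  p <- sigma(w$logistic_scale * (w$alpha * grid$t + w$beta * grid$e +
                                   w$gamma * grid$n - w$delta * grid$c -
                                   w$intercept))
  fear_gate <- grid$t >= w$theta_threat & grid$e < w$theta_efficacy
  want <- ifelse(!fear_gate & p >= w$tau, "evacuate", "stay")
  expect_identical(got, want)
})

test_that("ties at the threshold resolve toward evacuating", {
  w <- decision_weights(alpha = 1, beta = 1, gamma = 1, delta = 1,
                        intercept = 0, tau = 0.5)
  # zero inputs: danger control (threat below gate), propensity exactly 0.5
  expect_equal(decide(belief_matrix(0, 0, 0), 0, w), "evacuate")
})

test_that("fear control suppresses action regardless of propensity", {
  w <- decision_weights(alpha = 5, beta = 0.1, gamma = 0.1, delta = 0.1,
                        intercept = 0, theta_threat = 0.6,
                        theta_efficacy = 0.4)
  b <- belief_matrix(0.9, 0.1, 0.5)
  expect_gt(evacuation_propensity(0.9, 0.1, 0.5, 0, w), 0.95)
  expect_equal(decide(b, 0, w), "stay")
})

test_that("within danger control, decisions are monotone in beliefs and constraints", {
  w <- default_weights()
  set.seed(55)
  n <- 400
  t0 <- stats::runif(n); e0 <- stats::runif(n); n0 <- stats::runif(n)
  c0 <- stats::runif(n)
  base <- decide(belief_matrix(t0, e0, n0), c0, w)
  # removing constraints can only move stay -> evacuate
  lower_c <- decide(belief_matrix(t0, e0, n0), pmax(c0 - 0.3, 0), w)
  expect_false(any(base == "evacuate" & lower_c == "stay"))
  # raising any belief never flips evacuate -> stay while both sides stay
  # in the danger-control branch
  for (k in 1:3) {
    t1 <- t0 + (k == 1) * 0.2; e1 <- e0 + (k == 2) * 0.2
    n1 <- n0 + (k == 3) * 0.2
    t1 <- pmin(t1, 1); e1 <- pmin(e1, 1); n1 <- pmin(n1, 1)
    in_dc <- appraise(t0, e0, w) == "danger_control" &
      appraise(t1, e1, w) == "danger_control"
    after <- decide(belief_matrix(t1, e1, n1), c0, w)
    expect_false(any(in_dc & base == "evacuate" & after == "stay"))
  }
})

test_that("population-level response to threat is gated by efficacy", {
  # under the shipped calibration, fear-only compliance stays at or below
  # fear+efficacy compliance
  fear <- run_condition(condition_spec("F1", 222, 3, seed = 9))
  both <- run_condition(condition_spec("M1", 222, 3, seed = 9))
  expect_lte(sum(fear$evacuated), sum(both$evacuated))
})
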