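# Shared fixtures built in code for the test suite.

# A single-zone population config with fully known marginals, handy for
# convergence checks against the configured distributions.
one_zone_config <- function(n_agents, seed = 1, p_flood = 0.3,
                            p_prior = 0.4, dist_km = 10) {
  zone <- list(
    zone_id = "Z1", weight = 1,
    age_marginal = list(labels = c("18-29", "30-44", "45-64", "65+"),
                        probs = c(0.2, 0.3, 0.3, 0.2)),
    income_marginal = list(labels = c("under_25k", "25k_50k", "50k_75k",
                                      "75k_125k", "over_125k"),
                           probs = c(0.2, 0.25, 0.25, 0.2, 0.1)),
    education_marginal = list(labels = c("less_than_hs", "high_school",
                                         "some_college", "bachelor",
                                         "graduate"),
                              probs = c(0.1, 0.3, 0.3, 0.2, 0.1)),
    ethnicity_marginal = list(labels = c("hispanic", "white_nh", "black_nh",
                                         "other"),
                              probs = c(0.65, 0.15, 0.15, 0.05)),
    p_flood_zone = p_flood, p_prior_hurricane = p_prior,
    shelter_distance_km = dist_km,
    constraint_prevalences = list(mobility_limited = 0.1, no_vehicle = 0.1,
                                  financial_barrier = 0.2, pets = 0.35,
                                  caregiving = 0.1)
  )
  list(n_agents = n_agents, seed = seed, zones = list(zone))
}

# A single synthetic agent profile row with controllable attributes.
one_agent <- function(in_flood = FALSE, prior = FALSE, income = "under_25k",
                      edu = "less_than_hs", dist = 10, ...) {
  ag <- data.frame(agent_id = "A00001", zone_id = "Z1", age_band = "30-44",
                   income_band = income, education_level = edu,
                   ethnicity = "hispanic", in_flood_zone = in_flood,
                   prior_hurricane_experience = prior,
                   shelter_distance_km = dist,
                   mobility_limited = FALSE, no_vehicle = FALSE,
                   financial_barrier = FALSE, pets = FALSE,
                   caregiving = FALSE, stringsAsFactors = FALSE)
  extra <- list(...)
  for (k in names(extra)) ag[[k]] <- extra[[k]]
  ag
}

# Belief matrix with exact construct values (severity = susceptibility = T,
# both efficacy components = E, norm = N), so aggregate_constructs recovers
# (T, E, N) exactly under the mean composition.
belief_matrix <- function(threat, efficacy, norm) {
  cbind(severity = threat, susceptibility = threat, self_efficacy = efficacy,
        response_efficacy = efficacy, subjective_norm = norm)
}

# Independent textbook implementation of the Pearson chi-square test with
# adjusted standardized residuals, used as the oracle for chi_square_test.
textbook_chisq <- function(counts) {
  n <- sum(counts)
  rt <- rowSums(counts); ct <- colSums(counts)
  expected <- outer(rt, ct) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  adj <- (counts - expected) /
    sqrt(expected * outer(1 - rt / n, 1 - ct / n))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       adjusted_residuals = adj)
}

# Random r x 2 contingency table with no zero marginals.
random_table <- function(rows = 3, lambda = c(8, 40)) {
  repeat {
    counts <- cbind(evacuated = stats::rpois(rows, lambda[1]),
                    not_evacuated = stats::rpois(rows, lambda[2]))
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0) &&
        all(counts > 0)) break
  }
  build_table(data.frame(condition_id = paste0("R", seq_len(rows)),
                         evacuated = counts[, 1],
                         not_evacuated = counts[, 2]))
}
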