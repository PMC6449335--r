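# Shared fixtures for the test suite.

# A cheap campaign for property tests: 8 lakes, 2 chambers each.
tiny_config <- function(seed = 7L, ...) {
  campaign_config(
    seed = seed,
    n_lakes_per_zone = c(isolated = 2L, sporadic = 2L,
                         discontinuous = 2L, continuous = 2L),
    n_chambers_range = c(2L, 2L),
    ...)
}

# The default-conditions campaign (76 lakes, 3 seasons, ~900 chambers) and
# its pipeline result, computed once per test run and cached.
.campaign_cache <- new.env(parent = emptyenv())

default_campaign <- function() {
  if (is.null(.campaign_cache$camp)) {
    .campaign_cache$camp <- simulate_campaign(campaign_config(seed = 1L))
  }
  .campaign_cache$camp
}

default_pipeline <- function() {
  if (is.null(.campaign_cache$res)) {
    .campaign_cache$res <- suppressMessages(run_pipeline(default_campaign()))
  }
  .campaign_cache$res
}

# Independent closed-form OLS oracle (sums of squares), kept deliberately
# separate from the lm-based implementation.
ols_oracle <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * tm
  ss_tot <- sum((y - ym)^2)
  ss_res <- sum((y - intercept - slope * t)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = r2)
}
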