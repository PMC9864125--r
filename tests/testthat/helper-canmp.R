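# shared builders and independent oracles

make_observations <- function(counts, code = "X-1", mass = 50) {
  tibble::tibble(
    code = code,
    replicate = seq_along(counts),
    subsample_mass_g = mass,
    particle_count = as.integer(counts)
  )
}

make_particles <- function(n = 10, shape = "fragment", color = "blue",
                           size_mm = 1, polymer = NA_character_,
                           verified = "not_analyzed") {
  tibble::tibble(
    sample_id = "X-1-r1",
    shape = rep_len(shape, n),
    color = rep_len(color, n),
    size_mm = rep_len(size_mm, n),
    polymer = rep_len(polymer, n),
    verified = rep_len(verified, n)
  )
}

# closed-form mean of Normal(mu, sigma) truncated to [0, Inf) — independent
# oracle for the Monte Carlo engine
truncnorm_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

truncnorm_sd <- function(mu, sigma) {
  a <- -mu / sigma
  z <- dnorm(a) / (1 - pnorm(a))
  sigma * sqrt(1 + a * z - z^2)
}

reference_concentration_fixture <- function() {
  read_concentrations(canmp_example("reference_concentrations.csv"))
}

reference_polymer_fixture <- function() {
  readr::read_csv(canmp_example("reference_polymer_shares.csv"),
                  show_col_types = FALSE)
}

shares_vector <- function(poly, which_shape) {
  sub <- poly[poly$shape == which_shape, ]
  stats::setNames(sub$share_pct, sub$polymer)
}
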