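toy_traits <- function() data.frame(
  species = c("deer", "peccary", "bird"),
  guild = c("mammal", "mammal", "bird"),
  mass_kg = c(20, 25, 3),
  gregarious = c(FALSE, TRUE, FALSE))

test_that("kilometric index follows the contact/individual convention", {
  tr <- toy_traits()
  contacts <- data.frame(
    site = c(rep(1, 6), rep(1, 2)),
    species = c(rep("deer", 6), rep("peccary", 2)),
    km_position = 1,
    group_size = c(rep(1, 6), 3, 5),
    total_km = c(rep(12, 6), rep(10, 2)))
  sites <- data.frame(site = 1, total_km = 12)
  ki <- kilometric_index(contacts, tr, sites)
  expect_equal(ki$ki[ki$species == "deer"], 6 / 12)        # contacts/km
  # gregarious: individuals per km; effort comes from the site table
  sites10 <- data.frame(site = 1, total_km = 10)
  ki10 <- kilometric_index(contacts, tr, sites10)
  expect_equal(ki10$ki[ki10$species == "peccary"], (3 + 5) / 10)
  # zero contacts -> 0.0, not missing
  expect_equal(ki$ki[ki$species == "bird"], 0)

  expect_error(kilometric_index(
    data.frame(site = 1, species = "yeti", group_size = 1,
               km_position = 1, total_km = 5), tr), "missing trait")
})

test_that("KI is invariant to proportional rescaling of counts and effort", {
  tr <- toy_traits()
  base <- data.frame(site = 1, species = "deer", km_position = 1:4,
                     group_size = 1, total_km = 20)
  tripled <- data.frame(site = 1, species = "deer", km_position = 1:12,
                        group_size = 1, total_km = 60)
  k1 <- kilometric_index(base, tr, data.frame(site = 1, total_km = 20))
  k3 <- kilometric_index(tripled, tr, data.frame(site = 1, total_km = 60))
  expect_equal(k1$ki, k3$ki)
})

test_that("biomass index is mass-weighted and additive over species", {
  tr <- toy_traits()
  ki <- data.frame(site = c(1, 1, 1),
                   species = c("deer", "peccary", "bird"),
                   ki = c(0.5, 0.2, 1.0))
  bi <- biomass_index(ki, tr)
  expect_equal(bi$biomass, c(0.5 * 20, 0.2 * 25, 1.0 * 3))
  comm <- community_index(bi, "biomass")
  expect_equal(comm$total, 10 + 5 + 3)                      # manual sum
  # permutation invariance
  comm2 <- community_index(bi[c(3, 1, 2), ], "biomass")
  expect_equal(comm2$total, comm$total)
  ki$ki[1] <- -1
  expect_error(biomass_index(ki, tr), "negative")
})

test_that("effort truncation gives r = 1 at full length and flags overruns", {
  set.seed(33)
  n_sites <- 12
  L <- rep(100, n_sites)
  contacts <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    n <- rpois(1, 0.3 * L[s])
    data.frame(site = s, species = "deer", km_position = runif(n, 0, L[s]),
               group_size = 1, total_km = L[s])
  }))
  sites <- data.frame(site = seq_len(n_sites), total_km = L)
  eff <- effort_sufficiency(contacts, sites, c(50, 100, 120),
                            species = "deer")
  expect_equal(eff$r[eff$d == 100], 1)
  expect_equal(eff$r[eff$d == 120], 1)     # capped at full length
  expect_equal(attr(eff, "capped"), c(0L, 0L, 12L))
  expect_lt(eff$r[eff$d == 50], 1)
  expect_error(effort_sufficiency(contacts, sites[1:5, ], 50), "10")
})

test_that("guild-summed abundance vs footprint uses the definitional r", {
  # synthetic stand-in site table (the deposited survey table is not
  # redistributable); checks the computation, not the published values
  set.seed(5)
  n <- 30
  hfi <- runif(n, 0, 25)
  tab <- data.frame(site = 1:n, hfi = hfi,
                    deer_ki = exp(-0.05 * hfi) * rlnorm(n, 0, 0.3),
                    agouti_ki = exp(-0.03 * hfi) * rlnorm(n, 0, 0.3),
                    bird_ki = exp(-0.1 * hfi) * rlnorm(n, 0, 0.3))
  res <- site_prey_correlations(tab, c("deer_ki", "agouti_ki"), "bird_ki")
  # definitional product-moment formula as oracle
  r_def <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$guild == "mammals"],
               r_def(tab$deer_ki + tab$agouti_ki, hfi), tolerance = 1e-12)
  expect_equal(res$r[res$guild == "birds"], r_def(tab$bird_ki, hfi),
               tolerance = 1e-12)
  expect_equal(res$n, c(30, 30))
})
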