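test_that("the transformation step reproduces the hand-derived pool update", {
  # one node, MB = 1 ugC, no DOM: growth 0, mortality splits 0.55/0.45,
  # respiration 0.02 -> (0.93, 0.0275, 0.0225, 0, 0.02), sum preserved
  st <- transform_step(bio_state(volumes = 1, mb = 1),
                       bio_params(dt = 0.1 * 86400))
  expect_equal(unname(st$b[1, ]), c(0.93, 0.0275, 0.0225, 0, 0.02))
  expect_equal(sum(st$b), 1)

  # all-zero state stays all-zero
  z <- transform_step(bio_state(volumes = 1), bio_params())
  expect_equal(sum(abs(z$b)), 0)
})

test_that("transformation conserves carbon for arbitrary states and parameters", {
  for (seed in 1:5) {
    st <- poreskel:::with_seed(seed, bio_state(volumes = runif(20, 0.5, 3),
                                               mb = runif(20), dom = runif(20),
                                               som = runif(20), fom = runif(20)))
    p <- poreskel:::with_seed(seed + 100,
                              bio_params(rho = runif(1, 0, 1), mu = runif(1, 0, 1),
                                         v_dom = runif(1, 0, 10),
                                         v_som = runif(1, 0, 0.1),
                                         v_fom = runif(1, 0, 0.5), dt = 30))
    tot <- sum(st$b)
    expect_equal(sum(transform_step(st, p)$b), tot, tolerance = 1e-14)
  }
})

test_that("transformation guards against destructive time steps", {
  expect_error(transform_step(bio_state(volumes = 1, mb = 1),
                              bio_params(rho = 0.6, mu = 0.5, dt = 86400 * 2)),
               "time step too large")
  # enormous growth demand empties the DOM pool below zero
  expect_error(transform_step(bio_state(volumes = 1e-3, mb = 50, dom = 0.01),
                              bio_params(v_dom = 9.6, dt = 86400 * 0.9)),
               "negative")
})

test_that("theta is the conductance-scaled Fick exchange volume", {
  p <- bio_params(alpha = 0.35, dc = 1, dt = 30 * 86400)   # dc=1/day, dt=30 days
  expect_equal(theta(2, 4, p), 5.25)
  expect_equal(theta(0, 4, p), 0)                          # no contact, no arc
  p2 <- bio_params(alpha = 0.35, dc = 1, dt = 60 * 86400)
  expect_equal(theta(2, 4, p2), 2 * theta(2, 4, p))        # linear in dt
  expect_error(theta(1, 0, p), "distance")
})

two_node_graph <- function() {
  pore_graph(data.frame(id = 1:2, volume = 1, cx = c(0, 1), cy = 0, cz = 0),
             data.frame(r = 1L, s = 2L, faces = 1L, area_um2 = 1, distance = 1))
}

test_that("implicit diffusion matches the closed-form two-node solve", {
  g <- two_node_graph()
  p <- bio_params(dc = 1, alpha = 1, dt = 86400, rho = 0, mu = 0, v_dom = 0,
                  v_som = 0)                               # Theta = 1
  st <- diffusion_step_implicit(bio_state(g, dom = c(1, 0)), g, p)
  expect_equal(st$b[, 2], c(2 / 3, 1 / 3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("explicit diffusion matches direct evaluation and enforces stability", {
  g <- two_node_graph()
  p <- bio_params(dc = 0.25, alpha = 1, dt = 86400, rho = 0, mu = 0, v_dom = 0,
                  v_som = 0)                               # Theta = 0.25
  st <- diffusion_step_explicit(bio_state(g, dom = c(1, 0)), g, p)
  expect_equal(st$b[, 2], c(0.75, 0.25), ignore_attr = TRUE)

  p_bad <- bio_params(dc = 1.5, alpha = 1, dt = 86400, rho = 0, mu = 0,
                      v_dom = 0, v_som = 0)                # Theta/v = 1.5
  expect_error(diffusion_step_explicit(bio_state(g, dom = c(1, 0)), g, p_bad),
               "unstable")
})

test_that("uniform concentrations are equilibria of both schemes", {
  g <- make_fixture_graph(40, seed = 2)
  st <- bio_state(g, dom = 3 * g$nodes$volume)             # uniform c = 3
  p <- bio_params(dc = 10, alpha = 0.5, dt = 30)
  im <- diffusion_step_implicit(st, g, p)
  ex <- diffusion_step_explicit(st, g, p)
  expect_equal(im$b[, 2], st$b[, 2], tolerance = 1e-12)
  expect_equal(ex$b[, 2], st$b[, 2], tolerance = 1e-12)
})

test_that("carbon is conserved over 1000 alternating steps and the implicit scheme obeys the maximum principle", {
  g <- make_fixture_graph(100, seed = 11)
  init <- place_initial_biomass(g, total_mb = 0.18, n_spots = 10, mode = "spots",
                                seed = 5, total_dom = 2)
  # scale dc so the explicit scheme is comfortably stable at dt = 30 s
  op_unit <- poreskel:::diffusion_operator(g, bio_params(dc = 1, alpha = 0.35, dt = 30))
  dc <- 0.5 / max(op_unit$rs / g$nodes$volume)
  p <- bio_params(dc = dc, alpha = 0.35, dt = 30)
  total0 <- sum(init$b)
  dur <- 1000 * 30 / 86400
  for (scheme in c("implicit", "explicit")) {
    sim <- simulate_mineralization(g, init, p, dur, scheme = scheme)
    expect_equal(nrow(sim$series), 1001)
    drift <- max(abs(rowSums(sim$series[, c("MB", "DOM", "SOM", "FOM", "CO2")]) - total0))
    expect_lt(drift / total0, 1e-9)
  }
  # maximum principle for a single implicit step from a rough state
  st <- place_initial_biomass(g, 0, n_spots = 1, seed = 1, total_dom = 0)
  st$b[, 2] <- poreskel:::with_seed(3, runif(100, 0, 5)) * st$v
  c0 <- st$b[, 2] / st$v
  c1 <- diffusion_step_implicit(st, g, p)$b[, 2] / st$v
  expect_gte(min(c1), min(c0) - 1e-10)
  expect_lte(max(c1), max(c0) + 1e-10)
})

test_that("with no diffusion the graph simulation decouples into independent node reactions", {
  g <- make_fixture_graph(15, seed = 3)
  init <- place_initial_biomass(g, 0.1, n_spots = 5, mode = "spots", seed = 2,
                                total_dom = 1)
  p0 <- bio_params(dc = 0, dt = 360)
  sim <- simulate_mineralization(g, init, p0, 0.1, scheme = "explicit",
                                 snapshot_times = 0.1)
  st <- init
  for (s in seq_len(nrow(sim$series) - 1)) st <- transform_step(st, p0)
  expect_equal(sim$final_state$b, st$b, tolerance = 1e-12)
})

test_that("a single-node graph reproduces the 0D model exactly", {
  g1 <- pore_graph(data.frame(id = 1L, volume = 50, cx = 0, cy = 0, cz = 0),
                   data.frame(r = integer(0), s = integer(0)))
  p <- bio_params(dt = 120)
  sim <- simulate_mineralization(g1, bio_state(g1, mb = 0.2, dom = 1.5), p, 0.3)
  ref <- ode0d(c(0.2, 1.5, 0, 0), p, 0.3, total_volume = 50)
  expect_equal(sim$series$MB, ref$series$MB, tolerance = 1e-12)
  expect_equal(sim$series$CO2, ref$series$CO2, tolerance = 1e-12)
})

test_that("0D model: geometric biomass decay when growth and mortality are off", {
  p <- bio_params(rho = 0.2, mu = 0, v_dom = 0, v_som = 0, dt = 3600)
  r <- ode0d(c(1, 2, 0, 0), p, 1, total_volume = 10)
  ks <- seq_len(nrow(r$series)) - 1
  expect_equal(r$series$MB, (1 - 0.2 * 3600 / 86400)^ks, tolerance = 1e-12)
  expect_equal(r$series$DOM, rep(2, length(ks)))           # DOM untouched
})

test_that("0D long run mineralizes nearly all carbon to CO2 over decades", {
  # growth/crossover phase needs a finer step than the slow SOM tail, so the
  # thirty-year horizon is integrated in two phases
  total <- 0.18 + 289.5
  r1 <- ode0d(c(0.18, 289.5, 0, 0), bio_params(dt = 300), 730,
              total_volume = 1e4)
  g1 <- pore_graph(data.frame(id = 1L, volume = 1e4, cx = 0, cy = 0, cz = 0),
                   data.frame(r = integer(0), s = integer(0)))
  r2 <- simulate_mineralization(g1, r1$final_state, bio_params(dt = 3600),
                                28 * 365, scheme = "explicit")
  last <- tail(r2$series, 1)
  expect_lt(last$MB / total, 5e-3)
  expect_lt(last$DOM / total, 5e-3)
  expect_lt(last$SOM / total, 0.01)
  expect_gt(last$CO2 / total, 0.98)
})

test_that("biomass placement is seeded, mass-conserving and mode-dependent", {
  g <- make_fixture_graph(30, seed = 9)
  a <- place_initial_biomass(g, 1, n_spots = 7, mode = "spots", seed = 42,
                             total_dom = 5)
  b <- place_initial_biomass(g, 1, n_spots = 7, mode = "spots", seed = 42,
                             total_dom = 5)
  expect_identical(a$b, b$b)
  expect_equal(sum(a$b[, 1]), 1)
  expect_equal(sum(a$b[, 2]), 5)
  expect_equal(sum(a$b[, 1] > 0), 7)                       # distinct spots
  conc <- a$b[, 2] / a$v
  expect_equal(max(conc) - min(conc), 0, tolerance = 1e-12) # uniform DOM

  u <- place_initial_biomass(g, 1, mode = "uniform")
  expect_equal(u$b[, 1], g$nodes$volume / sum(g$nodes$volume), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(place_initial_biomass(g, 1, n_spots = 31, mode = "spots"),
               "exceeds")
})
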