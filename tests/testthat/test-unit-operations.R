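test_that("homogenizer heats the sludge to about 40 degC and conserves composition", {
  s2 <- ref_stream("s2")
  s3 <- homogenize(s2)
  expect_equal(s3$flows, s2$flows)
  expect_lt(abs(s3$temperature - 40.04), 0.5)
  # no-op at zero pressure rise
  expect_equal(homogenize(s2, delta_P = 0)$temperature, s2$temperature)
  # temperature rise is linear in delta_P (direct-arithmetic oracle)
  dT1 <- homogenize(s2, 100)$temperature - s2$temperature
  dT2 <- homogenize(s2, 200)$temperature - s2$temperature
  expect_equal(dT2, 2 * dT1, tolerance = 1e-12)
  expect_error(homogenize(s2, efficiency = 0), "efficiency")
})

test_that("reagent dosing reproduces the reference feed streams", {
  dosed <- dose_reagents(ref_stream("s3"))
  expect_equal(stream_total(dosed$enzyme), 4.79, tolerance = 0.01)
  expect_equal(dosed$enzyme$flows[["enzymes"]], 0.94, tolerance = 0.01)
  expect_equal(dosed$enzyme$flows[["sucrose"]], 1.44, tolerance = 0.01)
  expect_equal(stream_total(dosed$h2so4), 0.88, tolerance = 0.005)
  expect_equal(dosed$h2so4$flows[["h2so4"]], 0.86, tolerance = 0.005)
  expect_equal(stream_total(dosed$caoh2), 2.79, tolerance = 0.005)
  expect_equal(dosed$caoh2$flows[["caoh2"]], 1.40, tolerance = 0.005)
  expect_true(all(vapply(dosed, function(s) s$temperature, numeric(1)) ==
                    25))
})

test_that("dosing a zero sludge flow yields three zero streams and density is required", {
  zero <- process_stream(25, flows = c())
  dosed <- dose_reagents(zero)
  expect_equal(vapply(dosed, stream_total, numeric(1)),
               c(enzyme = 0, h2so4 = 0, caoh2 = 0))
  expect_error(dose_reagents(ref_stream("s3"), sludge_density = NA),
               "density")
})

test_that("hydrolysis and neutralization follow the stated stoichiometry", {
  feed <- mix_streams(list(ref_stream("s3"), ref_stream("s4"),
                           ref_stream("s5"), ref_stream("s6")))
  out <- hydrolyze_and_neutralize(feed)
  expect_equal(out$flows[["protein"]], 25.03 * 0.45, tolerance = 1e-9)
  expect_equal(out$flows[["amino_acids"]], 25.03 * 0.55, tolerance = 1e-9)
  expect_equal(out$flows[["caso4"]], 0.86 * 136.14 / 98.08,
               tolerance = 1e-9)
  expect_equal(out$flows[["caoh2"]], 1.40 - 0.86 * 74.09 / 98.08,
               tolerance = 1e-9)
  expect_equal(out$flows[["h2so4"]], 0)
  expect_equal(out$flows[["water"]] - feed$flows[["water"]],
               0.86 * 36.03 / 98.08, tolerance = 1e-9)
  expect_equal(out$temperature, 50)
  # total mass conserved exactly
  expect_equal(stream_total(out), stream_total(feed), tolerance = 1e-12)
  # published rounded values
  expect_equal(out$flows[["amino_acids"]], 13.77, tolerance = 0.01)
  expect_equal(out$flows[["protein"]], 11.26, tolerance = 0.01)
  expect_equal(out$flows[["caso4"]], 1.2, tolerance = 0.01)
  expect_equal(out$flows[["caoh2"]], 0.75, tolerance = 0.005)
})

test_that("hydrolysis reactor errors on a Ca(OH)2 deficit and passes through at zero extent", {
  starved <- process_stream(40, flows = c(water = 100, protein = 10,
                                          h2so4 = 1, caoh2 = 0.1))
  expect_error(hydrolyze_and_neutralize(starved), "insufficient Ca\\(OH\\)2")
  inert <- process_stream(40, flows = c(water = 100, protein = 10))
  out <- hydrolyze_and_neutralize(inert, reaction_spec(conversion = 0))
  expect_equal(out$flows, inert$flows)
  expect_equal(out$temperature, 50)
})

test_that("exchanger duty matches the hot-side energy balance", {
  feed <- mix_streams(list(ref_stream("s3"), ref_stream("s4"),
                           ref_stream("s5"), ref_stream("s6")))
  he <- exchanger_duty(feed)
  # algebraic identity: hot flow x cp_hot x 20 degC returns the duty
  expect_equal(he$hot_water_flow * cp_model()$cp_hot * 20, he$duty,
               tolerance = 1e-9)
  expect_equal(he$duty, 10336.50, tolerance = 0.03 * 10336.50)
  # zero duty when already at target
  at_t <- process_stream(50, flows = c(water = 10))
  expect_equal(exchanger_duty(at_t)$duty, 0)
  # approach violation: cold inlet too close to the hot return
  warm <- process_stream(58, flows = c(water = 10))
  expect_error(exchanger_duty(warm, T_target = 60), "approach")
})

test_that("centrifuge split reproduces the reference cake and centrate", {
  out <- centrifuge(ref_stream("s7"))
  expect_equal(stream_total(out$cake), 61.05, tolerance = 0.05)
  expect_equal(stream_total(out$centrate), 207.82, tolerance = 0.05)
  expect_equal(out$cake$flows[["water"]], 19.95, tolerance = 0.02)
  expect_equal(out$cake$flows[["amino_acids"]], 1.28, tolerance = 0.01)
  expect_equal(out$cake$flows[["sucrose"]], 0.13, tolerance = 0.05)
  expect_equal(out$centrate$flows[["amino_acids"]], 12.48,
               tolerance = 0.01)
  expect_equal(out$centrate$flows[["sucrose"]], 1.31, tolerance = 0.01)
  # no insolubles escape to the centrate at full recovery
  insol <- components_of_class("insoluble-solid")
  expect_equal(sum(out$centrate$flows[insol]), 0)
})

test_that("centrifuge honours the cake-humidity contract on random feeds", {
  set.seed(11)
  insol <- components_of_class("insoluble-solid")
  liq <- setdiff(component_names(), insol)
  for (i in 1:25) {
    feed <- random_stream()
    if (sum(feed$flows[insol]) == 0) next
    r <- stats::runif(1, 0.05, 0.6)
    spec <- centrifuge_spec(cake_liquid_fraction = r)
    S <- sum(feed$flows[insol])
    L <- sum(feed$flows[liq])
    if (S * r / (1 - r) > L) next
    out <- centrifuge(feed, spec)
    # cake liquid mass fraction equals the spec value exactly
    expect_equal(sum(out$cake$flows[liq]) / stream_total(out$cake), r,
                 tolerance = 1e-9)
    # entrained liquor fraction agrees with a numeric root-finding oracle
    # for cake * r = f * L with cake = S + f * L
    f_closed <- S * r / ((1 - r) * L)
    f_root <- stats::uniroot(function(f) (S + f * L) * r - f * L,
                             c(0, 1), tol = 1e-12)$root
    expect_equal(f_closed, f_root, tolerance = 1e-8)
    expect_equal(sum(out$cake$flows[liq]) / L, f_closed,
                 tolerance = 1e-9)
    # dissolved-solute ratios in the cake liquor match the feed liquor
    pos <- liq[feed$flows[liq] > 0]
    expect_equal(out$cake$flows[pos] / feed$flows[pos],
                 stats::setNames(rep(f_closed, length(pos)), pos),
                 tolerance = 1e-9)
    # mass closure
    expect_equal(stream_total(out$cake) + stream_total(out$centrate),
                 stream_total(feed), tolerance = 1e-12)
  }
})

test_that("centrifuging a solids-free feed returns it unchanged as centrate", {
  feed <- process_stream(50, flows = c(water = 100, amino_acids = 6))
  out <- centrifuge(feed)
  expect_equal(stream_total(out$cake), 0)
  expect_stream_equal(out$centrate, feed)
})

test_that("solar sizing follows the daily-energy capture rule", {
  sz <- size_solar(10336.50)
  expect_equal(sz$capture_area,
               10336.50 * 24 * 1.2 / (8 * 350.22 * 10), tolerance = 1e-12)
  expect_equal(round(sz$capture_area, 2), 10.63)
  expect_equal(round(sz$collectors_required, 1), 5.6)
  expect_equal(sz$collectors_installed, 7)
  # degenerate input keeps only the installed spare
  sz0 <- size_solar(0)
  expect_equal(sz0$capture_area, 0)
  expect_equal(sz0$collectors_installed, 1)
  expect_equal(size_solar(0, solar_spec(spare_collectors = 0))
               $collectors_installed, 0)
  # area is linear in duty
  expect_equal(size_solar(2 * 10336.50)$capture_area,
               2 * sz$capture_area, tolerance = 1e-12)
})

test_that("storage tanks size linearly with residence time", {
  v <- size_storage_tank(260.42, 1, 1.03)
  expect_equal(v, 8.07, tolerance = 0.01)
  expect_equal(size_storage_tank(260.42, 0, 1.03), 0)
  expect_equal(size_storage_tank(260.42, 3, 1.03), 3 * v,
               tolerance = 1e-12)
})
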