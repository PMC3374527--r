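test_that("activity_ee evaluates the published formula", {
  expect_equal(activity_ee(1, 1, 1), 4.184)
  expect_equal(activity_ee(6, 80, 0), 0)
  # independent hand evaluation: 8 x 70 x 0.5 x 4.184 = 1171.52 kJ/d
  expect_equal(activity_ee(8.0, 70.0, 0.5), 1171.52)
  expect_error(activity_ee(3, 70, -1), "negative duration")
  expect_error(activity_ee(0, 70, 1), "met must be positive")
  expect_error(activity_ee(3, 0, 1), "weight_kg must be positive")
})

test_that("score_response sums activity energies into domains and total", {
  p <- make_profile(weight = 60)
  empty <- make_response(rank = 1, occ_hours = 0)
  ep0 <- score_response(empty, p, CAT, MAP)
  expect_equal(ep0$crude_total_kj, 0)
  expect_equal(ep0$crude_hours, 0)

  single <- make_response(rank = 1, occ_hours = 0,
                          items = item_row("household_chores",
                                           "7 times/week", "60 min"))
  ep1 <- score_response(single, p, CAT, MAP)
  expect_equal(ep1$crude_total_kj, activity_ee(3.0, 60, 1))
  expect_equal(ep1$per_domain_kj[["leisure"]], activity_ee(3.0, 60, 1))

  multi <- make_response(rank = 3, occ_hours = 6, items = rbind(
    item_row("walking_transport", "7 times/week", "30 min"),
    item_row("watching_tv", "7 times/week", "120 min"),
    item_row("jogging_running", "3 times/week", "60 min")))
  ep <- score_response(multi, p, CAT, MAP)
  expect_equal(sum(ep$per_domain_kj), ep$crude_total_kj, tolerance = 1e-12)
  expect_equal(sum(ep$per_activity_kj), ep$crude_total_kj, tolerance = 1e-12)
  # occupation term uses the effort-rank MET and free-entry hours
  expect_equal(ep$per_domain_kj[["occupation"]], activity_ee(3.0, 60, 6))
  expect_equal(ep$crude_hours, 6 + 0.5 + 2 + 3 / 7)
  expect_error(score_response(
    make_response(items = item_row("quidditch")), p, CAT, MAP),
    "lookup error")
})

test_that("adjust_to_24h fills the day with sleep and signed MET-2 time", {
  p <- make_profile(weight = 70)
  mk <- function(occ_hours) {
    adjust_to_24h(score_response(make_response(rank = 3,
                                               occ_hours = occ_hours),
                                 p, CAT, MAP), 70)
  }
  exact <- mk(16)     # 16 h reported + 8 h sleep: zero filler
  expect_equal(exact$filler_hours, 0)
  expect_equal(exact$adjusted_total_kj,
               exact$crude_total_kj + activity_ee(0.9, 70, 8))
  # the cohort-mean day: 11.4 reported hours leaves 4.6 h of filler
  mean_day <- mk(11.4)
  expect_equal(mean_day$filler_hours, 4.6)
  expect_equal(mean_day$adjusted_total_kj,
               mean_day$crude_total_kj + activity_ee(0.9, 70, 8) +
                 activity_ee(2.0, 70, 4.6))
  # over-reporting: negative filler subtracts energy
  over <- mk(18)
  expect_equal(over$filler_hours, -2)
  expect_equal(over$adjusted_total_kj,
               over$crude_total_kj + activity_ee(0.9, 70, 8) -
                 2.0 * 70 * 2 * 4.184)
})

test_that("scored profiles conserve energy and the 24-h time budget", {
  set.seed(101)
  for (i in 1:25) {
    w <- runif(1, 45, 110)
    p <- make_profile(weight = w)
    r <- random_response("P1", n_items = sample(0:6, 1))
    ep <- adjust_to_24h(score_response(r, p, CAT, MAP), w)
    expect_equal(sum(ep$per_activity_kj), ep$crude_total_kj,
                 tolerance = 1e-12)
    expect_equal(sum(ep$per_domain_kj), ep$crude_total_kj, tolerance = 1e-12)
    expect_equal(ep$crude_hours + ep$sleep_hours + ep$filler_hours, 24)
    expect_true(all(ep$per_activity_kj >= 0))
  }
})

test_that("adding MET-2.0 activity time leaves adjusted EE unchanged", {
  set.seed(202)
  for (i in 1:10) {
    w <- runif(1, 50, 100)
    p <- make_profile(weight = w)
    base <- make_response(rank = 2, occ_hours = runif(1, 2, 8),
                          items = item_row("jogging_running",
                                           "3 times/week", "45 min"))
    # musical_instrument_computer_games carries MET exactly 2.0
    extra <- sample(c("30 min", "60 min", "240 min"), 1)
    with_met2 <- make_response(rank = 2, occ_hours = base$occupation_hours,
                               items = rbind(base$items,
                                             item_row("musical_instrument_computer_games",
                                                      "7 times/week", extra)))
    a0 <- adjust_to_24h(score_response(base, p, CAT, MAP), w)
    a1 <- adjust_to_24h(score_response(with_met2, p, CAT, MAP), w)
    expect_equal(a1$adjusted_total_kj, a0$adjusted_total_kj,
                 tolerance = 1e-9)
    expect_gt(a1$crude_total_kj, a0$crude_total_kj)
  }
})

test_that("adjusted EE is monotone in activity duration relative to MET 2", {
  p <- make_profile(weight = 65)
  adj_with <- function(id, dur) {
    r <- make_response(rank = 1, occ_hours = 4,
                       items = item_row(id, "7 times/week", dur))
    adjust_to_24h(score_response(r, p, CAT, MAP), 65)$adjusted_total_kj
  }
  # MET 8 activity: more time, more adjusted energy
  expect_gt(adj_with("jogging_running", "60 min"),
            adj_with("jogging_running", "30 min"))
  # MET 1 activity: more time, less adjusted energy
  expect_lt(adj_with("watching_tv", "60 min"),
            adj_with("watching_tv", "30 min"))
})

test_that("all energy outputs scale linearly in weight", {
  r <- make_response(rank = 4, occ_hours = 7,
                     items = item_row("spinning", "2 times/week", "45 min"))
  e1 <- adjust_to_24h(score_response(r, make_profile(weight = 50), CAT, MAP), 50)
  e2 <- adjust_to_24h(score_response(r, make_profile(weight = 100), CAT, MAP), 100)
  expect_equal(e2$crude_total_kj, 2 * e1$crude_total_kj, tolerance = 1e-12)
  expect_equal(e2$adjusted_total_kj, 2 * e1$adjusted_total_kj,
               tolerance = 1e-12)
})

test_that("met_hours recovers weight-free MET-hours", {
  w <- 70
  r <- make_response(rank = 3, occ_hours = 2)
  ep <- score_response(r, make_profile(weight = w), CAT, MAP)
  mh <- met_hours(ep, w)
  expect_equal(mh$crude_total, 3.0 * 2)  # MET 3 for 2 h
})
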