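test_that("the end-tidal CO2 bridge is the published linear map", {
  expect_equal(petco2_from_co_change(0), 0.13)
  # 7-11% end-tidal changes correspond to roughly 20-33% CO changes
  expect_equal(co_change_from_petco2(7), (7 - 0.13) / 0.33)
  expect_equal(co_change_from_petco2(7), 20.8, tolerance = 0.01)
  expect_equal(co_change_from_petco2(11), 32.9, tolerance = 0.01)
  x <- c(-20, -5, 0, 9, 30)
  expect_equal(co_change_from_petco2(petco2_from_co_change(x)), x)
})

test_that("a single-point sweep equals a direct comparison", {
  sw <- tpf_sweep(0.75, angle_deg = 90)
  direct <- cached_cmp(0.75, 90)
  expect_equal(sw$results[[1]]$pct_change, direct$pct_change,
               tolerance = 1e-10)
  expect_equal(sw$table$co_before, direct$before$co)
})

test_that("sweep axes are validated and tables are well-formed", {
  expect_error(tpf_sweep(c(0.5, 0.2)), "strictly increasing")
  expect_error(tpf_sweep(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(angle_sweep(c(10, 100)), "\\[0, 90\\]")
  sw <- tpf_sweep(0.75, angle_deg = 90)
  expect_s3_class(as.data.frame(sw), "data.frame")
  expect_named(sw$table, c("tpf", "co_before", "co_after", "cpp_change",
                           "co_change", "q_heart_change", "q_head_change",
                           "transferred_ml", "transfer_fraction_pct",
                           "p_ppv_after"))
})

test_that("baseline cardiac output decreases with the thoracic pump factor", {
  co <- vapply(c(0, 0.25, 0.5, 0.75, 1),
               function(tpf) cached_cmp(tpf, 90)$before$co, numeric(1))
  expect_true(all(diff(co) < 0))
  # pure cardiac pump is the strongest regime, pure thoracic the weakest
  expect_gt(co[1], 1.8)
  expect_lt(co[5], 1.3)
})

test_that("transferred volume grows monotonically with elevation angle", {
  fr <- vapply(c(0, 30, 45, 60, 90), function(a)
    leg_volume_transfer(cached_cmp(0.75, a))$transferred_ml, numeric(1))
  expect_true(all(diff(fr) > 0))
  # hydrostatic pressure scales with sin(angle), so does the shifted volume
  expect_equal(fr[2] / fr[5], sin(30 * pi / 180), tolerance = 0.2)
})

test_that("cerebral flow benefits from PLR at every pump regime", {
  qh <- vapply(c(0, 0.25, 0.5, 0.75, 1),
               function(tpf) cached_cmp(tpf, 90)$pct_change[["q_head"]],
               numeric(1))
  expect_true(all(qh > 0))
})

test_that("table comparison report lines up simulated and reference values", {
  sw <- structure(list(axis = "tpf", values = c(0, 0.5, 1),
                       results = list(cached_cmp(0, 90), cached_cmp(0.5, 90),
                                      cached_cmp(1, 90))),
                  class = "cpr_sweep")
  tab <- reproduce_table3(sweep = sw)
  expect_equal(nrow(tab), 9)
  expect_named(tab, c("metric", "tpf", "before", "after", "change_pct",
                      "ref_before", "ref_after", "ref_change_pct",
                      "dev_before_rel", "dev_change_pp"))
  # simulated absolute baselines track the reference values
  expect_true(all(abs(tab$dev_before_rel[tab$metric != "q_head"]) < 0.15))
  expect_true(all(abs(tab$dev_before_rel) < 0.25))
  bad <- structure(list(values = c(0, 0.5)), class = "cpr_sweep")
  expect_error(reproduce_table3(sweep = bad), "0, 0.5, 1")
})
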