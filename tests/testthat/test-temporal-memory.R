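test_that("anomaly is 1 on first presentation and 0 once a cycle is learned", {
  tm <- temporal_memory(80, 4, seed = 1)
  pats <- disjoint_sdrs(5, 4, 80)
  out <- tm_compute(tm, pats[[1]])
  expect_equal(out$anomaly, 1)
  an <- 1
  for (r in 1:30) for (p in pats) an <- tm_compute(tm, p)$anomaly
  expect_equal(an, 0)
})

test_that("confidence is 0 with no prediction and scales with predicted columns", {
  tm <- temporal_memory(60, 5, seed = 2)
  p <- sdr(0:4, 60)
  out <- tm_compute(tm, p)
  expect_equal(out$confidence, 0)
  q <- sdr(10:14, 60)
  for (r in 1:5) { tm_reset(tm); tm_compute(tm, p); tm_compute(tm, q) }
  tm_reset(tm)
  out <- tm_compute(tm, p)
  expect_equal(out$confidence, 1)
  expect_equal(out$predicted_columns$active, 10:14)
})

test_that("high-order context disambiguates shared subsequences", {
  # ABC and XBY: after learning, B is predicted differently depending on
  # what preceded it, so C vs Y are distinguished (cells, not just columns)
  tm <- temporal_memory(100, 4, cells_per_column = 8, seed = 3)
  v <- disjoint_sdrs(5, 4, 100)
  A <- v[[1]]; B <- v[[2]]; C <- v[[3]]; X <- v[[4]]; Y <- v[[5]]
  for (r in 1:40) {
    tm_reset(tm); for (p in list(A, B, C)) tm_compute(tm, p)
    tm_reset(tm); for (p in list(X, B, Y)) tm_compute(tm, p)
  }
  tm_reset(tm); tm_compute(tm, A); outB <- tm_compute(tm, B, learn = FALSE)
  expect_true(all(C$active %in% outB$predicted_columns$active))
  expect_false(any(Y$active %in% outB$predicted_columns$active))
  tm_reset(tm); tm_compute(tm, X); outB2 <- tm_compute(tm, B, learn = FALSE)
  expect_true(all(Y$active %in% outB2$predicted_columns$active))
  expect_false(any(C$active %in% outB2$predicted_columns$active))
})

test_that("tm_predict queries superpositions without touching state", {
  tm <- temporal_memory(60, 4, seed = 4)
  v <- disjoint_sdrs(4, 4, 60)
  for (r in 1:5) {
    tm_reset(tm); tm_compute(tm, v[[1]]); tm_compute(tm, v[[2]])
    tm_reset(tm); tm_compute(tm, v[[3]]); tm_compute(tm, v[[4]])
  }
  tm_reset(tm)
  cells1 <- all_cells <- NULL
  q <- function(s) {
    cols <- s$active
    cells <- as.integer(outer(0:(tm$cells - 1L), cols * tm$cells, `+`))
    sdr(cells, n = tm$n_cells)
  }
  before <- tm$pred_cols
  p1 <- tm_predict(tm, q(v[[1]]))
  expect_equal(p1$predicted_columns$active, v[[2]]$active)
  # superposition query: union of the individual predictions
  pu <- tm_predict(tm, sdr(union(q(v[[1]])$active, q(v[[3]])$active),
                           n = tm$n_cells))
  expect_setequal(pu$predicted_columns$active,
                  union(v[[2]]$active, v[[4]]$active))
  expect_identical(tm$pred_cols, before)
})

test_that("segment introspection reports presynaptic and owner columns", {
  tm <- temporal_memory(40, 3, seed = 5)
  a <- sdr(0:2, 40); b <- sdr(10:12, 40)
  tm_reset(tm); tm_compute(tm, a); tm_compute(tm, b)
  segs <- seq_len(tm$seg_n)
  pre <- tm_segment_columns(tm, segs)
  own <- tm_segment_owner_columns(tm, segs)
  expect_true(all(own %in% b$active))
  for (cc in pre) expect_true(all(cc %in% a$active))
})

test_that("wrong predictions are punished toward forgetting", {
  tm <- temporal_memory(60, 4, perm_punish = 0.2, seed = 6)
  v <- disjoint_sdrs(3, 4, 60)
  for (r in 1:3) { tm_reset(tm); tm_compute(tm, v[[1]]); tm_compute(tm, v[[2]]) }
  # now repeatedly present 1 -> 3: the 1->2 segments get punished
  for (r in 1:20) { tm_reset(tm); tm_compute(tm, v[[1]]); tm_compute(tm, v[[3]]) }
  tm_reset(tm)
  out <- tm_compute(tm, v[[1]], learn = FALSE)
  expect_false(any(v[[2]]$active %in% out$predicted_columns$active))
  expect_true(all(v[[3]]$active %in% out$predicted_columns$active))
})

test_that("apical feedback alone can drive predictions", {
  tm <- temporal_memory(60, 4, apical_enabled = TRUE, apical_space = 30,
                        apical_threshold = 3, seed = 7)
  fb <- sdr(0:3, 30)
  a <- sdr(0:3, 60); b <- sdr(20:23, 60)
  for (r in 1:5) {
    tm_reset(tm)
    tm_compute(tm, a, apical_input = fb)
    tm_compute(tm, b, apical_input = fb)
  }
  # fresh context, apical only: feeding a with feedback predicts b's columns
  tm_reset(tm)
  out <- tm_compute(tm, a, apical_input = fb, learn = FALSE)
  expect_true(all(b$active %in% out$predicted_columns$active))
})

test_that("state snapshot and restore preserve behavior", {
  tm <- temporal_memory(60, 4, seed = 8)
  v <- disjoint_sdrs(3, 4, 60)
  for (r in 1:5) { tm_reset(tm); tm_compute(tm, v[[1]]); tm_compute(tm, v[[2]]) }
  st <- tm_state(tm)
  tm2 <- tm_restore(st)
  tm_reset(tm); tm_reset(tm2)
  o1 <- tm_compute(tm, v[[1]], learn = FALSE)
  o2 <- tm_compute(tm2, v[[1]], learn = FALSE)
  expect_true(o1$predicted_columns == o2$predicted_columns)
})
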