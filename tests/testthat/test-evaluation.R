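test_that("identical wave lists give an identity correspondence", {
  df <- one_wave(c(10, 50, 90), c(15, 55, 95), c(20, 60, 100))
  H <- correspondence_matrix(df, df)
  expect_equal(H, diag(1L, 3))
})

test_that("disjoint intervals never match", {
  a <- one_wave(10, 15, 20)
  b <- one_wave(21, 25, 30)
  expect_equal(correspondence_matrix(a, b), matrix(0L, 1, 1))
  expect_error(correspondence_matrix(one_wave(c(50, 10), c(55, 15),
                                              c(60, 20)), a), "ordered")
})

test_that("correspondence agrees with a literal membership oracle", {
  set.seed(202)
  for (rep in 1:1000) {
    n <- sample(150:300, 1)
    a <- random_wave_df(n); a <- a[a$wave == "QRS", ]
    b <- random_wave_df(n); b <- b[b$wave == "QRS", ]
    expect_identical(correspondence_matrix(a, b), brute_force_H(a, b))
  }
})

test_that("lead fusion is an elementwise OR with OR's algebra", {
  A <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  B <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  expect_equal(fuse_leads(list(A)), A)
  f <- fuse_leads(list(A, B))
  expect_equal(f, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(fuse_leads(list(B, A)), f)
  expect_equal(fuse_leads(list(A, B, A)), f)
  expect_error(fuse_leads(list(A, matrix(0L, 1, 2))), "dimension")
})

test_that("a wave caught on either lead counts once as TP", {
  truth <- one_wave(c(10, 50), c(15, 55), c(20, 60))
  H_lead1 <- brute_force_H(truth, one_wave(10, 15, 20))   # misses wave 2
  H_lead2 <- brute_force_H(truth, one_wave(50, 55, 60))   # misses wave 1
  ## pad to common prediction space: two predictions, one per lead
  H1 <- cbind(H_lead1, 0L); H2 <- cbind(0L, H_lead2)
  fused <- fuse_leads(list(H1, H2))
  cnt <- detection_counts(fused, M = 2, M_hat = 2)
  expect_equal(cnt$TP, 2)
  expect_equal(cnt$FP, 0)
  expect_equal(cnt$FN, 0)
})

test_that("detection counts match the hand-worked 3x2 case", {
  ## M = 3 true waves, 2 predictions, both matched
  H <- matrix(c(1L, 0L, 0L,
                0L, 1L, 0L), 3, 2)
  cnt <- detection_counts(H)
  expect_equal(cnt$TP, 2)
  expect_equal(cnt$FP, 0)
  expect_equal(cnt$FN, 1)
  expect_equal(cnt$precision, 1)
  expect_equal(cnt$recall, 2 / 3)
})

test_that("degenerate detection cases follow the 0/0 convention", {
  perfect <- detection_counts(diag(1L, 4))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  empty_pred <- detection_counts(matrix(0L, 5, 0), M = 5, M_hat = 0)
  expect_equal(empty_pred$TP, 0)
  expect_equal(empty_pred$FN, 5)
  expect_equal(empty_pred$precision, 1)
  expect_equal(empty_pred$recall, 0)
})

test_that("delineation errors carry the true-minus-predicted sign in ms", {
  truth <- one_wave(100, 105, 110)
  pred <- one_wave(102, 107, 112)   # 2 samples late at 250 Hz
  H <- correspondence_matrix(truth, pred)
  err <- delineation_errors(truth, list(pred), list(H), fs = 250)
  expect_equal(err$on_err_ms, -8)
  expect_equal(err$off_err_ms, -8)
})

test_that("the closest lead wins the per-wave error minimization", {
  truth <- one_wave(100, 105, 110)
  pred1 <- one_wave(95, 100, 107)    # onset error +5 samples
  pred2 <- one_wave(99, 104, 109)    # onset error +1 sample
  H1 <- correspondence_matrix(truth, pred1)
  H2 <- correspondence_matrix(truth, pred2)
  err <- delineation_errors(truth, list(pred1, pred2), list(H1, H2), 250)
  expect_equal(err$on_err_ms, 4)     # 1 sample at 250 Hz
  ## matches a full enumeration over matched (j, lead) pairs
  cands_on <- c(100 - 95, 100 - 99) * 4
  expect_equal(err$on_err_ms, cands_on[which.min(abs(cands_on))])
})

test_that("error magnitudes are multiples of the sample period", {
  set.seed(33)
  for (rep in 1:50) {
    n <- 300
    truth <- random_wave_df(n); truth <- truth[truth$wave == "T", ]
    if (!nrow(truth)) next
    jit <- truth
    jit$on <- pmax(0L, jit$on + sample(-3:3, nrow(jit), TRUE))
    jit$peak <- pmax(jit$on, jit$peak)
    jit$off <- pmax(jit$peak, jit$off + sample(-3:3, nrow(jit), TRUE))
    jit <- jit[order(jit$on), ]
    H <- correspondence_matrix(truth, jit)
    err <- delineation_errors(truth, list(jit), list(H), 250)
    expect_true(all(abs(err$on_err_ms %% 4) < 1e-9 |
                    abs(err$on_err_ms %% 4 - 4) < 1e-9))
  }
})

test_that("dice score counts overlap per channel with the empty convention", {
  a <- seg_mask(cbind(P = c(rep(1, 6), rep(0, 6)), QRS = rep(0, 12),
                      T = rep(1, 12)), fs = 250)
  b <- seg_mask(cbind(P = c(rep(0, 2), rep(1, 6), rep(0, 4)),
                      QRS = rep(0, 12), T = rep(1, 12)), fs = 250)
  d <- dice_score(a, b)
  expect_equal(unname(d["P"]), 2 * 4 / (6 + 6))
  expect_equal(unname(d["QRS"]), 1)   # both empty
  expect_equal(unname(d["T"]), 1)
  disjoint <- seg_mask(cbind(P = c(rep(0, 6), rep(1, 6)), QRS = rep(0, 12),
                             T = rep(1, 12)), fs = 250)
  expect_equal(unname(dice_score(a, disjoint)["P"]), 0)
  expect_error(dice_score(a, seg_mask(matrix(0, 5, 3), fs = 250)), "shape")
})

test_that("identical observers show zero inter-observer bias", {
  out <- fixture_record(seed = 15)
  rep <- interobserver_bias(out$fiducials, out$fiducials)
  expect_equal(rep$on_mean_ms, rep(0, 3))
  expect_equal(rep$on_sd_ms, rep(0, 3))
  expect_true(all(rep$n > 0))
})

test_that("a constant one-sample shift appears as a 4 ms QRS bias", {
  out <- fixture_record(seed = 16)
  shifted <- out$fiducials
  for (l in seq_along(shifted$leads)) {
    qrs <- shifted$leads[[l]]$wave == "QRS"
    shifted$leads[[l]]$on[qrs] <- shifted$leads[[l]]$on[qrs] + 1L
  }
  rep <- interobserver_bias(out$fiducials, shifted)
  qrs_row <- rep[rep$wave == "QRS", ]
  expect_equal(qrs_row$on_mean_ms, -4)  # obs1 - obs2
  expect_equal(qrs_row$on_sd_ms, 0)
  expect_equal(qrs_row$off_mean_ms, 0)
})

test_that("a wave type absent in one observer is skipped", {
  out <- fixture_record(seed = 17)
  nop <- out$fiducials
  for (l in seq_along(nop$leads))
    nop$leads[[l]] <- nop$leads[[l]][nop$leads[[l]]$wave != "P", ]
  rep <- interobserver_bias(out$fiducials, nop)
  p_row <- rep[rep$wave == "P", ]
  expect_true(p_row$skipped)
  expect_equal(p_row$n, 0)
})

test_that("injected Gaussian jitter is recovered by the bias estimator", {
  delta <- 2.5; sigma <- 1.5  # samples
  spec <- sim_spec(duration = 600, seed = 19, missing_p_probability = 0)
  out <- generate_record(spec, "r")
  jittered <- out$fiducials
  set.seed(55)
  for (l in seq_along(jittered$leads)) {
    df <- jittered$leads[[l]]
    df$on <- df$on + as.integer(round(rnorm(nrow(df), delta, sigma)))
    df$off <- df$off + as.integer(round(rnorm(nrow(df), delta, sigma)))
    df$peak <- pmin(pmax(df$peak, df$on), df$off)
    jittered$leads[[l]] <- df[order(df$on), ]
  }
  rep <- interobserver_bias(out$fiducials, jittered)
  ms <- 4  # 1000 / 250
  for (w in c("P", "QRS", "T")) {
    row <- rep[rep$wave == w, ]
    expect_gt(row$n, 300)
    expect_equal(row$on_mean_ms, -delta * ms, tolerance = 0.15)
    expect_equal(row$on_sd_ms, sigma * ms, tolerance = 0.2)
  }
})

test_that("a wave correlates perfectly with itself at zero lag", {
  set.seed(9)
  x <- rnorm(40)
  cc <- ecgdelnet:::ncc_best(x, x)
  expect_equal(cc$peak, 1)
  expect_equal(cc$lag, 0L)
})

test_that("duplicated waves with differing offsets yield the 8 ms gap", {
  fs <- 250
  b <- generate_beat(beat_template(), fs)
  n <- 3 * b$n
  sig <- rep(0, n)
  sig[seq_len(b$n)] <- b$waveform
  sig[2 * b$n + seq_len(b$n)] <- b$waveform  # exact copy later on
  t1 <- b$fiducials[b$fiducials$wave == "T", ]
  t2 <- t1
  t2$on <- t2$on + 2L * b$n
  t2$peak <- t2$peak + 2L * b$n
  t2$off <- t2$off + 2L * b$n + 2L  # annotated 2 samples (8 ms) later
  fid <- fiducial_set("r", list(lead1 = rbind(t1, t2)), fs, n_samples = n)
  rec <- ecg_record("r", matrix(sig, ncol = 1), fs)
  rep <- intraobserver_bias(fid, rec)
  t_row <- rep[rep$wave == "T", ]
  expect_equal(t_row$n, 1)
  expect_equal(abs(t_row$off_mean_ms), 8)
  expect_equal(t_row$on_mean_ms, 0)
})

test_that("unrelated noise segments are almost never matched at 0.99", {
  set.seed(70)
  fs <- 250
  n <- 4000
  sig <- rnorm(n)
  ons <- seq(50L, 3800L, by = 150L)
  df <- data.frame(beat = seq_along(ons), wave = "T", on = ons,
                   peak = ons + 10L, off = ons + 20L)
  fid <- fiducial_set("r", list(lead1 = df), fs, n_samples = n)
  rec <- ecg_record("r", matrix(sig, ncol = 1), fs)
  rep <- intraobserver_bias(fid, rec)
  n_pairs <- choose(length(ons), 2)
  matched_frac <- rep[rep$wave == "T", "n"] / n_pairs
  expect_lt(matched_frac, 0.02)
})

test_that("perfect predictions give unit rates and zero errors end-to-end", {
  out <- fixture_record(seed = 21)
  preds <- list(fix001 = list(lead_waves(out$fiducials, 1),
                              lead_waves(out$fiducials, 2)))
  rep <- evaluate_delineation(preds, list(fix001 = out$fiducials))
  expect_equal(rep$waves$precision, rep(1, 3))
  expect_equal(rep$waves$recall, rep(1, 3))
  expect_equal(rep$waves$f1, rep(1, 3))
  expect_equal(rep$waves$on_mean_ms, rep(0, 3))
  expect_equal(rep$waves$off_sd_ms, rep(0, 3))
})

test_that("empty predictions give zero recall but unit precision", {
  out <- fixture_record(seed = 22)
  empty <- lead_waves(out$fiducials, 1)[0, ]
  preds <- list(fix001 = list(empty, empty))
  rep <- evaluate_delineation(preds, list(fix001 = out$fiducials))
  expect_equal(rep$waves$recall, rep(0, 3))
  expect_equal(rep$waves$precision, rep(1, 3))
  expect_equal(rep$waves$TP, rep(0, 3))
})

test_that("fusing an extra lead never lowers TP nor raises FN", {
  set.seed(88)
  for (rep_i in 1:200) {
    n <- 250
    truth <- random_wave_df(n); truth <- truth[truth$wave == "QRS", ]
    predA <- random_wave_df(n); predA <- predA[predA$wave == "QRS", ]
    predB <- random_wave_df(n); predB <- predB[predB$wave == "QRS", ]
    HA <- correspondence_matrix(truth, predA)
    HB <- correspondence_matrix(truth, predB)
    tp1 <- if (nrow(truth)) sum(rowSums(HA) > 0) else 0
    both <- if (nrow(truth)) sum(rowSums(HA) > 0 | rowSums(HB) > 0) else 0
    expect_gte(both, tp1)
  }
})
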