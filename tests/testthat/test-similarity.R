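make_connectome <- function(edges, labels = sprintf("R%02d", 1:10)) {
  unvectorize(edges, labels)
}

test_that("Fisher-z similarity matches a direct correlation oracle and the clipping rule", {
  set.seed(51)
  n_edge <- 45
  ev_a <- rnorm(n_edge)
  ev_b <- rnorm(n_edge)
  conns <- list(a = make_connectome(ev_a), b = make_connectome(ev_b),
                a2 = make_connectome(ev_a))
  sim <- pairwise_similarity(conns)

  oracle <- atanh(stats::cor(ev_a, ev_b))
  expect_equal(sim$z["a", "b"], oracle, tolerance = 1e-12)
  expect_equal(sim$z["b", "a"], oracle, tolerance = 1e-12)
  # identical connectomes: r clipped to 1 - 1e-7, so z is large but finite
  expect_equal(sim$z["a", "a2"], atanh(1 - 1e-7))
  expect_true(is.finite(sim$z["a", "a2"]))
  expect_true(all(is.na(diag(sim$z))))
})

test_that("orthogonal edge vectors give z = 0 and zero-variance vectors are excluded", {
  ev <- c(1, -1, 1, -1)
  ev_orth <- c(1, 1, -1, -1)  # correlation exactly 0
  labels <- sprintf("R%d", 1:4)
  conns <- list(x = unvectorize(c(ev, 0, 0), labels),
                y = unvectorize(c(ev_orth, 0, 0), labels))
  expect_equal(pairwise_similarity(conns)$z["x", "y"],
               atanh(stats::cor(c(ev, 0, 0), c(ev_orth, 0, 0))),
               tolerance = 1e-12)

  flat <- unvectorize(rep(0.5, 6), labels)
  varied <- unvectorize(c(0.1, 0.2, 0.3, -0.1, 0, 0.4), labels)
  sim <- pairwise_similarity(list(flat = flat, varied = varied))
  expect_true(is.na(sim$z["flat", "varied"]))
})

test_that("pair categories follow the overlapping membership definitions", {
  sess <- data.frame(
    subject_id = c("sub-01", "sub-01", "sub-04"),
    dataset_id = c("A", "A", "B"),
    session_id = c("ses-001", "ses-002", "ses-001"),
    hc_use = c(1, 1, 1)
  )
  pr <- classify_pairs(sess)
  p12 <- pr[pr$a == 1 & pr$b == 2, ]
  expect_true(p12$is_individual)
  expect_equal(p12$primary, "individual")
  # different subject + dataset, same HC status: group and hc_use, not dataset
  p13 <- pr[pr$a == 1 & pr$b == 3, ]
  expect_true(p13$is_group && p13$is_hc_use)
  expect_false(p13$is_dataset)
  expect_equal(p13$primary, "hc_use")
})

test_that("pair counts match brute-force enumeration for 4 subjects x 2 sessions", {
  sess <- expand.grid(session_id = c("ses-1", "ses-2"),
                      subject_id = paste0("s", 1:4),
                      stringsAsFactors = FALSE)
  sess$dataset_id <- ifelse(sess$subject_id %in% c("s1", "s2"), "A", "B")
  sess$hc_use <- ifelse(sess$subject_id %in% c("s1", "s3"), 0, 1)
  pr <- classify_pairs(sess)

  # brute-force oracle over all index pairs
  n_ind <- n_all <- n_between <- 0
  for (a in 1:7) for (b in (a + 1):8) {
    n_all <- n_all + 1
    if (sess$subject_id[a] == sess$subject_id[b]) n_ind <- n_ind + 1
    else n_between <- n_between + 1
  }
  expect_equal(nrow(pr), n_all)
  expect_equal(n_all, 28L)
  expect_equal(sum(pr$is_individual), n_ind)
  expect_equal(n_ind, 4L)
  expect_equal(sum(pr$is_group), n_between)
  expect_equal(n_between, 24L)
})

test_that("degenerate and separated category values give t = 0 and clear significance", {
  sess <- data.frame(subject_id = c("s1", "s1", "s2", "s2"),
                     dataset_id = "A", session_id = paste0("ses-", 1:4),
                     hc_use = 0)
  labels <- sprintf("R%d", 1:4)
  same <- lapply(1:4, function(i) unvectorize(c(.1, .2, .3, .4, .5, .6), labels))
  names(same) <- paste(sess$subject_id, sess$session_id, sep = "_")
  sim <- pairwise_similarity(same)
  cs <- category_summary(sim, classify_pairs(sess))
  expect_true(all(cs$contrasts$t == 0))
  expect_false(any(cs$contrasts$significant))

  # near-complete separation flags significance
  a <- c(1, 1, 1) + c(1e-4, -1e-4, 0)
  b <- c(0, 0, 0) + c(1e-4, -1e-4, 0)
  tt <- stats::t.test(a, b)
  expect_lt(tt$p.value, 0.01)
})

test_that("strong individual offsets raise within-individual similarity significantly", {
  des <- small_multi_design(n_regions = 15, seed = 52)
  st <- generate_study(des, ground_truth_spec(individual_offset_scale = 0.8,
                                              noise_scale = 0.1))
  cs <- category_summary(pairwise_similarity(st),
                         classify_pairs(st$sessions))
  means <- setNames(cs$summary$mean_z, cs$summary$category)
  expect_gt(means["individual"], means["group"])
  row <- cs$contrasts[cs$contrasts$category_a == "group" &
                        cs$contrasts$category_b == "individual", ]
  expect_true(row$significant)
  expect_gt(normalized_effect_magnitude(means[["individual"]],
                                        means[["group"]]), 0)
})

test_that("similarity is permutation-equivariant in session order", {
  st <- generate_study(small_multi_design(n_regions = 12, seed = 53))
  sim <- pairwise_similarity(st)
  perm <- withr::with_seed(1, sample(length(st$connectomes)))
  sim_p <- pairwise_similarity(st$connectomes[perm])
  expect_equal(sim_p$z, sim$z[perm, perm], tolerance = 1e-12)
})

test_that("individual-minus-group effect magnitude grows with the individual offset", {
  mags <- vapply(c(0.1, 0.4, 0.8), function(s) {
    st <- generate_study(small_multi_design(n_regions = 15, seed = 54),
                         ground_truth_spec(individual_offset_scale = s,
                                           noise_scale = 0.15))
    cs <- category_summary(pairwise_similarity(st),
                           classify_pairs(st$sessions))
    means <- setNames(cs$summary$mean_z, cs$summary$category)
    normalized_effect_magnitude(means[["individual"]], means[["group"]])
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("normalized effect magnitude is a plain z-score difference", {
  expect_equal(normalized_effect_magnitude(1.07, 0.59), 0.48)
  expect_equal(normalized_effect_magnitude(1.07, 0.54), 0.53)
  expect_equal(normalized_effect_magnitude(0.77, 0.77), 0)
})
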