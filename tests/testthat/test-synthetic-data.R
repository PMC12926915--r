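test_that("protein simulation is deterministic and partitions classes", {
  cfg <- sim_config(seed = 1, n_per_class = 50)
  r1 <- simulate_protein_sets(cfg)
  r2 <- simulate_protein_sets(cfg)
  expect_identical(lapply(r1, `[[`, "sequence"),
                   lapply(r2, `[[`, "sequence"))
  expect_length(r1, 150)
  labs <- vapply(r1, `[[`, "", "label")
  expect_equal(as.vector(table(labs)), c(50, 50, 50))
})

test_that("planted acidic tracts lower NCPR of the FC-like class", {
  cfg <- sim_config(seed = 2, n_per_class = 100)
  recs <- simulate_protein_sets(cfg)
  labs <- vapply(recs, `[[`, "", "label")
  ncpr <- vapply(recs, function(r)
    compositional_features(r)[["NCPR"]], numeric(1))
  expect_lt(mean(ncpr[labs == "FC_like"]), mean(ncpr[labs == "nuclear"]))
  # K blocks raise NCPR of the DFC-like class
  expect_gt(mean(ncpr[labs == "DFC_like"]), mean(ncpr[labs == "nuclear"]))
  # FC-like proteins are drawn longer; DFC-like shorter, with RRM annotation
  len <- vapply(recs, function(r) nchar(r$sequence), numeric(1))
  expect_gt(mean(len[labs == "FC_like"]), mean(len[labs == "DFC_like"]))
  expect_true(all(vapply(recs[labs == "DFC_like"], function(r)
    "RRM" %in% r$annotations$category, logical(1))))
})

test_that("tract longer than the sequence is rejected with a sizing error", {
  cfg <- sim_config(seed = 1, n_per_class = 2,
                    length_dist = list(FC_like = c(60, 0),
                                       DFC_like = c(60, 0),
                                       nuclear = c(60, 0)),
                    tract_spec = list(
                      FC_like = list(residues = "D", block_length = 500L,
                                     count = 1L),
                      DFC_like = NULL, nuclear = NULL))
  expect_error(simulate_protein_sets(cfg), "sizing")
})

test_that("config invariants are validated", {
  bad <- setNames(rep(0.05, 20), AA)
  expect_error(sim_config(background_freqs = bad * 1.5), "sum to 1")
  expect_error(sim_config(mnar_slope = 0))
})

test_that("LFQ simulation honours the design and degenerates cleanly", {
  des <- expand.grid(bait = c("b1", "b2", "b3"), labtime = c(1, 3, 5, 15),
                     stringsAsFactors = FALSE)
  des$n_replicates <- 4L
  cfg <- sim_config(seed = 3, lfq_design = des,
                    effect_sizes = data.frame(bait = "b2", labtime = 5,
                                              shift = 2),
                    n_proteins = 50, noise_sd = 0)
  sim <- simulate_lfq(cfg)
  expect_equal(ncol(sim$lfq), 48)
  # noise-free, effect-free columns are identical before censoring
  cfg0 <- sim_config(seed = 3, lfq_design = des,
                     effect_sizes = data.frame(bait = character(),
                                               labtime = numeric(),
                                               shift = numeric()),
                     n_proteins = 50, noise_sd = 0)
  sim0 <- simulate_lfq(cfg0)
  expect_true(all(apply(sim0$complete, 1, function(r) max(r) - min(r)) == 0))
  # truth table records the planted effect
  expect_true(all(sim$truth$bait == "b2" & sim$truth$shift == 2))
})

test_that("MNAR censoring hits low-abundance proteins hardest", {
  cfg <- sim_config(seed = 4, n_proteins = 2000, baseline_sd = 3)
  sim <- simulate_lfq(cfg)
  dec <- cut(sim$baseline, quantile(sim$baseline, c(0, 0.1, 0.9, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  miss <- rowMeans(is.na(sim$lfq))
  expect_gt(mean(miss[dec == "low"]), mean(miss[dec == "high"]))
  # monotone censoring probability in intensity
  p <- plogis((cfg$mnar_mid - sort(rnorm(100, 25, 4))) / cfg$mnar_slope)
  expect_true(all(diff(p) <= 0))
})

test_that("image pairs are seeded, halo moves the channel-B peak outward", {
  cfg <- sim_config(seed = 5)
  p1 <- simulate_image_pair(cfg, halo = FALSE)
  p2 <- simulate_image_pair(cfg, halo = FALSE)
  expect_identical(p1$a, p2$a)
  # noise-free, halo off: channels identical, PCC 1
  cfg_inf <- sim_config(seed = 5, image_spec = list(snr = Inf))
  pp <- simulate_image_pair(cfg_inf, halo = FALSE)
  expect_equal(pp$a, pp$b)
  expect_equal(pearson_colocalization(pp), 1, tolerance = 1e-12)
  # halo on: radial profile of channel B peaks off-centre, channel A at 0
  ph <- simulate_image_pair(sim_config(seed = 6,
                                       image_spec = list(snr = Inf)),
                            halo = TRUE)
  rp_a <- radial_mean_profile(ph$a, ph$center_px)
  rp_b <- radial_mean_profile(ph$b, ph$center_px)
  expect_lt(rp_a$r[which.max(rp_a$mean_intensity)], 2)
  expect_gt(rp_b$r[which.max(rp_b$mean_intensity)], 5)
  # recorded pixel size propagates
  expect_equal(ph$pixel_size, 0.03)
})
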