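test_that("empty field contains only background and noise", {
  cfg <- test_sim_config(n_cells = 0)
  fg <- generate_field(cfg)
  expect_equal(nrow(fg$truth$cells), 0)
  expect_equal(nrow(fg$truth$vesicles), 0)
  for (ch in fg$field$channels) {
    expect_lt(abs(median(ch) - 300), 15)  # background 300 plus noise only
    expect_lt(max(ch), 300 + 8 * 30)      # no planted objects anywhere
  }
})

test_that("identical config and seed give bit-identical output", {
  cfg <- test_sim_config(seed = 42)
  a <- generate_field(cfg)
  b <- generate_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$vesicles, b$truth$vesicles)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(generate_field(cfg))
  expect_identical(rnorm(1), before)
})

test_that("realized positive fraction concentrates at the planted fraction", {
  cfgs <- lapply(1:4, function(s) {
    test_sim_config(seed = s, positivity_fraction = c(ubiquitin_FK2 = 0.5))
  })
  ves <- do.call(rbind, lapply(cfgs, function(cfg) {
    generate_field(cfg)$truth$vesicles
  }))
  n <- nrow(ves)
  expect_gte(n, 500)
  expect_lt(abs(mean(ves$positive_ubiquitin_FK2) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("vesicle placement respects the separation rule", {
  fg <- generate_field(test_sim_config(seed = 3))
  v <- fg$truth$vesicles
  d <- as.matrix(dist(v[, c("row", "col")]))
  need <- outer(v$radius_px, v$radius_px, "+") * 2
  diag(d) <- Inf
  expect_true(all(d >= need - 1e-9))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(image_shape = c(0, 10)), "image_shape")
  expect_error(sim_config(pixel_size = -1), "pixel_size")
  expect_error(sim_config(positivity_fraction = c(gal3 = 1.2)), "\\[0, 1\\]")
  expect_error(generate_field(test_sim_config(),
                              overrides = list(positivity = list(
                                ubiquitin_FK2 = 1.5))),
               "outside")
})

test_that("plate wells follow baseline x effect with clamping", {
  design <- plate_design()
  cfg <- test_sim_config(seed = 5)
  plate <- generate_plate(design, cfg, gene_effects = c(E2_10 = 0.25),
                          well_sd = 0)
  w <- plate$truth$wells
  lib <- w[w$gene == "E2_10" & w$staining == "ubiquitin_FK2", ]
  expect_equal(lib$planted_fraction, rep(0.8 * 0.25, nrow(lib)))
  ctl <- w[w$gene == "siCtrl" & w$treatment == "damaged" &
             w$staining == "ubiquitin_FK2", ]
  expect_equal(ctl$planted_fraction, rep(0.8, nrow(ctl)))
  unt <- w[w$treatment == "untreated", ]
  expect_equal(unique(unt$planted_fraction), 0.05)
  expect_true("E2_10" %in% plate$truth$true_hits)
})

test_that("metric-level plate has the designed well and cell counts", {
  design <- plate_design()
  expect_equal(sum(!design$is_control), 37 * 4)
  plate <- generate_plate(design, test_sim_config(), cells_per_well = 60)
  counts <- table(plate$cells$well_id, plate$cells$staining)
  expect_true(all(counts == 60))
  expect_equal(nrow(plate$truth$wells), nrow(design) * 2)  # two stainings
})

test_that("unknown gene in the effect map is reported by name", {
  design <- plate_design()
  expect_error(
    generate_plate(design, test_sim_config(), gene_effects = c(NOPE = 0.5)),
    "NOPE"
  )
})

test_that("effect monotonicity: larger effect never lowers the planted fraction", {
  design <- plate_design(genes = "E2_01", replicates = 2)
  frac_at <- function(eff) {
    plate <- generate_plate(design, test_sim_config(seed = 8),
                            gene_effects = c(E2_01 = eff), well_sd = 0)
    w <- plate$truth$wells
    mean(w$planted_fraction[w$gene == "E2_01"])
  }
  fr <- vapply(c(0.1, 0.3, 0.6, 1.0, 1.3), frac_at, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_lte(max(fr), 1)  # clamped
})

test_that("planted vesicle count equals rendered disks (zero noise)", {
  cfg <- noiseless_config(seed = 9)
  fg <- generate_field(cfg)
  img <- fg$field$channels$lysosome
  mask <- img > 300 + 5000 / 2  # half amplitude over background
  lab <- lysoscreen:::label_components(mask)
  expect_equal(max(lab), nrow(fg$truth$vesicles))
})

test_that("kinetics defaults: early K63/p62, late K48/UBE2QL1", {
  prof <- kinetics_profile()
  frac <- evaluate_kinetics(prof)
  expect_true(all(frac >= 0 & frac <= 1))
  # baseline at t = 0 for every marker
  expect_equal(unname(frac["0", ]), rep(0.05, 4))
  expect_equal(unname(which.max(frac[, "ubiquitin_K63"])), 3)  # t = 60
  expect_equal(unname(which.max(frac[, "p62"])), 3)
  expect_true(which.max(frac[, "ubiquitin_K48"]) %in% c(4, 5))  # 120/180
  expect_true(which.max(frac[, "ube2ql1"]) %in% c(4, 5))
  # the early markers must peak before the late ones
  t_peak <- function(m) prof$markers[[m]][["peak_time"]]
  expect_lt(t_peak("ubiquitin_K63"), t_peak("ubiquitin_K48"))
})

test_that("timecourse plants the profile fraction at each time point", {
  prof <- kinetics_profile(time_points = c(0, 60))
  cfg <- test_sim_config(seed = 2, n_cells = 6)
  tc <- generate_timecourse(prof, cfg)
  expect_equal(length(tc), 2)
  expect_equal(tc[[1]]$time, 0)
  frac <- evaluate_kinetics(prof)
  expect_equal(tc[[2]]$planted_fraction, frac["60", ])
  # realized labels track the planted fraction (binomial bound, pooled)
  v <- tc[[2]]$truth$vesicles
  f <- frac["60", "ubiquitin_K63"]
  expect_lt(abs(mean(v$positive_ubiquitin_K63) - f),
            3 * sqrt(f * (1 - f) / nrow(v)) + 1e-9)
  expect_error(kinetics_profile(time_points = c(60, 0)), "ascending")
  bad <- kinetics_profile(markers = list(x = c(baseline = 0.2, peak = 1.4,
                                               peak_time = 60, shape = 1)))
  expect_error(evaluate_kinetics(bad), "\\[0, 1\\]")
})

test_that("silac degenerate cases and arithmetic", {
  cfg <- silac_sim_config(n_proteins = 20, null_log2_sd = 0,
                          enriched_set = setNames(numeric(0), character(0)),
                          contaminant_fraction = 0, reverse_fraction = 0,
                          site_only_fraction = 0, detection_prob = 1)
  ds <- generate_silac_dataset(cfg)
  for (r in 1:4) {
    expect_equal(ds$quant[[paste0("heavy_", r)]],
                 ds$quant[[paste0("light_", r)]])  # log2 H/L exactly 0
  }
  cfg2 <- silac_sim_config(n_proteins = 5, null_log2_sd = 0,
                           enriched_set = c(P0001 = 2),
                           contaminant_fraction = 0, reverse_fraction = 0,
                           site_only_fraction = 0, detection_prob = 1)
  ds2 <- generate_silac_dataset(cfg2)
  expect_equal(ds2$quant$heavy_1[1] / ds2$quant$light_1[1], 4)  # H/L = 2^2
  expect_error(silac_sim_config(n_replicates = 1), "t-test")
  expect_error(silac_sim_config(detection_prob = 1.2), "\\[0, 1\\]")
  expect_error(silac_sim_config(n_proteins = 5,
                                enriched_set = c(P9999 = 2)), "outside")
})

test_that("silac null ratios satisfy the CLT bound and seed determinism", {
  cfg <- silac_sim_config(rng_seed = 7, n_proteins = 1000, null_log2_sd = 0.3,
                          enriched_set = setNames(numeric(0), character(0)),
                          detection_prob = 1)
  ds <- generate_silac_dataset(cfg)
  ratios <- log2(as.matrix(ds$quant[, paste0("heavy_", 1:4)]) /
                   as.matrix(ds$quant[, paste0("light_", 1:4)]))
  per_protein_mean <- rowMeans(ratios[ds$quant$protein_id %in%
                                        ds$truth$protein_id, ])
  expect_lt(abs(mean(per_protein_mean)), 3 * (0.3 / 2) / sqrt(1000))
  expect_identical(generate_silac_dataset(cfg)$quant, ds$quant)
})

test_that("metric-level and image-level plate fidelities agree", {
  # one gene, 16 zero-noise wells simulated both ways; the pooled
  # percent-positive readouts must agree within 2 percentage points
  design <- plate_design(genes = "E2_01", replicates = 16,
                         controls = character(0))
  cfg <- noiseless_config(seed = 21)
  met <- generate_plate(design, cfg, fidelity = "metric", well_sd = 0,
                        cells_per_well = 200)
  img <- generate_plate(design, cfg, fidelity = "image", well_sd = 0)
  pp_met <- with(met$cells[met$cells$staining == "ubiquitin_FK2", ],
                 100 * sum(n_positive) / sum(n_vesicles))
  pooled <- do.call(rbind, lapply(img$fields, function(fg) {
    q <- quantify_field(fg$field, marker_roles = "ubiquitin_FK2")
    q$vesicles
  }))
  pp_img <- 100 * mean(pooled$positive_ubiquitin_FK2)
  expect_lt(abs(pp_met - pp_img), 2)
})
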