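# One double-positive vesicle fixture: a lysosome disk with a concentric
# marker disk, plus one marker-negative lysosome.
double_positive_field <- function(seed = 1, snr = 10) {
  amp <- snr_amplitude(snr)
  set.seed(seed)
  lyso <- matrix(300, 96, 96)
  lyso <- lysoscreen:::render_disk(lyso, c(30, 30), 2.5, amp)
  lyso <- lysoscreen:::render_disk(lyso, c(60, 60), 2.5, amp)
  fk2 <- matrix(300, 96, 96)
  fk2 <- lysoscreen:::render_disk(fk2, c(30, 30), 2, amp)
  mk <- function(img) {
    lysoscreen:::apply_camera_noise(gaussian_blur(img, 0.8), 25, 0.5)
  }
  image_field(list(lysosome = mk(lyso), ubiquitin_FK2 = mk(fk2)),
              pixel_size = 0.25)
}

test_that("vesicle positivity criteria on planted fixtures", {
  field <- double_positive_field()
  ves <- detect_puncta(field, "lysosome")
  ves <- measure_objects(ves, field)
  mp <- detect_puncta(field, "ubiquitin_FK2")
  expect_equal(nrow(ves), 2)
  pos_overlap <- vesicle_is_positive(ves, "ubiquitin_FK2", "overlap",
                                     marker_puncta = mp)
  ord <- order(ves$row)  # vesicle at (30,30) first
  expect_equal(as.logical(pos_overlap)[ord], c(TRUE, FALSE))
  pos_int <- vesicle_is_positive(ves, "ubiquitin_FK2", "intensity",
                                 field = field)
  expect_equal(as.logical(pos_int)[ord], c(TRUE, FALSE))
  expect_error(vesicle_is_positive(ves, "ubiquitin_FK2", "overlap"),
               "marker_puncta")
})

test_that("a blank marker channel is negative under both criteria", {
  field <- double_positive_field()
  field$channels$ubiquitin_FK2 <- matrix(0, 96, 96)
  ves <- detect_puncta(field, "lysosome")
  ves <- measure_objects(ves, field)
  mp <- detect_puncta(field, "ubiquitin_FK2")
  expect_false(any(vesicle_is_positive(ves, "ubiquitin_FK2", "overlap",
                                       marker_puncta = mp)))
  expect_false(any(vesicle_is_positive(ves, "ubiquitin_FK2", "intensity",
                                       field = field)))
})

test_that("overlap classification accuracy vs planted labels at f = 0.5", {
  det_all <- list()
  truth_all <- list()
  for (s in 1:4) {
    cfg <- test_sim_config(seed = 100 + s,
                           positivity_fraction = c(ubiquitin_FK2 = 0.5))
    fg <- generate_field(cfg)
    q <- quantify_field(fg$field, marker_roles = "ubiquitin_FK2")
    # match detections to planted vesicles
    tv <- fg$truth$vesicles
    for (i in seq_len(nrow(q$vesicles))) {
      d2 <- (tv$row - q$vesicles$row[i])^2 + (tv$col - q$vesicles$col[i])^2
      j <- which.min(d2)
      if (d2[j] <= 9) {
        det_all[[length(det_all) + 1]] <- q$vesicles$positive_ubiquitin_FK2[i]
        truth_all[[length(truth_all) + 1]] <- tv$positive_ubiquitin_FK2[j]
      }
    }
  }
  acc <- mean(unlist(det_all) == unlist(truth_all))
  expect_gte(length(det_all), 500)
  expect_gte(acc, 0.95)
})

test_that("percent positive per cell: totals, degenerate cells, permutation", {
  ves <- data.frame(vesicle_id = 1:6, cell_id = c(1, 1, 1, 2, 2, 3),
                    row = 0, col = 0, radius_px = 2)
  pos <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  pp <- percent_positive_vesicles(ves, pos, cell_ids = 1:4)
  expect_equal(pp$percent_positive, c(100, 50, 0, NA))
  expect_equal(pp$excluded, c(FALSE, FALSE, FALSE, TRUE))
  perm <- sample(6)
  pp2 <- percent_positive_vesicles(ves[perm, ], pos[perm], cell_ids = 1:4)
  expect_equal(pp2, pp)
})

test_that("pooled percent positive meets the binomial recovery bound", {
  ves <- do.call(rbind, lapply(1:3, function(s) {
    cfg <- test_sim_config(seed = 40 + s,
                           positivity_fraction = c(gal3 = 0.3))
    generate_field(cfg)$truth$vesicles
  }))
  n <- nrow(ves)
  pp <- percent_positive_vesicles(ves, ves$positive_gal3)
  pooled <- 100 * sum(pp$n_positive) / sum(pp$n_vesicles)
  expect_gte(n, 300)
  expect_lt(abs(pooled - 30), 3 * sqrt(0.3 * 0.7 / n) * 100)
})

test_that("Pearson per cell: exact fixtures and undefined cases", {
  f <- image_field(list(a = matrix(c(1, 2, 3, 4), 2),
                        b = matrix(c(2, 4, 6, 8), 2),
                        d = matrix(c(4, 3, 2, 1), 2),
                        k = matrix(5, 2, 2)),
                   pixel_size = 1)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(pearson_per_cell(f, "a", "b", mask)$pcc, 1)
  expect_equal(pearson_per_cell(f, "a", "d", mask)$pcc, -1)
  res <- pearson_per_cell(f, "a", "k", mask)
  expect_false(res$defined)
  expect_true(is.na(res$pcc))  # undefined, never a silent 0
  # identical non-constant channels across a real field
  fg <- generate_field(test_sim_config(seed = 31))
  ff <- fg$field
  ff$channels$copy <- ff$channels$lysosome
  m <- matrix(TRUE, nrow(ff$channels[[1]]), ncol(ff$channels[[1]]))
  expect_equal(pearson_per_cell(ff, "lysosome", "copy", m)$pcc, 1)
})

test_that("independent noise decorrelates and affine maps preserve the PCC", {
  set.seed(7)
  a <- matrix(rnorm(10000, 500, 40), 100)
  b <- matrix(rnorm(10000, 500, 40), 100)
  f <- image_field(list(a = a, b = b, b_aff = 2.5 * b + 100,
                        b_neg = 2 * mean(b) - b),
                   pixel_size = 1)
  mask <- matrix(TRUE, 100, 100)
  r <- pearson_per_cell(f, "a", "b", mask)$pcc
  expect_lt(abs(r), 0.05)
  expect_equal(pearson_per_cell(f, "a", "b_aff", mask)$pcc, r,
               tolerance = 1e-12)
  expect_equal(pearson_per_cell(f, "a", "b_neg", mask)$pcc, -r,
               tolerance = 1e-12)
})

test_that("puncta-count classification is strict and monotone", {
  expect_true(count_and_classify_puncta(4, 3)$positive)    # > 3 positive
  expect_false(count_and_classify_puncta(3, 3)$positive)   # boundary negative
  expect_equal(count_and_classify_puncta(rep(0, 10), 3)$percent_positive_cells,
               0)
  expect_error(count_and_classify_puncta(1:3, -1), ">= 0")
  counts <- c(0, 2, 3, 4, 5, 9)
  base <- count_and_classify_puncta(counts, 3)$positive
  lowered <- count_and_classify_puncta(pmax(0, counts - 2), 3)$positive
  expect_true(all(lowered <= base))  # lowering counts never adds positives
})

test_that("nuclear/cytoplasmic ratio arithmetic and translocation", {
  cells <- data.frame(cell_id = 1:2,
                      nuclear_poi = c(10, 20), cytoplasm_poi = c(10, 10))
  expect_equal(nuclear_cytoplasmic_ratio(cells, "poi"), c(1, 0.5))
  # background-corrected undefined when nuclear mean falls to 0
  expect_true(is.na(nuclear_cytoplasmic_ratio(cells, "poi",
                                              background = 10)[1]))
  expect_error(nuclear_cytoplasmic_ratio(cells, "gal3"), "gal3")
  expect_error(nuclear_cytoplasmic_ratio(
    data.frame(cell_id = 1, nuclear_poi = NA_real_, cytoplasm_poi = 2), "poi"),
    "empty")
  # planted translocation: nuclear amplitude up, cytoplasm down => ratio drops
  mk_field <- function(nuc_amp, cyt_amp) {
    nucleus <- matrix(300, 96, 96)
    nucleus <- lysoscreen:::render_disk(nucleus, c(48, 48), 12, 5000)
    poi <- matrix(0, 96, 96)
    poi <- poi + cyt_amp
    poi <- lysoscreen:::render_disk(poi, c(48, 48), 12, nuc_amp - cyt_amp)
    image_field(list(nucleus = gaussian_blur(nucleus, 0.8),
                     poi = gaussian_blur(poi, 0.8)), pixel_size = 0.25)
  }
  ratio_of <- function(field) {
    nuc <- segment_nuclei(field)
    cells <- partition_cells(nuc, field)
    crec <- cell_records(nuc, cells, field, edge_margin = 0)
    nuclear_cytoplasmic_ratio(crec, "poi")
  }
  baseline <- ratio_of(mk_field(nuc_amp = 500, cyt_amp = 500))
  transloc <- ratio_of(mk_field(nuc_amp = 1500, cyt_amp = 200))
  expect_lt(transloc, baseline)
  expect_equal(baseline, 1, tolerance = 0.05)  # uniform concentration
})

test_that("fold-change normalization modes and guards", {
  expect_equal(as.numeric(fold_change_normalize(c(2, 4), c(2, 2))), c(1, 2))
  expect_equal(as.numeric(fold_change_normalize(2, c(1, 3))), 1)
  pct <- fold_change_normalize(c(1, 2), c(2, 2), mode = "percent_of_control")
  expect_equal(as.numeric(pct), c(50, 100))
  expect_equal(attr(pct, "mode"), "percent_of_control")
  expect_error(fold_change_normalize(1, c(0, 0)), "> 0")
})
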