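# Plate-level screening statistics: well summaries with a cells-per-well QC
# gate, robust z-scores against the whole plate, primary hit calling
# ("one or both" stainings at z <= -2), pool deconvolution ("both
# stainings" per single siRNA), group comparisons, and the screen report.

#' Summarize per-cell readouts into well summaries
#'
#' Per (well, staining): the median (primary summary) and mean of the
#' per-cell percent-positive readout and the number of analyzable cells.
#' Wells below the QC minimum keep their metadata but carry undefined
#' summaries.
#'
#' @param cells per-cell table with columns `well_id`, `staining`,
#'   `percent_positive` (NA for cells excluded upstream).
#' @param design a [plate_design()] supplying `gene`, `reagent`,
#'   `treatment` per well.
#' @param qc_min minimum analyzable cells per well (default 50).
#' @return data.frame of class `well_summary`: one row per well x staining
#'   with `n_cells`, `median_percent`, `mean_percent`, `qc_pass`.
#' @export
summarize_wells <- function(cells, design, qc_min = 50) {
  check_columns(cells, c("well_id", "staining", "percent_positive"),
                "per-cell table")
  check_columns(design, c("well_id", "gene", "reagent", "treatment"),
                "plate design")
  key <- interaction(cells$well_id, cells$staining, drop = TRUE)
  agg <- do.call(rbind, lapply(split(cells, key), function(d) {
    v <- d$percent_positive[!is.na(d$percent_positive)]
    data.frame(well_id = d$well_id[1], staining = d$staining[1],
               n_cells = length(v),
               median_percent = if (length(v)) median(v) else NA_real_,
               mean_percent = if (length(v)) mean(v) else NA_real_)
  }))
  agg$qc_pass <- agg$n_cells >= qc_min
  agg$median_percent[!agg$qc_pass] <- NA_real_
  agg$mean_percent[!agg$qc_pass] <- NA_real_
  out <- merge(design[, c("well_id", "gene", "reagent", "treatment")],
               agg, by = "well_id")
  out <- out[order(out$staining, out$well_id), ]
  rownames(out) <- NULL
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Robust z-scores against the whole plate
#'
#' The four replicate wells of each reagent are first collapsed to one
#' sample value `x_i` (median by default); `z_i = (x_i - median_plate) /
#' (1.4826 * MAD_plate)` where the plate reference population is all
#' QC-passing, damage-treated library samples (controls excluded from the
#' reference by default but still scored). The alternative
#' `replicate_mode = "per_well"` z-scores each well against the per-well
#' plate distribution and reports the replicate-median z.
#'
#' @param summaries a [summarize_wells()] table.
#' @param staining staining to score; default scores each staining present.
#' @param summary_col which well summary feeds the z-score.
#' @param replicate_mode `"average"` (replicates collapsed before scoring)
#'   or `"per_well"`.
#' @param replicate_average `"median"` or `"mean"` across replicate wells.
#' @param include_controls include control reagents in the plate reference
#'   population.
#' @param mad_constant scale factor making the MAD consistent with the
#'   normal sd (1.4826).
#' @return data.frame: `gene`, `reagent`, `staining`, `x`, `robust_z`,
#'   `n_wells`, with attributes recording the mode. Falls back to the plate
#'   SD (with a warning) when the MAD is zero; errors if the SD is zero too.
#' @export
robust_zscores <- function(summaries, staining = NULL,
                           summary_col = "median_percent",
                           replicate_mode = c("average", "per_well"),
                           replicate_average = c("median", "mean"),
                           include_controls = FALSE,
                           mad_constant = 1.4826) {
  replicate_mode <- match.arg(replicate_mode)
  replicate_average <- match.arg(replicate_average)
  stainings <- staining %||% unique(summaries$staining)
  avg_fun <- if (replicate_average == "median") median else mean
  is_control_gene <- function(g) g %in% c("siCtrl", "ATG5", "ATG7")

  out <- list()
  for (st in stainings) {
    d <- summaries[summaries$staining == st & summaries$qc_pass &
                     summaries$treatment == "damaged", ]
    if (nrow(d) < 4) {
      stop_config("fewer than 4 QC-passing treated wells for staining %s", st)
    }
    d$sample <- paste(d$gene, d$reagent, sep = "|")
    x <- vapply(split(d[[summary_col]], d$sample), avg_fun, numeric(1))
    n_wells <- vapply(split(d[[summary_col]], d$sample), length, integer(1))
    genes <- vapply(strsplit(names(x), "\\|"), `[`, character(1), 1)
    reagents <- vapply(strsplit(names(x), "\\|"), `[`, character(1), 2)
    in_ref <- if (include_controls) rep(TRUE, length(x)) else
      !is_control_gene(genes)
    scale_of <- function(v) {
      med <- median(v)
      s <- mad_constant * median(abs(v - med))
      if (s == 0) {
        warning("plate MAD is zero; falling back to plate SD", call. = FALSE)
        s <- sd(v)
        if (is.na(s) || s == 0) {
          stop_config("plate SD is zero; z-scores undefined")
        }
      }
      list(center = med, scale = s)
    }
    if (replicate_mode == "average") {
      ref <- scale_of(x[in_ref])
      z <- (x - ref$center) / ref$scale
    } else {
      ref <- scale_of(d[[summary_col]][!is_control_gene(d$gene)])
      zw <- (d[[summary_col]] - ref$center) / ref$scale
      z <- vapply(split(zw, d$sample), median, numeric(1))[names(x)]
    }
    out[[st]] <- data.frame(
      gene = genes, reagent = reagents, staining = st,
      x = unname(x), robust_z = unname(z), n_wells = unname(n_wells)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicate_mode") <- replicate_mode
  attr(res, "replicate_average") <- replicate_average
  attr(res, "mad_constant") <- mad_constant
  res
}

#' Primary hit calling: significant reduction in one or both stainings
#'
#' A gene pool is a primary hit iff its robust z is at or below the
#' threshold (inclusive, default -2) in at least one staining.
#'
#' @param zscores long table from [robust_zscores()] (columns `gene`,
#'   `reagent`, `staining`, `robust_z`).
#' @param threshold inclusive hit threshold.
#' @return the input with `staining_hit` (per row) and `is_hit` (per gene,
#'   any staining), `stage = "primary"`.
#' @export
call_primary_hits <- function(zscores, threshold = -2) {
  stainings <- unique(zscores$staining)
  if (length(stainings) < 2) {
    warning("hit calling on a single staining (one expected per readout pair)",
            call. = FALSE)
  }
  zscores$staining_hit <- zscores$robust_z <= threshold
  gene_hit <- tapply(zscores$staining_hit, zscores$gene, any)
  zscores$is_hit <- as.logical(gene_hit[zscores$gene])
  zscores$stage <- "primary"
  attr(zscores, "threshold") <- threshold
  zscores
}

#' Secondary screen: deconvolve pools into single siRNAs
#'
#' A single siRNA scores iff its robust z is at or below the threshold in
#' BOTH stainings; a gene is confirmed iff at least `min_singles` of its
#' singles score.
#'
#' @param zscores long table from [robust_zscores()] on the singles plate.
#' @param threshold inclusive threshold per staining.
#' @param min_singles scoring singles required to confirm a gene.
#' @return data.frame per gene x reagent: per-staining z (wide columns
#'   `z_<staining>`), `single_scores`, `gene_confirmed`,
#'   `stage = "secondary"`.
#' @export
deconvolve_secondary <- function(zscores, threshold = -2, min_singles = 1) {
  stainings <- sort(unique(zscores$staining))
  wide <- stats::reshape(
    zscores[, c("gene", "reagent", "staining", "robust_z")],
    direction = "wide", idvar = c("gene", "reagent"),
    timevar = "staining", v.names = "robust_z"
  )
  names(wide) <- sub("^robust_z\\.", "z_", names(wide))
  zcols <- paste0("z_", stainings)
  wide$single_scores <- apply(wide[, zcols, drop = FALSE] <= threshold, 1,
                              function(r) all(!is.na(r)) && all(r))
  n_singles <- table(wide$gene)
  if (any(n_singles < 4)) {
    warning(sprintf("gene(s) with fewer than 4 singles: %s",
                    paste(names(n_singles)[n_singles < 4], collapse = ", ")),
            call. = FALSE)
  }
  confirmed <- tapply(wide$single_scores, wide$gene, sum) >= min_singles
  wide$gene_confirmed <- as.logical(confirmed[wide$gene])
  wide$stage <- "secondary"
  rownames(wide) <- NULL
  attr(wide, "threshold") <- threshold
  attr(wide, "min_singles") <- min_singles
  wide
}

#' One-way ANOVA with Bonferroni or Dunnett multiple comparisons
#'
#' Classic one-way analysis of variance followed by all-pairs t-tests with
#' Bonferroni adjustment, or comparisons against a control group with
#' Dunnett's multivariate-t adjustment. Both use the pooled ANOVA error.
#'
#' @param values numeric readouts.
#' @param groups group labels, same length.
#' @param method `"bonferroni"` (all pairs) or `"dunnett"` (vs control).
#' @param control control group label (Dunnett; default first level).
#' @return list: `anova` (one row: `F`, `df1`, `df2`, `p`),
#'   `comparisons` (per pair: estimate, t, adjusted p).
#' @export
compare_conditions <- function(values, groups,
                               method = c("bonferroni", "dunnett"),
                               control = NULL) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_config("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop_config("every group needs >= 2 values (offender: %s)",
                names(sizes)[which(sizes < 2)[1]])
  }
  fit <- stats::aov(values ~ groups)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  means <- tapply(values, groups, mean)
  lv <- levels(groups)

  if (method == "bonferroni") {
    pairs <- utils::combn(lv, 2)
    m <- ncol(pairs)
    comp <- do.call(rbind, lapply(seq_len(m), function(i) {
      a <- pairs[1, i]
      b <- pairs[2, i]
      se <- sqrt(mse * (1 / sizes[[a]] + 1 / sizes[[b]]))
      tval <- (means[[a]] - means[[b]]) / se
      p_raw <- 2 * pt(-abs(tval), df_err)
      data.frame(group_1 = a, group_2 = b,
                 estimate = means[[a]] - means[[b]], t = tval,
                 p_adjusted = min(1, m * p_raw))
    }))
  } else {
    control <- control %||% lv[1]
    if (!control %in% lv) stop_config("unknown control group %s", control)
    others <- setdiff(lv, control)
    k <- length(others)
    n0 <- sizes[[control]]
    lam <- vapply(others, function(g) {
      sqrt(sizes[[g]] / (sizes[[g]] + n0))
    }, numeric(1))
    corr <- outer(lam, lam)
    diag(corr) <- 1
    comp <- do.call(rbind, lapply(seq_len(k), function(i) {
      g <- others[i]
      se <- sqrt(mse * (1 / sizes[[g]] + 1 / n0))
      tval <- (means[[g]] - means[[control]]) / se
      p_adj <- 1 - with_seed(1L, mvtnorm::pmvt(
        lower = rep(-abs(tval), k), upper = rep(abs(tval), k),
        df = df_err, corr = corr,
        algorithm = mvtnorm::GenzBretz(abseps = 1e-8, maxpts = 100000L)))[1]
      data.frame(group_1 = g, group_2 = control,
                 estimate = means[[g]] - means[[control]], t = tval,
                 p_adjusted = min(1, max(0, p_adj)))
    }))
  }
  rownames(comp) <- NULL
  list(
    anova = data.frame(F = an[["F value"]][1], df1 = an[["Df"]][1],
                       df2 = df_err, p = an[["Pr(>F)"]][1]),
    comparisons = comp,
    method = method
  )
}

#' Screen report
#'
#' Gene-level table of robust z by staining and stage with hit flags, plus
#' recall and precision against planted true hits when ground truth is
#' supplied.
#'
#' @param primary output of [call_primary_hits()].
#' @param secondary optional output of [deconvolve_secondary()].
#' @param truth optional list with `true_hits` (gene labels).
#' @return list: `genes` (per-gene wide table), `recall`, `precision`
#'   (absent columns when no truth), `n_primary_hits`.
#' @export
screen_report <- function(primary, secondary = NULL, truth = NULL) {
  if (nrow(primary) == 0) {
    return(list(genes = data.frame(gene = character(0)),
                n_primary_hits = 0L))
  }
  wide <- stats::reshape(
    primary[, c("gene", "staining", "robust_z")],
    direction = "wide", idvar = "gene", timevar = "staining",
    v.names = "robust_z"
  )
  names(wide) <- sub("^robust_z\\.", "z_", names(wide))
  hit <- tapply(primary$is_hit, primary$gene, any)
  wide$primary_hit <- as.logical(hit[wide$gene])
  if (!is.null(secondary)) {
    conf <- tapply(secondary$gene_confirmed, secondary$gene, any)
    wide$secondary_confirmed <- as.logical(conf[wide$gene])
  }
  rownames(wide) <- NULL
  out <- list(genes = wide, n_primary_hits = sum(wide$primary_hit))
  if (!is.null(truth) && !is.null(truth$true_hits)) {
    called <- wide$gene[wide$primary_hit]
    tp <- length(intersect(called, truth$true_hits))
    out$recall <- if (length(truth$true_hits)) {
      tp / length(truth$true_hits)
    } else {
      NA_real_
    }
    out$precision <- if (length(called)) tp / length(called) else NA_real_
  }
  out
}
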