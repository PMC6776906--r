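# Comparative SILAC proximity-proteomics: contaminant/reverse/site-only
# filtering, per-replicate log2 H/L ratios (the 1:1 mixing design makes 0
# the null), one-sample enrichment t-tests, volcano classification at
# |log2 FC| >= 1.5 and p < 0.05, and replicate-agreement diagnostics.

#' Filter a protein-quantification table
#'
#' Removes rows flagged as common contaminants, reverse (decoy)
#' identifications, or identifications based only on modification sites,
#' and logs the count per reason (a doubly flagged row is removed once but
#' counted under each reason).
#'
#' @param table data.frame with logical `contaminant`, `reverse`,
#'   `site_only` columns.
#' @return list: `table` (filtered), `removal_log` (reason, n),
#'   `n_removed`.
#' @export
filter_quant_table <- function(table) {
  check_columns(table, c("contaminant", "reverse", "site_only"),
                "quant table")
  flagged <- table$contaminant | table$reverse | table$site_only
  removal_log <- data.frame(
    reason = c("contaminant", "reverse", "site_only"),
    n = c(sum(table$contaminant), sum(table$reverse), sum(table$site_only))
  )
  list(table = table[!flagged, , drop = FALSE],
       removal_log = removal_log,
       n_removed = sum(flagged))
}

#' Per-replicate and mean log2 H/L ratios
#'
#' A replicate contributes iff both its heavy and light intensities are
#' present and positive; replicates with a zero or missing channel are
#' skipped and counted (a zero light intensity with positive heavy would be
#' an infinite ratio and is excluded with a warning). Proteins with fewer
#' than `min_replicates` contributing replicates are dropped and counted.
#'
#' @param table filtered quantification table with `heavy_k` / `light_k`
#'   columns.
#' @param min_replicates minimum contributing replicates to retain a
#'   protein (default 2, the smallest n with a defined t-test).
#' @return data.frame: `protein_id`, `gene_symbol` (if present),
#'   `ratio_k` per replicate, `n_replicates_used`, `mean_log2`; attribute
#'   `n_dropped` counts proteins lost to the replicate gate.
#' @export
compute_log2_ratios <- function(table, min_replicates = 2) {
  hcols <- sort(grep("^heavy_", names(table), value = TRUE))
  lcols <- sort(grep("^light_", names(table), value = TRUE))
  if (length(hcols) == 0 || length(hcols) != length(lcols)) {
    stop_config("need matching heavy_<k> / light_<k> columns")
  }
  k <- length(hcols)
  ratios <- matrix(NA_real_, nrow(table), k)
  n_zero_light <- 0
  for (r in seq_len(k)) {
    h <- table[[hcols[r]]]
    l <- table[[lcols[r]]]
    ok <- !is.na(h) & !is.na(l) & h > 0 & l > 0
    n_zero_light <- n_zero_light + sum(!is.na(h) & h > 0 & !is.na(l) & l == 0)
    ratios[ok, r] <- log2(h[ok] / l[ok])
  }
  if (n_zero_light > 0) {
    warning(sprintf("%d replicate measurement(s) with zero light intensity excluded",
                    n_zero_light), call. = FALSE)
  }
  n_used <- rowSums(!is.na(ratios))
  keep <- n_used >= min_replicates
  out <- data.frame(protein_id = table$protein_id[keep])
  if ("gene_symbol" %in% names(table)) {
    out$gene_symbol <- table$gene_symbol[keep]
  }
  for (r in seq_len(k)) out[[sprintf("ratio_%d", r)]] <- ratios[keep, r]
  out$n_replicates_used <- n_used[keep]
  out$mean_log2 <- rowMeans(ratios[keep, , drop = FALSE], na.rm = TRUE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' One-sample enrichment t-test against the 1:1 mixing null
#'
#' Two-sided Student's t-test of each protein's per-replicate log2 H/L
#' ratios against 0, with n - 1 degrees of freedom. Zero-variance proteins
#' are flagged `degenerate`: with nonzero mean the p-value is reported as
#' the zero-variance limit 0 (never silently), with zero mean it is
#' undefined (NA) and the protein cannot be called enriched.
#'
#' @param ratios data.frame from [compute_log2_ratios()] (or a numeric
#'   matrix of per-replicate log2 ratios).
#' @return data.frame: `protein_id`, `t`, `df`, `p_value`, `degenerate`.
#' @export
test_enrichment <- function(ratios) {
  if (is.data.frame(ratios)) {
    mat <- as.matrix(ratios[, grep("^ratio_", names(ratios)), drop = FALSE])
    ids <- ratios$protein_id
  } else {
    mat <- as.matrix(ratios)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  n <- rowSums(!is.na(mat))
  if (any(n < 2)) stop_config("every protein needs >= 2 contributing replicates")
  m <- rowMeans(mat, na.rm = TRUE)
  s <- apply(mat, 1, sd, na.rm = TRUE)
  tval <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tval), df = n - 1)
  degenerate <- s == 0
  p[degenerate & m != 0] <- 0
  p[degenerate & m == 0] <- NA_real_
  tval[degenerate] <- NA_real_
  data.frame(protein_id = ids, t = tval, df = n - 1, p_value = p,
             degenerate = degenerate)
}

#' Volcano classification at joint fold-change and significance gates
#'
#' `enriched_heavy` iff mean log2 H/L >= `fc_cut` and p < `p_cut`;
#' `depleted_heavy` symmetrically at <= -`fc_cut`; otherwise
#' `not_significant`. The fold-change boundary is inclusive and the p
#' boundary exclusive; an undefined p (degenerate zero-mean protein) is
#' never significant.
#'
#' @param mean_log2 numeric vector of mean log2 H/L.
#' @param p numeric vector of p-values.
#' @param fc_cut fold-change cut on the log2 scale (default 1.5).
#' @param p_cut significance cut (default 0.05).
#' @return factor with levels `enriched_heavy`, `depleted_heavy`,
#'   `not_significant`, plus `passes_fc` / `passes_p` attributes.
#' @export
classify_volcano <- function(mean_log2, p, fc_cut = 1.5, p_cut = 0.05) {
  stopifnot(length(mean_log2) == length(p))
  passes_fc <- abs(mean_log2) >= fc_cut
  passes_p <- !is.na(p) & p < p_cut
  cls <- rep("not_significant", length(p))
  cls[passes_fc & passes_p & mean_log2 >= fc_cut] <- "enriched_heavy"
  cls[passes_fc & passes_p & mean_log2 <= -fc_cut] <- "depleted_heavy"
  structure(factor(cls, levels = c("enriched_heavy", "depleted_heavy",
                                   "not_significant")),
            passes_fc = passes_fc, passes_p = passes_p)
}

#' Replicate agreement: pairwise correlations and Venn overlap counts
#'
#' Pearson correlation of per-replicate log2 ratios over proteins detected
#' in both members of each pair (undefined and flagged when fewer than two
#' common proteins), plus the cardinality of every exclusive region of the
#' detection-set Venn diagram.
#'
#' @param ratios data.frame from [compute_log2_ratios()] run with
#'   `min_replicates = 1` if full detection sets are wanted.
#' @return list: `correlations` (k x k matrix, NA where undefined),
#'   `pairs` (long table with `n_common`), `venn` (data.frame `region`,
#'   e.g. `"1&3"`, and `count`), `detected_per_replicate`.
#' @export
replicate_agreement <- function(ratios) {
  mat <- as.matrix(ratios[, grep("^ratio_", names(ratios)), drop = FALSE])
  k <- ncol(mat)
  if (k < 2) stop_config("need >= 2 replicates")
  cors <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  diag(cors) <- 1
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      both <- !is.na(mat[, i]) & !is.na(mat[, j])
      r <- if (sum(both) >= 2 && sd(mat[both, i]) > 0 && sd(mat[both, j]) > 0) {
        stats::cor(mat[both, i], mat[both, j])
      } else {
        NA_real_
      }
      cors[i, j] <- cors[j, i] <- r
      pairs[[length(pairs) + 1]] <- data.frame(
        replicate_1 = i, replicate_2 = j, n_common = sum(both),
        correlation = r, defined = !is.na(r)
      )
    }
  }
  detected <- !is.na(mat)
  patterns <- apply(detected, 1, function(d) {
    paste(which(d), collapse = "&")
  })
  patterns <- patterns[patterns != ""]
  venn <- as.data.frame(table(patterns), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  list(correlations = cors,
       pairs = do.call(rbind, pairs),
       venn = venn,
       detected_per_replicate = colSums(detected))
}

#' Full volcano analysis of a quantification table
#'
#' Convenience pipeline: filter flagged rows, compute log2 H/L ratios, test
#' enrichment, classify. The per-protein FDR column (Benjamini-Hochberg) is
#' informational only; the classification uses the unadjusted per-protein
#' p, matching the stated decision rule.
#'
#' @param table raw quantification table (see [read_quant_table()] /
#'   [generate_silac_dataset()]).
#' @param min_replicates minimum contributing replicates per protein.
#' @param fc_cut,p_cut volcano gates.
#' @return list: `results` (per protein: mean log2, p, fdr, class),
#'   `removal_log`, `n_removed`, `n_dropped`.
#' @export
volcano_analysis <- function(table, min_replicates = 2,
                             fc_cut = 1.5, p_cut = 0.05) {
  filt <- filter_quant_table(table)
  ratios <- compute_log2_ratios(filt$table, min_replicates = min_replicates)
  tests <- test_enrichment(ratios)
  cls <- classify_volcano(ratios$mean_log2, tests$p_value,
                          fc_cut = fc_cut, p_cut = p_cut)
  results <- data.frame(
    protein_id = ratios$protein_id,
    n_replicates_used = ratios$n_replicates_used,
    mean_log2 = ratios$mean_log2,
    t = tests$t,
    p_value = tests$p_value,
    fdr = stats::p.adjust(tests$p_value, "BH"),
    degenerate = tests$degenerate,
    class = cls,
    passes_fc = attr(cls, "passes_fc"),
    passes_p = attr(cls, "passes_p")
  )
  list(results = results, removal_log = filt$removal_log,
       n_removed = filt$n_removed, n_dropped = attr(ratios, "n_dropped"))
}
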