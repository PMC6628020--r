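#' Pipeline configuration
#'
#' @param min_samples Minimum total samples for a study to enter the
#'   meta-analysis (default 30, the usual inclusion floor for cohort
#'   screening).
#' @param threshold Classification probability cutoff (default 0.5).
#' @param model Pooling model for ratio indices, "random" or "fixed".
#' @param sroc_weighted Inverse-variance weighting for the Moses fit.
#' @param correction Continuity-correction constant for zero cells.
#' @param normalize Apply log-standardisation + quantile normalisation per
#'   study before classification.
#' @param on_missing_gene "drop" the study for that gene (with a warning) or
#'   "fail".
#' @return A named list of settings.
#' @export
pipeline_config <- function(min_samples = 30L, threshold = 0.5,
                            model = c("random", "fixed"),
                            sroc_weighted = TRUE, correction = 0.5,
                            normalize = TRUE,
                            on_missing_gene = c("drop", "fail")) {
  list(min_samples = min_samples, threshold = threshold,
       model = match.arg(model), sroc_weighted = sroc_weighted,
       correction = correction, normalize = normalize,
       on_missing_gene = match.arg(on_missing_gene))
}

#' Full diagnostic meta-analysis of a set of 2x2 tables
#'
#' The core reporting stage: per-study indices, pooled sensitivity and
#' specificity (aggregate proportions), random-effects pooled PLR/NLR/DOR,
#' and the Moses-Littenberg SROC with AUC and Q*. The headline I2 is the one
#' from the sensitivity pooling (I2 < 50% is conventionally read as small
#' heterogeneity).
#'
#' @param tables List of `confusion_table` objects.
#' @param model "random" or "fixed" for the ratio indices.
#' @param sroc_weighted Weighting of the Moses fit.
#' @param correction Zero-cell continuity-correction constant.
#' @return A `dta_report`: list with `indices`, `pooled` (named list of
#'   `pooled_result`), `sroc` (`sroc_model`), and `summary` (one-row
#'   data.frame: sens, spec, plr, nlr, dor, auc, q_star, i2).
#' @export
dta_report <- function(tables, model = "random", sroc_weighted = TRUE,
                       correction = 0.5) {
  indices <- lapply(tables, study_indices, correction = correction)
  pooled <- list(
    sens = pool_proportion(tables, "sens"),
    spec = pool_proportion(tables, "spec"),
    plr = pool_log_ratio(indices, "plr", model = model),
    nlr = pool_log_ratio(indices, "nlr", model = model),
    dor = pool_log_ratio(indices, "dor", model = model))
  sroc <- fit_moses(indices, weighted = sroc_weighted)
  summary <- data.frame(
    sens = pooled$sens$estimate, spec = pooled$spec$estimate,
    plr = pooled$plr$estimate, nlr = pooled$nlr$estimate,
    dor = pooled$dor$estimate, auc = sroc$auc, q_star = sroc$q_star,
    i2 = pooled$sens$i2)
  structure(list(indices = indices, pooled = pooled, sroc = sroc,
                 summary = summary),
            class = "dta_report")
}

#' @export
print.dta_report <- function(x, ...) {
  cat("Diagnostic meta-analysis of", length(x$indices), "studies\n")
  for (p in x$pooled) print(p)
  print(x$sroc)
  invisible(x)
}

normalize_study <- function(s) {
  s$expr <- quantile_normalize(log_standardize(s$expr))
  s
}

#' Run the end-to-end biomarker comparison pipeline
#'
#' Per gene: normalise each study (log2 standardisation + quantile
#' normalisation), fit the per-study logistic classifier, derive 2x2 tables,
#' and pool them into one report row (sens, spec, PLR, NLR, DOR, AUC, Q*,
#' I2) — the comparison-table layout for ranking candidate biomarkers over a
#' common study set.
#'
#' @param set A `study_set`.
#' @param genes Character vector of genes to score.
#' @param config A [pipeline_config()].
#' @return A data.frame, one row per gene, ordered as `genes`.
#' @export
run_pipeline <- function(set, genes, config = pipeline_config()) {
  stopifnot(inherits(set, "study_set"))
  keep <- vapply(set$studies, function(s) ncol(s$expr) >= config$min_samples,
                 logical(1L))
  if (any(!keep)) {
    dropped <- vapply(set$studies[!keep], `[[`, character(1L), "study_id")
    message("excluding ", sum(!keep), " study(ies) under min_samples = ",
            config$min_samples, ": ", paste(dropped, collapse = ", "))
  }
  studies <- set$studies[keep]
  if (length(studies) < 2L) stop("fewer than 2 eligible studies")
  if (config$normalize) {
    studies <- lapply(studies, function(s) suppressMessages(normalize_study(s)))
  }
  rows <- lapply(genes, function(g) {
    have <- vapply(studies, function(s) g %in% rownames(s$expr), logical(1L))
    if (!all(have)) {
      if (config$on_missing_gene == "fail") {
        stop("gene '", g, "' missing from study(ies): ",
             paste(vapply(studies[!have], `[[`, character(1L), "study_id"),
                   collapse = ", "))
      }
      warning("gene '", g, "' missing from ", sum(!have),
              " study(ies); they are dropped for this gene")
    }
    used <- studies[have]
    if (length(used) < 2L) stop("gene '", g, "' present in fewer than 2 studies")
    tables <- lapply(used, function(s) {
      classify_study(s$expr, s$phenotype, g,
                     threshold = config$threshold, study_id = s$study_id)
    })
    rep <- dta_report(tables, model = config$model,
                      sroc_weighted = config$sroc_weighted,
                      correction = config$correction)
    cbind(data.frame(gene = g, n_studies = length(used),
                     stringsAsFactors = FALSE),
          rep$summary)
  })
  do.call(rbind, rows)
}

#' Per-study, per-group five-number expression summaries
#'
#' Boxplot-ready quartile tables (min, Q1, median, Q3, max) of one gene's
#' expression for cases and controls in every study.
#'
#' @param set A `study_set`.
#' @param gene Gene identifier.
#' @return A data.frame with one row per study x group.
#' @export
group_summaries <- function(set, gene) {
  stopifnot(inherits(set, "study_set"))
  rows <- lapply(set$studies, function(s) {
    if (!gene %in% rownames(s$expr)) {
      stop("gene '", gene, "' absent from study '", s$study_id, "'")
    }
    do.call(rbind, lapply(c("case", "control"), function(grp) {
      x <- s$expr[gene, s$phenotype$sample[s$phenotype$group == grp]]
      q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(study_id = s$study_id, group = grp,
                 min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank genes by expression similarity to a target gene
#'
#' Pearson correlation of every other gene with `target_gene` across samples,
#' computed within each study and averaged (unweighted) across the studies
#' containing both genes; genes are ranked by decreasing r with ties broken
#' by gene id. Zero-variance genes are excluded with a warning.
#'
#' @param x A `study_set` or a single expression matrix.
#' @param target_gene Gene to compare against.
#' @param k Number of top genes to return (default all).
#' @return A data.frame (gene, r), ranked.
#' @export
similar_genes <- function(x, target_gene, k = Inf) {
  mats <- if (inherits(x, "study_set")) {
    lapply(x$studies, `[[`, "expr")
  } else {
    list(x)
  }
  per_study <- list()
  dropped <- character(0)
  for (m in mats) {
    if (!target_gene %in% rownames(m)) next
    if (ncol(m) < 3L) stop("similarity needs at least 3 samples per study")
    target <- m[target_gene, ]
    if (stats::sd(target) == 0) stop("target gene has zero variance")
    others <- setdiff(rownames(m), target_gene)
    sds <- apply(m[others, , drop = FALSE], 1L, stats::sd)
    dropped <- union(dropped, others[sds == 0])
    ok <- others[sds > 0]
    r <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), target))
    per_study[[length(per_study) + 1L]] <- stats::setNames(r, ok)
  }
  if (!length(per_study)) stop("target gene '", target_gene, "' not found")
  if (length(dropped)) {
    warning("excluding ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  genes <- sort(unique(unlist(lapply(per_study, names))))
  genes <- setdiff(genes, dropped)
  r_bar <- vapply(genes, function(g) {
    vals <- unlist(lapply(per_study, function(v) v[g]))
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  ord <- order(-r_bar, genes)
  out <- data.frame(gene = genes[ord], r = unname(r_bar[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}
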