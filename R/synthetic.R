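#' Specify one synthetic case/control expression study
#'
#' Defines the sampling model for a single cohort: log2 intensities are
#' Gaussian with a study-level baseline; the marker gene is shifted by
#' `marker_shift` in cases (negative = down-regulated, as for CHGA in early
#' colon cancer) while noise genes share one distribution in both groups.
#'
#' @param study_id Study label.
#' @param n_case,n_control Group sizes (n_case + n_control >= 1).
#' @param baseline_mean Study baseline, log2-intensity units.
#' @param baseline_sd Within-gene standard deviation, log2 units (> 0).
#' @param marker_shift Case-minus-control mean difference of the marker gene,
#'   log2 units. The default -2.5 puts the expected resubstitution
#'   sensitivity/specificity near 0.89 (`pnorm(2.5/2)`), the operating point
#'   of the CHGA cohorts.
#' @param n_noise_genes Number of unassociated genes (>= 0).
#' @param seed Integer seed; identical spec + seed gives bit-identical data.
#' @return A `study_spec` object.
#' @export
study_spec <- function(study_id, n_case, n_control,
                       baseline_mean = 8, baseline_sd = 1,
                       marker_shift = -2.5, n_noise_genes = 50,
                       seed = 1L) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!is.numeric(n_case) || !is.numeric(n_control) ||
      n_case < 0 || n_control < 0 || n_case + n_control < 1 ||
      n_case != round(n_case) || n_control != round(n_control)) {
    stop("n_case and n_control must be non-negative integers with n_case + n_control >= 1")
  }
  if (!is.numeric(baseline_sd) || baseline_sd <= 0) {
    stop("baseline_sd must be a positive real")
  }
  if (n_noise_genes < 0 || n_noise_genes != round(n_noise_genes)) {
    stop("n_noise_genes must be a non-negative integer")
  }
  structure(
    list(study_id = study_id, n_case = as.integer(n_case),
         n_control = as.integer(n_control),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         marker_shift = marker_shift,
         n_noise_genes = as.integer(n_noise_genes),
         seed = as.integer(seed)),
    class = "study_spec")
}

# Run code under a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate one synthetic study
#'
#' Draws the marker gene Normal(baseline_mean + marker_shift, baseline_sd)
#' in cases and Normal(baseline_mean, baseline_sd) in controls; each noise
#' gene gets its own mean (drawn once per gene) and is identically
#' distributed in both groups.
#'
#' @param spec A [study_spec()].
#' @param marker_gene Marker gene identifier (default "CHGA").
#' @param case_samples Optional pre-generated case block (matrix of marker +
#'   noise rows) to share one case cohort across several control arms.
#' @return A list with elements `study_id`, `expr` (genes x samples matrix)
#'   and `phenotype` (data.frame sample/group/stage).
#' @export
generate_study <- function(spec, marker_gene = "CHGA", case_samples = NULL) {
  stopifnot(inherits(spec, "study_spec"))
  n_genes <- spec$n_noise_genes + 1L
  gene_ids <- c(marker_gene, sprintf("NOISE%03d", seq_len(spec$n_noise_genes)))
  with_seed(spec$seed, {
    noise_means <- stats::rnorm(spec$n_noise_genes, spec$baseline_mean, 1)
    gene_means <- c(spec$baseline_mean, noise_means)
    draw_block <- function(n, shift_marker) {
      mu <- gene_means
      if (shift_marker) mu[1L] <- mu[1L] + spec$marker_shift
      matrix(stats::rnorm(n_genes * n, mean = mu, sd = spec$baseline_sd),
             nrow = n_genes)
    }
    case_block <- if (is.null(case_samples)) {
      draw_block(spec$n_case, shift_marker = TRUE)
    } else {
      stopifnot(nrow(case_samples) == n_genes)
      unname(case_samples)
    }
    control_block <- draw_block(spec$n_control, shift_marker = FALSE)
    expr <- cbind(case_block, control_block)
    rownames(expr) <- gene_ids
    colnames(expr) <- if (is.null(case_samples)) {
      c(sprintf("%s_case_%03d", spec$study_id, seq_len(spec$n_case)),
        sprintf("%s_ctrl_%03d", spec$study_id, seq_len(spec$n_control)))
    } else {
      c(colnames(case_samples),
        sprintf("%s_ctrl_%03d", spec$study_id, seq_len(spec$n_control)))
    }
    phenotype <- data.frame(
      sample = colnames(expr),
      group = rep(c("case", "control"), c(spec$n_case, spec$n_control)),
      stage = rep(c("early", "normal"), c(spec$n_case, spec$n_control)),
      stringsAsFactors = FALSE)
    list(study_id = spec$study_id, expr = expr, phenotype = phenotype)
  })
}

#' Bundle studies into a study set
#'
#' @param studies List of study entries as returned by [generate_study()].
#' @param marker_gene Marker gene identifier present in every study.
#' @return A `study_set` object.
#' @export
study_set <- function(studies, marker_gene) {
  for (s in studies) {
    stopifnot(is.matrix(s$expr), is.data.frame(s$phenotype))
    if (!setequal(colnames(s$expr), s$phenotype$sample) ||
        ncol(s$expr) != nrow(s$phenotype)) {
      stop("study ", s$study_id, ": samples and phenotype table disagree")
    }
    if (anyDuplicated(rownames(s$expr))) {
      stop("study ", s$study_id, ": duplicated gene ids")
    }
  }
  structure(list(studies = studies, marker_gene = marker_gene),
            class = "study_set")
}

#' Generate the five-cohort CHGA-like study set
#'
#' Emulates the four GEO colon-cancer cohorts used in the CHGA screening
#' analysis: GSE44076 (98 early-stage patients with 148 controls split into
#' 50 healthy and 98 adjacent-mucosa samples, yielding two analysis entries
#' that share the case arm), GSE74602 (30/30), GSE10972 (24/24) and GSE23878
#' (35/24) — 187 distinct cases and 226 distinct controls over five analysis
#' entries. Marker shifts are moderate so classification errors are nonzero.
#'
#' @param seed Global integer seed; per-study child seeds are derived by
#'   fixed arithmetic so adding a study never perturbs earlier ones.
#' @param marker_shift Case shift of the marker gene, log2 units.
#' @param n_noise_genes Noise genes per study.
#' @return A `study_set` with five entries and `marker_gene = "CHGA"`.
#' @export
generate_chga_cohorts <- function(seed = 1L, marker_shift = -2.5,
                                   n_noise_genes = 50L) {
  child <- function(i) as.integer((as.double(seed) * 101 + 7919 * i) %% 2147483647)
  mk <- function(id, ncase, nctrl, i, base) {
    study_spec(id, ncase, nctrl, baseline_mean = base, baseline_sd = 1,
               marker_shift = marker_shift, n_noise_genes = n_noise_genes,
               seed = child(i))
  }
  # study-specific baselines stand in for platform differences
  bases <- c(8, 7, 9, 6.5)
  # one GSE44076 cohort (98 cases, 50 healthy + 98 mucosa controls),
  # analysed as two entries that share the case arm and the gene means
  s0 <- generate_study(mk("GSE44076", 98L, 148L, 1L, bases[1]))
  take <- function(entry_id, ctrl_idx) {
    ctrl <- which(s0$phenotype$group == "control")[ctrl_idx]
    keep <- c(which(s0$phenotype$group == "case"), ctrl)
    list(study_id = entry_id,
         expr = s0$expr[, keep, drop = FALSE],
         phenotype = s0$phenotype[keep, , drop = FALSE])
  }
  s1 <- take("GSE44076_healthy", 1:50)
  s2 <- take("GSE44076_mucosa", 51:148)
  s3 <- generate_study(mk("GSE74602", 30L, 30L, 3L, bases[2]))
  s4 <- generate_study(mk("GSE10972", 24L, 24L, 4L, bases[3]))
  s5 <- generate_study(mk("GSE23878", 35L, 24L, 5L, bases[4]))
  study_set(list(s1, s2, s3, s4, s5), marker_gene = "CHGA")
}

#' Write a study set to a directory as TSV files
#'
#' One `<study_id>_expr.tsv` and `<study_id>_pheno.tsv` pair per study;
#' round-trips through [read_expression()] / [read_phenotype()].
#'
#' @param set A `study_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_set <- function(set, dir) {
  stopifnot(inherits(set, "study_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in set$studies) {
    write_expression(s$expr, file.path(dir, paste0(s$study_id, "_expr.tsv")))
    write_phenotype(s$phenotype, file.path(dir, paste0(s$study_id, "_pheno.tsv")))
  }
  invisible(dir)
}
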