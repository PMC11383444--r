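#' Specification for a synthetic multimodal cohort
#'
#' Bundles every knob of the generative model behind [generate_cohort()]:
#' a community-structured correlation for the BOLD signals (within-block
#' correlation `rho_in` above the between-block `rho_out`, per-subject
#' jitter, per-ROI AR(1) coefficients spread over `ar_range` so intrinsic
#' timescales genuinely vary by region), block-modulated Poisson streamline
#' counts, log-normal gray-matter volumes and morphology columns, and a
#' target built from a planted within-block edge set plus a planted subset
#' of informative morphology columns.
#'
#' @param n_subjects Cohort size.
#' @param q Number of ROIs.
#' @param n_blocks Number of communities (blocks).
#' @param t_len Time points per BOLD run.
#' @param tr Repetition time in seconds.
#' @param rho_in,rho_out Within/between-block BOLD correlation.
#' @param jitter_sd SD of the per-subject symmetric jitter on the
#'   correlation matrix.
#' @param ar_range Range of the per-ROI AR(1) coefficients.
#' @param planted_edge_fraction Fraction of within-block pairs planted as
#'   predictive edges.
#' @param n_informative_as Number of morphology columns carrying signal.
#' @param beta_edge,beta_as Effect sizes (SD units) of the edge and
#'   anatomical components of the target.
#' @param noise_sd SD of the target noise.
#' @param sc_rate_in,sc_rate_out Poisson streamline rates within/between
#'   blocks.
#' @param extreme_quantiles NULL for a median split of the target when
#'   labelling, or `c(lo, hi)` quantiles for an extreme-group design
#'   (subjects between the quantiles get an NA label).
#' @param seed Master seed; all randomness in the generator flows from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 300, q = 40, n_blocks = 4,
                           t_len = 400, tr = 0.72,
                           rho_in = 0.5, rho_out = 0.1, jitter_sd = 0.05,
                           ar_range = c(0, 0.6),
                           planted_edge_fraction = 0.05,
                           n_informative_as = 3,
                           beta_edge = 1, beta_as = 1, noise_sd = 1,
                           sc_rate_in = 30, sc_rate_out = 0.5,
                           extreme_quantiles = NULL, seed = 1) {
  stopifnot(q >= 2, n_blocks >= 1, n_blocks <= q, t_len >= 3, tr > 0,
            planted_edge_fraction > 0, planted_edge_fraction < 1,
            n_informative_as >= 0, n_informative_as <= 9,
            noise_sd >= 0, n_subjects >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Projection of a jittered correlation matrix back to a valid (PD)
# correlation matrix; only invoked when the jitter broke definiteness.
project_correlation <- function(r, tol = 1e-8) {
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > tol) return(r)
  out <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
  ev2 <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) <= 0)
    stop("project_correlation: projection failed to restore definiteness")
  out
}

# Stationary correlation implied by AR(1) dynamics x_t = phi x_{t-1} + e_t
# with innovation correlation R: corr_ij = R_ij sqrt((1-phi_i^2)(1-phi_j^2))
#                                          / (1 - phi_i phi_j).
stationary_correlation <- function(r, phi) {
  s <- sqrt(1 - phi^2)
  r * outer(s, s) / (1 - outer(phi, phi))
}

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Implements the fixed generative model documented in [synthetic_spec()]:
#' block-structured per-subject BOLD correlations (jittered and, when
#' needed, projected back to a valid correlation matrix), AR(1) time series
#' driven by correlated innovations, block-modulated Poisson streamline
#' counts (symmetric, zero diagonal), log-normal gray-matter volumes and
#' morphology columns, and a target
#' `y = beta_edge * z(edge component) + beta_as * z(AS component) + noise`,
#' where the edge component sums `FC_ij * SC_ij` (scaled FC, normalized SC)
#' over the planted within-block edge set and the AS component sums the
#' per-subject means of the scaled informative morphology columns. The two
#' components are standardized across the cohort so the betas are effect
#' sizes in SD units. Binary labels come from a median split of `y`, or
#' from extreme-group quantiles when configured.
#'
#' @param spec A `synthetic_spec`.
#' @return Object of class `maskgnn_cohort`: per-subject raw data plus a
#'   `truth` element (planted edge set, informative columns, coefficients,
#'   block assignment).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  q <- spec$q
  blocks <- sort(rep_len(seq_len(spec$n_blocks), q))
  same_block <- outer(blocks, blocks, "==")

  r0 <- matrix(spec$rho_out, q, q)
  r0[same_block] <- spec$rho_in
  diag(r0) <- 1

  phi <- seq(spec$ar_range[1], spec$ar_range[2], length.out = q)

  # planted predictive edges: a fraction of the within-block pairs
  wb <- which(same_block & upper.tri(same_block), arr.ind = TRUE)
  n_plant <- max(1L, round(spec$planted_edge_fraction * nrow(wb)))
  planted <- wb[sample.int(nrow(wb), n_plant), , drop = FALSE]
  colnames(planted) <- c("i", "j")

  informative <- if (spec$n_informative_as > 0)
    sort(sample.int(9, spec$n_informative_as)) else integer(0)

  morph_names <- morphology_columns()
  morph_mu <- c(7, 6.4, 8.5, 1, 0.3, -1.2, -2.5, 0.5, 0.8)
  roi_profile <- matrix(stats::rnorm(q * 9, 0, 0.3), q, 9)  # fixed ROI shape
  contrast_rois <- seq_len(max(1L, floor(q / 4)))           # where subject contrast lives

  burn <- 200L
  subjects <- vector("list", spec$n_subjects)
  edge_comp <- numeric(spec$n_subjects)
  as_comp <- numeric(spec$n_subjects)

  for (s in seq_len(spec$n_subjects)) {
    jit <- matrix(stats::rnorm(q * q, 0, spec$jitter_sd), q, q)
    jit <- (jit + t(jit)) / 2
    diag(jit) <- 0
    rs <- project_correlation(r0 + jit)

    innov <- matrix(stats::rnorm((spec$t_len + burn) * q), ncol = q) %*% chol(rs)
    ts <- vapply(seq_len(q), function(v)
      as.numeric(stats::filter(innov[, v], phi[v], method = "recursive")),
      numeric(spec$t_len + burn))
    ts <- ts[(burn + 1):(burn + spec$t_len), , drop = FALSE]

    rate <- ifelse(same_block, spec$sc_rate_in, spec$sc_rate_out)
    rate <- rate * stats::rgamma(1, shape = 20, rate = 20)  # subject factor
    sc <- matrix(0, q, q)
    ut <- upper.tri(sc)
    sc[ut] <- stats::rpois(sum(ut), rate[ut])
    sc <- sc + t(sc)

    gm <- stats::rlnorm(q, meanlog = morph_mu[3], sdlog = 0.2)
    u <- stats::rnorm(9)  # subject-level contrast per morphology column
    logm <- matrix(morph_mu, q, 9, byrow = TRUE) + roi_profile +
      matrix(stats::rnorm(q * 9, 0, 0.15), q, 9)
    logm[contrast_rois, ] <- logm[contrast_rois, ] +
      matrix(0.4 * u, length(contrast_rois), 9, byrow = TRUE)
    morph <- exp(logm)
    morph[, 3] <- gm  # same volumes that normalize SC
    colnames(morph) <- morph_names

    fc_scaled <- minmax_scale(compute_fc(ts)$values)
    sc_norm <- normalize_sc(connectivity(sc, "SC"), gm)$values
    as_scaled <- scale_anatomical(morph)

    edge_comp[s] <- sum(fc_scaled[planted] * sc_norm[planted])
    as_comp[s] <- if (length(informative) > 0)
      sum(colMeans(as_scaled[, informative, drop = FALSE])) else 0

    subjects[[s]] <- list(
      id = sprintf("sub%04d", s),
      ts = roi_timeseries(ts, tr = spec$tr),
      sc_raw = sc,
      gm_volumes = gm,
      morphology = morph,
      fc_true = stationary_correlation(rs, phi))
  }

  zs <- function(x) {
    if (length(x) < 2 || !isTRUE(stats::sd(x) > 0)) return(x * 0)
    (x - mean(x)) / stats::sd(x)
  }
  y <- spec$beta_edge * zs(edge_comp) +
    spec$beta_as * zs(as_comp) +
    stats::rnorm(spec$n_subjects, 0, spec$noise_sd)

  label <- if (is.null(spec$extreme_quantiles)) {
    ifelse(y > stats::median(y), 2L, 1L)
  } else {
    qs <- stats::quantile(y, spec$extreme_quantiles)
    ifelse(y <= qs[1], 1L, ifelse(y >= qs[2], 2L, NA_integer_))
  }
  for (s in seq_len(spec$n_subjects)) {
    subjects[[s]]$y <- y[s]
    subjects[[s]]$label <- label[s]
  }

  structure(list(
    subjects = subjects, n = spec$n_subjects, q = q,
    roi_ids = paste0("ROI", seq_len(q)), spec = spec,
    truth = list(planted_edges = planted, informative_cols = informative,
                 beta_edge = spec$beta_edge, beta_as = spec$beta_as,
                 blocks = blocks, phi = phi)
  ), class = "maskgnn_cohort")
}

#' @export
#' @method print maskgnn_cohort
print.maskgnn_cohort <- function(x, ...) {
  cat(sprintf("<maskgnn_cohort> %d subjects, Q = %d ROIs", x$n, x$q))
  if (!is.null(x$truth))
    cat(sprintf(", %d planted edges, %d informative AS columns",
                nrow(x$truth$planted_edges), length(x$truth$informative_cols)))
  cat("\n")
  invisible(x)
}

#' Derive model-ready features for every subject of a cohort
#'
#' Runs the full feature pipeline per subject: Pearson FC (min-max scaled),
#' volume-normalized SC, intrinsic neural timescales, structure-function
#' coupling, and the scaled 11-column anatomical table.
#'
#' @param cohort A `maskgnn_cohort` (from [generate_cohort()] or
#'   [load_cohort()]).
#' @return The cohort with a `features` list added (per subject:
#'   `fc_scaled`, `sc_norm`, `as_table`, `int`, `coupling`).
#' @export
featurize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "maskgnn_cohort"))
  cohort$features <- lapply(cohort$subjects, function(su) {
    fc <- if (!is.null(su$ts)) compute_fc(su$ts) else NULL
    fc_scaled <- if (!is.null(fc)) minmax_scale(fc$values) else su$fc_scaled
    sc_norm <- if (!is.null(su$sc_raw))
      normalize_sc(connectivity(su$sc_raw, "SC"), su$gm_volumes)$values
    else su$sc_norm
    int_vec <- if (!is.null(su$ts)) compute_int(su$ts) else NULL
    coup <- if (!is.null(sc_norm) && !is.null(fc))
      compute_coupling(sc_norm, fc$values) else NULL
    as_table <- if (!is.null(su$morphology) && !is.null(int_vec))
      assemble_as(su$morphology, int_vec, coup) else NULL
    list(fc_scaled = fc_scaled, sc_norm = sc_norm,
         as_table = as_table, int = int_vec, coupling = coup)
  })
  cohort
}
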