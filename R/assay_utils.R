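# Closed-form single-construct assay computations: gel densitometry,
# qPCR normalization, flow-cytometry relative fluorescence with gating,
# and the one-site equilibrium binding model.

#' Fraction cleaved from gel band intensities
#'
#' Band intensities are background-subtracted and normalized per nucleotide
#' (stain signal scales with fragment length):
#'   n_c = (I_cleaved - I_bg) / length_cleaved,
#'   n_u = (I_uncleaved - I_bg) / length_uncleaved,
#'   fraction cleaved = n_c / (n_c + n_u).
#'
#' @param i_cleaved,i_uncleaved,i_background band intensities (arbitrary
#'   units; background must not exceed either band).
#' @param length_cleaved,length_uncleaved fragment lengths in nt.
#' @return list with `fraction_cleaved` and `fraction_uncleaved`
#'   (complementary by construction).
#' @export
fraction_cleaved <- function(i_cleaved, i_uncleaved, i_background,
                             length_cleaved, length_uncleaved) {
  stopifnot(length_cleaved > 0, length_uncleaved > 0,
            i_background <= i_cleaved, i_background <= i_uncleaved)
  n_c <- (i_cleaved - i_background) / length_cleaved
  n_u <- (i_uncleaved - i_background) / length_uncleaved
  if (n_c + n_u == 0) stop("both normalized band intensities are zero")
  f <- n_c / (n_c + n_u)
  list(fraction_cleaved = f, fraction_uncleaved = 1 - f)
}

#' Ligand-dependent fold change in cleavage
#'
#' Ratios of the cleaved and uncleaved fractions with vs without ligand.
#'
#' @param f_with,f_without fraction cleaved with / without ligand, in [0, 1].
#' @return list with `delta_cleaved` = f_with / f_without and
#'   `delta_uncleaved` = (1 - f_with) / (1 - f_without).
#' @export
cleavage_fold_change <- function(f_with, f_without) {
  stopifnot(f_with >= 0, f_with <= 1, f_without >= 0, f_without <= 1)
  if (f_without == 0) stop("fraction cleaved without ligand is zero")
  if (f_without == 1) stop("fraction uncleaved without ligand is zero")
  list(delta_cleaved = f_with / f_without,
       delta_uncleaved = (1 - f_with) / (1 - f_without))
}

#' Normalized transcript level from qPCR quantities
#'
#' (mCherry/BFP of the sample) over (mCherry/BFP of the control), scaled by
#' 100, so the non-cleaving control reads 100.
#'
#' @param mcherry_rna,bfp_rna sample transcript quantities.
#' @param mcherry_rna_ctl,bfp_rna_ctl control transcript quantities (> 0).
#' @return normalized mCherry RNA concentration.
#' @export
qpcr_normalize <- function(mcherry_rna, bfp_rna,
                           mcherry_rna_ctl, bfp_rna_ctl) {
  stopifnot(mcherry_rna_ctl > 0, bfp_rna_ctl > 0, bfp_rna > 0)
  (mcherry_rna / bfp_rna) / (mcherry_rna_ctl / bfp_rna_ctl) * 100
}

apply_flow_gate <- function(events, gate) {
  keep <- rep(TRUE, nrow(events))
  for (ch in names(gate)) {
    if (!ch %in% names(events)) stop("gate channel '", ch, "' not in events")
    keep <- keep & events[[ch]] > gate[[ch]]
  }
  events[keep, , drop = FALSE]
}

#' Relative fluorescence units from per-cell flow events
#'
#' Gates transfected cells (default: BFP above 10^2.7 fluorescence units),
#' computes the mean per-cell reporter ratio, and normalizes to the control
#' sample times 100. The default mode ratios mCherry to BFP; `"gfp"` mode
#' ratios GFP to mCherry (co-transfection marker).
#'
#' @param events,control_events data.frames with per-cell intensity columns
#'   (`mCherry`, `BFP`, optionally `GFP`), one row per cell.
#' @param gate named list of lower thresholds per channel; default
#'   `list(BFP = 10^2.7)`.
#' @param mode `"mcherry"` (mCherry/BFP) or `"gfp"` (GFP/mCherry).
#' @return list with `rfu`, `f_sample`, `f_control`, and post-gate cell
#'   counts.
#' @export
flow_rfu <- function(events, control_events, gate = list(BFP = 10^2.7),
                     mode = c("mcherry", "gfp")) {
  mode <- match.arg(mode)
  num <- if (mode == "mcherry") "mCherry" else "GFP"
  den <- if (mode == "mcherry") "BFP" else "mCherry"
  ev <- apply_flow_gate(events, gate)
  cev <- apply_flow_gate(control_events, gate)
  if (nrow(ev) == 0L || nrow(cev) == 0L) {
    stop("no cells pass the gate in sample and/or control")
  }
  f_sample <- mean(ev[[num]] / ev[[den]])
  f_control <- mean(cev[[num]] / cev[[den]])
  list(rfu = f_sample / f_control * 100,
       f_sample = f_sample, f_control = f_control,
       n_cells = nrow(ev), n_cells_control = nrow(cev))
}

#' Fit the one-site equilibrium binding model
#'
#' Nonlinear least squares for R = [L] * Rmax / ([L] + KD) + offset with KD
#' constrained positive. Initialized at Rmax = max(R) - min(R),
#' KD = median([L] > 0), offset = min(R).
#'
#' @param conc ligand concentrations `[L]` (>= 0; at least 3 distinct).
#' @param response measured equilibrium responses R.
#' @return list with `rmax`, `kd`, `offset`, `residual_norm`, `identifiable`
#'   (FALSE for flat curves, where the fit is meaningless).
#' @export
fit_binding <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  if (length(unique(conc)) < 3L) stop("need >= 3 distinct concentrations")
  flat <- stats::sd(response) < 1e-12 * max(abs(response), 1)
  df <- data.frame(L = conc, R = response)
  start <- list(rmax = max(response) - min(response),
                kd = stats::median(conc[conc > 0]),
                offset = min(response))
  fit <- try(stats::nls(R ~ L * rmax / (L + kd) + offset, data = df,
                        start = start, algorithm = "port",
                        lower = c(rmax = -Inf, kd = 1e-12, offset = -Inf),
                        control = stats::nls.control(maxiter = 500,
                                                     warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(rmax = NA_real_, kd = NA_real_, offset = mean(response),
                residual_norm = NA_real_, identifiable = FALSE))
  }
  cf <- stats::coef(fit)
  list(rmax = unname(cf["rmax"]), kd = unname(cf["kd"]),
       offset = unname(cf["offset"]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       identifiable = !flat)
}
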