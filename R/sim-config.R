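# Generative configuration for the synthetic assay world.

#' Configure the synthetic cholesterol-efflux assay world
#'
#' Describes a transient-transfection efflux experiment with known ground
#' truth: each construct has a true relative activity (% of WT), cells leak a
#' small acceptor-independent amount of labelled cholesterol into the medium,
#' mock-transfected cells show an ABCA1-unspecific efflux, per-well label load
#' varies, and transfection efficiency varies per construct and experiment and
#' is reported by a co-transfected renilla luciferase signal.
#'
#' Defaults mirror the assay design being emulated: 4 independent experiments,
#' one well per construct per experiment, a wild-type specific efflux of 0.30
#' (fraction of label exported to HDL acceptor in 4 h), 5% passive leakage, 5%
#' unspecific mock efflux, 15% load CV, 10% multiplicative measurement CV and
#' 5% transfection-efficiency CV. The transfection CV default is small because
#' the emulated study used the renilla reporter as a QC monitor without
#' applying a correction, a practice that is only sound when intra-assay
#' transfection variation is minor; larger values combined with
#' `renilla_normalize = TRUE` exercise the correction path.
#'
#' @param seed integer seed; identical configs give bit-identical simulations.
#' @param n_experiments number of independent experiments (>= 2).
#' @param constructs data.frame with columns `name` and `activity` (true
#'   relative activity in % of WT). Names `WT` and `MOCK` are reserved and
#'   added automatically.
#' @param wt_true_specific_efflux true ABCA1-specific efflux fraction of the
#'   wild type, in (0,1).
#' @param leakage_fraction acceptor-independent fraction of label found in the
#'   medium (what mock wells without acceptor measure).
#' @param mock_unspecific_efflux ABCA1-unspecific, acceptor-dependent efflux
#'   fraction (what mock wells with acceptor measure, above leakage).
#' @param load_cv coefficient of variation of total per-well label.
#' @param noise_cv multiplicative measurement CV applied to each read.
#' @param renilla_cv CV of the per-construct, per-experiment transfection
#'   efficiency factor.
#' @param wells_per_construct replicate wells per construct per experiment.
#' @param protein_levels optional named vector of true total-protein levels
#'   relative to WT = 1 (defaults to 1 for every construct).
#' @param surface_levels optional named vector of true surface-protein levels
#'   relative to WT = 1.
#' @param wt_band_actin_ratio true (band1+band2)/actin densitometry ratio of a
#'   WT lane.
#' @param treatment_effects named list: condition -> named list of construct ->
#'   numeric `c(total = , surface = , activity = )` fold changes vs mock
#'   treatment. Constructs absent from a condition keep fold 1.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, constructs = data.frame(
#'   name = c("p.E284K", "p.V589I"), activity = c(20, 95)))
#' @export
sim_config <- function(seed = 1L,
                       n_experiments = 4L,
                       constructs = data.frame(name = character(),
                                               activity = numeric()),
                       wt_true_specific_efflux = 0.30,
                       leakage_fraction = 0.05,
                       mock_unspecific_efflux = 0.05,
                       load_cv = 0.15,
                       noise_cv = 0.10,
                       renilla_cv = 0.05,
                       wells_per_construct = 1L,
                       protein_levels = NULL,
                       surface_levels = NULL,
                       wt_band_actin_ratio = 1.5,
                       treatment_effects = list()) {
  constructs <- as.data.frame(constructs)
  if (!all(c("name", "activity") %in% names(constructs))) {
    stop("constructs needs columns 'name' and 'activity'", call. = FALSE)
  }
  constructs$name <- as.character(constructs$name)
  constructs$activity <- as.numeric(constructs$activity)
  if (anyDuplicated(constructs$name)) {
    stop("duplicated construct names", call. = FALSE)
  }
  if (any(constructs$name %in% c("WT", "MOCK"))) {
    stop("'WT' and 'MOCK' are reserved construct names", call. = FALSE)
  }
  if (any(constructs$activity < 0)) {
    stop("true relative activities must be >= 0", call. = FALSE)
  }
  if (!is_count(n_experiments, min = 2L)) {
    stop("n_experiments must be an integer >= 2", call. = FALSE)
  }
  if (!is_count(wells_per_construct, min = 1L)) {
    stop("wells_per_construct must be an integer >= 1", call. = FALSE)
  }
  for (nm in c("leakage_fraction", "mock_unspecific_efflux")) {
    if (!is_fraction(get(nm))) stop(nm, " must lie in [0,1)", call. = FALSE)
  }
  if (!is_fraction(wt_true_specific_efflux) || wt_true_specific_efflux <= 0) {
    stop("wt_true_specific_efflux must lie in (0,1)", call. = FALSE)
  }
  if (wt_true_specific_efflux + leakage_fraction >= 1) {
    stop("wt_true_specific_efflux + leakage_fraction must be < 1",
         call. = FALSE)
  }
  # every well's expected medium fraction must stay below 1
  emax <- max(c(1, constructs$activity / 100)) * wt_true_specific_efflux +
    mock_unspecific_efflux + leakage_fraction
  if (emax >= 1) {
    stop("bounds error: configured activity implies efflux + leakage >= 1",
         call. = FALSE)
  }
  all_names <- c("WT", constructs$name)
  fill_levels <- function(x, what) {
    out <- stats::setNames(rep(1, length(all_names)), all_names)
    if (!is.null(x)) {
      if (is.null(names(x))) stop(what, " must be a named vector", call. = FALSE)
      bad <- setdiff(names(x), all_names)
      if (length(bad)) stop(what, ": unknown construct ", bad[1], call. = FALSE)
      out[names(x)] <- as.numeric(x)
    }
    if (any(out < 0)) stop(what, " must be >= 0", call. = FALSE)
    out
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_experiments = as.integer(n_experiments),
    constructs = constructs,
    wt_true_specific_efflux = wt_true_specific_efflux,
    leakage_fraction = leakage_fraction,
    mock_unspecific_efflux = mock_unspecific_efflux,
    load_cv = load_cv,
    noise_cv = noise_cv,
    renilla_cv = renilla_cv,
    wells_per_construct = as.integer(wells_per_construct),
    protein_levels = fill_levels(protein_levels, "protein_levels"),
    surface_levels = fill_levels(surface_levels, "surface_levels"),
    wt_band_actin_ratio = wt_band_actin_ratio,
    treatment_effects = treatment_effects
  ), class = "sim_config")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", nrow(x$constructs), "constructs |",
      x$n_experiments, "experiments\n")
  cat("  WT specific efflux", x$wt_true_specific_efflux,
      "| leakage", x$leakage_fraction,
      "| mock unspecific", x$mock_unspecific_efflux, "\n")
  cat("  CVs: load", x$load_cv, "noise", x$noise_cv,
      "renilla", x$renilla_cv, "\n")
  invisible(x)
}

#' @noRd
treatment_fold <- function(config, condition, construct, what) {
  eff <- config$treatment_effects[[condition]]
  if (is.null(eff)) return(1)
  e <- eff[[construct]]
  if (is.null(e) || is.null(e[[what]]) || is.na(e[[what]])) return(1)
  as.numeric(e[[what]])
}
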